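#' @useDynLib aortamark, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

.LANDMARK_CLASSES <- c("LCC", "NCC", "RCC", "LCO", "RCO")
.LANDMARK_CODES <- stats::setNames(1:5, .LANDMARK_CLASSES)

.is_orthonormal <- function(D, tol = 1e-6) {
    is.matrix(D) && all(dim(D) == c(3L, 3L)) &&
        max(abs(crossprod(D) - diag(3))) < tol
}

#' Voxel-grid geometry
#'
#' Describes the sampling lattice of a volumetric image: voxel counts per
#' axis, physical voxel size in mm, the world (RAS+) position of the centre
#' of voxel (0,0,0), and an orthonormal 3x3 direction matrix whose columns
#' are the world directions of the voxel axes. Voxel indices are 0-based
#' throughout; the world position of fractional index \eqn{i} is
#' \eqn{origin + D (spacing \circ i)}.
#'
#' @slot shape integer(3), voxels per axis (>= 1).
#' @slot spacing numeric(3), mm per voxel (> 0).
#' @slot origin numeric(3), world mm of the centre of voxel (0,0,0).
#' @slot direction 3x3 orthonormal matrix.
#' @export
setClass("GridGeometry",
    representation(shape = "integer", spacing = "numeric",
                   origin = "numeric", direction = "matrix"),
    validity = function(object) {
        msg <- character()
        if (length(object@shape) != 3L || any(object@shape < 1L))
            msg <- c(msg, "shape must be three integers >= 1")
        if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
            any(object@spacing <= 0))
            msg <- c(msg, "spacing must be three positive reals")
        if (length(object@origin) != 3L || any(!is.finite(object@origin)))
            msg <- c(msg, "origin must be three finite reals")
        if (!.is_orthonormal(object@direction))
            msg <- c(msg, "direction must be a 3x3 orthonormal matrix")
        if (length(msg)) msg else TRUE
    })

#' Volumetric scalar image
#'
#' A 3D scalar grid with physical geometry. \code{unit} records the value
#' scale: \code{"HU"} (Hounsfield units), \code{"probability"} (per-voxel
#' probabilities in [0,1]), \code{"label"} (integer class codes 0-5, 0 =
#' background, 1-5 = LCC/NCC/RCC/LCO/RCO), or \code{"normalized"}
#' (window-normalised intensities in [0,1]).
#'
#' @slot values 3D numeric array matching \code{geometry@shape}.
#' @slot geometry a [GridGeometry-class].
#' @slot unit character scalar.
#' @export
setClass("CTVolume",
    representation(values = "array", geometry = "GridGeometry",
                   unit = "character"),
    validity = function(object) {
        msg <- character()
        if (length(dim(object@values)) != 3L)
            msg <- c(msg, "values must be a 3D array")
        else if (!all(dim(object@values) == object@geometry@shape))
            msg <- c(msg, "values dimensions must match geometry shape")
        if (!(length(object@unit) == 1L &&
              object@unit %in% c("HU", "probability", "label", "normalized")))
            msg <- c(msg, "unit must be one of HU, probability, label, normalized")
        else if (object@unit %in% c("probability", "normalized")) {
            rng <- range(object@values)
            if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
                msg <- c(msg, sprintf("%s values must lie in [0,1]", object@unit))
        } else if (object@unit == "label") {
            v <- object@values
            if (max(abs(v - round(v))) > 1e-9 || min(v) < 0 || max(v) > 5)
                msg <- c(msg, "label values must be integers in 0..5")
        }
        if (length(msg)) msg else TRUE
    })

#' Named aortic landmark set
#'
#' Holds the five TAVI planning landmarks as world-coordinate (RAS+, mm)
#' points: the basal hinge points of the left-, non- and right-coronary
#' cusps (LCC, NCC, RCC) and the left and right coronary ostia (LCO, RCO).
#'
#' @slot points 5x3 numeric matrix, rownames LCC, NCC, RCC, LCO, RCO.
#' @export
setClass("LandmarkSet",
    representation(points = "matrix"),
    validity = function(object) {
        p <- object@points
        if (!is.numeric(p) || !all(dim(p) == c(5L, 3L)))
            return("points must be a 5x3 numeric matrix")
        if (!identical(rownames(p), .LANDMARK_CLASSES))
            return("rownames must be exactly LCC, NCC, RCC, LCO, RCO")
        if (any(!is.finite(p)))
            return("all coordinates must be finite")
        TRUE
    })

#' Per-class probability maps
#'
#' Six per-voxel probability grids (class 0 = background, classes 1-5 =
#' LCC/NCC/RCC/LCO/RCO) sharing one [GridGeometry-class]. Probabilities
#' sum to 1 per voxel.
#'
#' @slot geometry a [GridGeometry-class].
#' @slot maps 4D array, dims \code{c(shape, 6)}; class c is slice c+1.
#' @export
setClass("ProbabilityMaps",
    representation(geometry = "GridGeometry", maps = "array"),
    validity = function(object) {
        d <- dim(object@maps)
        if (length(d) != 4L || d[4] != 6L)
            return("maps must be a 4D array with 6 class slices")
        if (!all(d[1:3] == object@geometry@shape))
            return("maps dimensions must match geometry shape")
        # range/normalisation checks on a deterministic voxel stride so
        # construction stays cheap on large grids (full check <= 128^3/8)
        nvox <- prod(d[1:3])
        step <- max(1, nvox %/% 262144)
        vox <- seq(1, nvox, by = step)
        tot <- 0
        for (cc in 0:5) {
            v <- object@maps[vox + cc * nvox]
            if (min(v) < -1e-9 || max(v) > 1 + 1e-9)
                return("probabilities must lie in [0,1]")
            tot <- tot + v
        }
        if (max(abs(tot - 1)) > 1e-6)
            return("per-voxel class probabilities must sum to 1")
        TRUE
    })

#' Detector backend contract
#'
#' Virtual parent for landmark detector backends. A backend emulates one of
#' the three sphere-radius models (radius tag 3, 5 or 7 mm) and maps a
#' normalised sub-volume to per-class probabilities of identical shape via
#' [predictProbabilities()].
#'
#' @slot radiusTag numeric scalar, sphere radius (mm) the model targets.
#' @export
setClass("DetectorBackend",
    representation("VIRTUAL", radiusTag = "numeric"))

#' Gaussian surrogate detector backend
#'
#' Stands in for a trained convolutional network: given the true landmark
#' positions it emits, for each class, an isotropic Gaussian probability
#' bump (sd = radiusTag/2 mm) centred on a jittered copy of the true point,
#' normalised per voxel against a constant background score. The jitter is
#' drawn once per backend from the seed, so predictions are deterministic
#' and window-size independent.
#'
#' @slot landmarks a [LandmarkSet-class] of true positions (world mm).
#' @slot jitterSd numeric, sd (mm) of the Gaussian centre jitter.
#' @slot backgroundScore numeric, unnormalised background score.
#' @slot seed integer seed.
#' @export
setClass("SurrogateBackend", contains = "DetectorBackend",
    representation(landmarks = "LandmarkSet", jitterSd = "numeric",
                   backgroundScore = "numeric", seed = "integer"),
    validity = function(object) {
        if (!(object@radiusTag > 0)) return("radiusTag must be positive")
        if (object@jitterSd < 0) return("jitterSd must be >= 0")
        if (object@backgroundScore <= 0)
            return("backgroundScore must be positive")
        TRUE
    })

#' Aortic annular plane
#'
#' The plane through the three basal hinge points (LCC, NCC, RCC), with the
#' unit normal oriented towards the coronary ostia so that ostium heights
#' are positive.
#'
#' @slot point numeric(3), centroid of the three hinge points (world mm).
#' @slot normal numeric(3), unit normal.
#' @export
setClass("AnnularPlane",
    representation(point = "numeric", normal = "numeric"),
    validity = function(object) {
        if (length(object@point) != 3L || any(!is.finite(object@point)))
            return("point must be a finite 3-vector")
        if (length(object@normal) != 3L ||
            abs(sqrt(sum(object@normal^2)) - 1) > 1e-9)
            return("normal must be a unit 3-vector")
        TRUE
    })

#' Synthetic aortic-root CT phantom specification
#'
#' A fully materialised, seeded parameter record for one synthetic
#' contrast-enhanced aortic-root CT volume. The constructor
#' [phantomSpec()] draws all random parameters from the seed and records
#' them here, so the same spec always renders the same volume and landmark
#' set.
#'
#' @slot shape integer(3) voxels.
#' @slot spacing numeric(3) mm.
#' @slot seed integer.
#' @slot annulusRadius numeric, annular circle radius (mm).
#' @slot planeTilt numeric, tilt of the annular plane from axial (deg).
#' @slot tiltAzimuth numeric, azimuth of the tilt axis (deg).
#' @slot hingeAngles numeric(3), in-plane angles (deg) of LCC/NCC/RCC.
#' @slot ostiumAngles numeric(2), in-plane angles (deg) of LCO/RCO.
#' @slot ostiumRadii numeric(2), in-plane radial offsets (mm) of LCO/RCO.
#' @slot lcoHeight,rcoHeight numeric, perpendicular ostium heights (mm).
#' @slot lumenHU,tissueHU numeric, mean attenuation (HU).
#' @slot calciumHU numeric vector, one HU value per calcific deposit.
#' @slot calciumOffsets matrix (n x 3), deposit centres relative to a hinge
#'   point (mm); row i attaches to hinge ((i-1) mod 3)+1.
#' @slot calciumRadii numeric vector, deposit radii (mm).
#' @slot noiseSd numeric, additive Gaussian noise sd (HU).
#' @slot motionBlurSd numeric, motion blur sd (mm), 0 = off.
#' @slot blurAxis integer, axis (1-3) along which motion blur acts.
#' @export
setClass("PhantomSpec",
    representation(shape = "integer", spacing = "numeric", seed = "integer",
                   annulusRadius = "numeric", planeTilt = "numeric",
                   tiltAzimuth = "numeric", hingeAngles = "numeric",
                   ostiumAngles = "numeric", ostiumRadii = "numeric",
                   lcoHeight = "numeric", rcoHeight = "numeric",
                   lumenHU = "numeric", tissueHU = "numeric",
                   calciumHU = "numeric", calciumOffsets = "matrix",
                   calciumRadii = "numeric", noiseSd = "numeric",
                   motionBlurSd = "numeric", blurAxis = "integer"),
    validity = function(object) {
        msg <- character()
        if (length(object@shape) != 3L || any(object@shape < 8L))
            msg <- c(msg, "shape must be three integers >= 8")
        if (length(object@spacing) != 3L || any(object@spacing <= 0))
            msg <- c(msg, "spacing must be positive")
        if (object@annulusRadius <= 0)
            msg <- c(msg, "annulusRadius must be positive")
        if (abs(object@planeTilt) > 20)
            msg <- c(msg, "planeTilt must be within 20 degrees")
        if (length(object@hingeAngles) != 3L)
            msg <- c(msg, "hingeAngles must have length 3")
        if (object@noiseSd < 0 || object@motionBlurSd < 0)
            msg <- c(msg, "noise and blur sd must be >= 0")
        if (length(msg)) msg else TRUE
    })

#' Pipeline run configuration
#'
#' Bundles every tunable constant of the detection pipeline in one
#' serialisable record: target isotropic spacing (1.0 mm), ROI size
#' (128 voxels), the three sphere-radius tags (3, 5, 7 mm), the selection
#' and high-confidence probability thresholds (0.5, 0.9), the clustering
#' link threshold (1.1 mm), surrogate backend parameters, sliding-window
#' size/stride (64/32) and the master seed.
#'
#' @slot backend character, \code{"surrogate"} (the trained-CNN backend of
#'   the original method is out of scope).
#' @slot radii numeric vector of sphere-radius tags (mm).
#' @slot targetSpacing numeric, isotropic resampling target (mm).
#' @slot roiSize integer, cropped cube edge (voxels).
#' @slot roiCenter numeric(3) or NA, explicit ROI centre (world mm).
#' @slot lowThreshold,highThreshold numeric, probability thresholds.
#' @slot linkThreshold numeric, clustering threshold (mm).
#' @slot jitterSd,backgroundScore numeric, surrogate parameters.
#' @slot window,stride integer, sliding-window geometry (voxels).
#' @slot useSlidingWindow logical.
#' @slot seed integer.
#' @export
setClass("RunConfig",
    representation(backend = "character", radii = "numeric",
                   targetSpacing = "numeric", roiSize = "integer",
                   roiCenter = "numeric", lowThreshold = "numeric",
                   highThreshold = "numeric", linkThreshold = "numeric",
                   jitterSd = "numeric", backgroundScore = "numeric",
                   window = "integer", stride = "integer",
                   useSlidingWindow = "logical", seed = "integer"),
    validity = function(object) {
        msg <- character()
        if (!(object@lowThreshold >= 0 &&
              object@lowThreshold < object@highThreshold &&
              object@highThreshold <= 1))
            msg <- c(msg, "need 0 <= lowThreshold < highThreshold <= 1")
        if (any(object@radii <= 0)) msg <- c(msg, "radii must be positive")
        if (object@linkThreshold <= 0)
            msg <- c(msg, "linkThreshold must be positive")
        if (object@targetSpacing <= 0)
            msg <- c(msg, "targetSpacing must be positive")
        if (length(msg)) msg else TRUE
    })
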