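# Per-voxel sums over the class dimension of a c(shape, 6) array.
# Slice-wise accumulation avoids reshaping the full array.
.class_sums <- function(maps) {
    d <- dim(maps)
    tot <- maps[, , , 1L]
    for (i in seq(2L, d[4]))
        tot <- tot + maps[, , , i]
    tot
}

.normalize_classes <- function(maps) {
    tot <- .class_sums(maps)
    maps / as.numeric(tot)   # tot recycles over the class dimension
}

#' Construct per-class probability maps
#'
#' @param maps 4D array \code{c(shape, 6)}; class 0 (background) first.
#' @param geometry a [GridGeometry-class].
#' @param normalize renormalise per voxel before validation (default TRUE).
#' @return a [ProbabilityMaps-class].
#' @export
probabilityMaps <- function(maps, geometry, normalize = TRUE) {
    if (normalize) maps <- .normalize_classes(maps)
    new("ProbabilityMaps", geometry = geometry, maps = maps)
}

#' @param object a [ProbabilityMaps-class].
#' @param class landmark class code 0-5 (0 = background).
#' @rdname aortamark-generics
#' @export
setMethod("classMap", "ProbabilityMaps", function(object, class) {
    stopifnot(class %in% 0:5)
    object@maps[, , , class + 1L]
})

setMethod("show", "ProbabilityMaps", function(object) {
    cat(sprintf("ProbabilityMaps %s, 6 classes (background + %s)\n",
                paste(object@geometry@shape, collapse = "x"),
                paste(.LANDMARK_CLASSES, collapse = "/")))
})

#' Window-normalise a CT volume
#'
#' Clips Hounsfield values to [-1024, 2048] and maps the window linearly to
#' [0,1]. The fixed window keeps contrast-enhanced blood (~300-500 HU) and
#' calcium (~700-1500 HU) separable and is identical across patients.
#'
#' @param volume a [CTVolume-class] with unit \code{"HU"}.
#' @return a [CTVolume-class] with unit \code{"normalized"}.
#' @export
normalizeVolume <- function(volume) {
    if (volume@unit != "HU") stop("normalizeVolume expects an HU volume")
    v <- (pmin(pmax(volume@values, -1024), 2048) + 1024) / 3072
    ctVolume(v, volume@geometry, unit = "normalized")
}

#' Create a Gaussian surrogate backend
#'
#' @param radiusTag sphere-radius tag (3, 5 or 7 mm) of the emulated model.
#' @param landmarks true landmark positions ([LandmarkSet-class]).
#' @param jitterSd sd (mm) of the per-class Gaussian centre jitter
#'   (default 0.5).
#' @param backgroundScore unnormalised background score (default 0.05).
#' @param seed integer seed; jitter draws are independent per class and per
#'   radius tag.
#' @return a [SurrogateBackend-class].
#' @export
surrogateBackend <- function(radiusTag, landmarks, jitterSd = 0.5,
                             backgroundScore = 0.05, seed = 1L) {
    new("SurrogateBackend", radiusTag = radiusTag, landmarks = landmarks,
        jitterSd = jitterSd, backgroundScore = backgroundScore,
        seed = as.integer(seed))
}

# Jittered per-class centres for one (seed, radiusTag) pair: 5x3 matrix.
.surrogate_centers <- function(landmarks, radiusTag, jitterSd, seed) {
    P <- landmarkPoints(landmarks)
    set.seed(as.integer((as.numeric(seed) + 97 * radiusTag) %% 2147483647))
    eps <- matrix(stats::rnorm(15, 0, jitterSd), 5, 3, byrow = TRUE)
    P + eps
}

#' Surrogate probability prediction on a grid
#'
#' Emulates one trained sphere-radius model: per class c the unnormalised
#' score at voxel v is \eqn{\exp(-\|center(v) - \tilde x_c\|^2 / (2\sigma^2))}
#' with \eqn{\sigma = radiusTag / 2} and \eqn{\tilde x_c} the true landmark
#' jittered by N(0, jitterSd^2 I); the background scores a constant; per
#' voxel, probabilities are the scores normalised to sum to 1. Jitter is
#' seeded independently per class and per radius tag, so repeated calls are
#' deterministic.
#'
#' @param grid a [GridGeometry-class].
#' @param landmarks true landmark positions ([LandmarkSet-class]).
#' @param radiusTag sphere-radius tag (mm); sigma = radiusTag/2.
#' @param jitterSd jitter sd in mm (default 0.5).
#' @param backgroundScore constant background score (default 0.05).
#' @param seed integer seed.
#' @return a [ProbabilityMaps-class].
#' @export
surrogatePredict <- function(grid, landmarks, radiusTag, jitterSd = 0.5,
                             backgroundScore = 0.05, seed = 1L) {
    if (jitterSd < 0) stop("jitterSd must be >= 0")
    grid <- as_geometry(grid)
    centers <- .surrogate_centers(landmarks, radiusTag, jitterSd, seed)
    sigma2 <- (radiusTag / 2)^2
    maps <- c_surrogate_maps(grid@shape, grid@spacing, grid@origin,
                             grid@direction, centers, sigma2,
                             backgroundScore)
    probabilityMaps(maps, grid, normalize = FALSE)
}

#' @rdname predictProbabilities
#' @export
setMethod("predictProbabilities", "SurrogateBackend",
    function(backend, volume, ...) {
        surrogatePredict(as_geometry(volume), backend@landmarks,
                         backend@radiusTag, backend@jitterSd,
                         backend@backgroundScore, backend@seed)
    })

#' Sliding-window prediction over a volume
#'
#' Tiles the volume with \code{window}^3 sub-volumes at the given stride
#' (the final window along each axis is shifted to touch the border), runs
#' the backend on each, averages overlapping per-class predictions per
#' voxel, and renormalises. Volumes smaller than the window are handled as
#' a single zero-padded window.
#'
#' @param volume a normalised, isotropic [CTVolume-class].
#' @param backend a [DetectorBackend-class].
#' @param window window edge in voxels (default 64).
#' @param stride window step in voxels (default 32).
#' @return a [ProbabilityMaps-class] on the volume's grid.
#' @export
slidingWindowPredict <- function(volume, backend, window = 64L,
                                 stride = 32L) {
    g <- volume@geometry
    window <- as.integer(window); stride <- as.integer(stride)
    pad <- pmax(window - g@shape, 0L)
    if (any(pad > 0L)) {
        padded <- array(0, dim = pmax(g@shape, window))
        padded[seq_len(g@shape[1]), seq_len(g@shape[2]),
               seq_len(g@shape[3])] <- volume@values
        volume <- ctVolume(padded,
                           gridGeometry(dim(padded), g@spacing, g@origin,
                                        g@direction),
                           unit = volume@unit)
        res <- slidingWindowPredict(volume, backend, window, stride)
        maps <- res@maps[seq_len(g@shape[1]), seq_len(g@shape[2]),
                         seq_len(g@shape[3]), , drop = FALSE]
        return(probabilityMaps(maps, g, normalize = TRUE))
    }
    starts <- function(n) unique(c(seq(0L, n - window, by = stride),
                                   n - window))
    s1 <- starts(g@shape[1]); s2 <- starts(g@shape[2]); s3 <- starts(g@shape[3])
    acc <- array(0, c(g@shape, 6L))
    cnt <- array(0, g@shape)
    for (a in s1) for (b in s2) for (cc in s3) {
        ia <- (a + 1L):(a + window)
        ib <- (b + 1L):(b + window)
        ic <- (cc + 1L):(cc + window)
        sub <- ctVolume(volume@values[ia, ib, ic],
                        gridGeometry(rep(window, 3L), g@spacing,
                                     voxelToWorld(g, c(a, b, cc)),
                                     g@direction),
                        unit = volume@unit)
        p <- predictProbabilities(backend, sub)
        acc[ia, ib, ic, ] <- acc[ia, ib, ic, , drop = FALSE] + p@maps
        cnt[ia, ib, ic] <- cnt[ia, ib, ic] + 1
    }
    avg <- acc / as.numeric(cnt)  # recycles cnt over the class dimension
    probabilityMaps(avg, g, normalize = TRUE)
}

#' Fuse the three sphere-radius probability maps
#'
#' Averages the per-class probabilities of the three model outputs
#' elementwise, then renormalises per voxel so class probabilities sum
#' to 1 (combine-and-normalise fusion).
#'
#' @param maps3 list of three [ProbabilityMaps-class] on identical grids.
#' @return a [ProbabilityMaps-class].
#' @export
fuseProbabilityMaps <- function(maps3) {
    if (length(maps3) < 2L) stop("need at least two maps to fuse")
    g <- maps3[[1]]@geometry
    for (m in maps3[-1])
        if (!.same_geometry(g, m@geometry))
            stop("probability maps must share one grid geometry")
    acc <- Reduce(`+`, lapply(maps3, function(m) m@maps)) / length(maps3)
    probabilityMaps(acc, g, normalize = TRUE)
}
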