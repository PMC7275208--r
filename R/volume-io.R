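#' Read a volumetric image from NIfTI
#'
#' Reads a 3D NIfTI-1 image (.nii or .nii.gz) into a [CTVolume-class],
#' taking spacing, origin and direction from the stored transform (sform
#' preferred). The world frame is RAS+ and voxel indices are 0-based with
#' the origin at the centre of voxel (0,0,0), as in the NIfTI standard.
#'
#' @param path file path to a .nii / .nii.gz image.
#' @param unit value scale of the stored data; default \code{"HU"}.
#' @return a [CTVolume-class].
#' @seealso [writeVolume()]
#' @export
readVolume <- function(path, unit = "HU") {
    if (!file.exists(path)) stop("volume file not found: ", path)
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L)
        stop("expected a 3D image, got ", length(d), " dimensions: ", path)
    M <- RNifti::xform(img, useQuaternionFirst = FALSE)
    sp <- RNifti::pixdim(img)[1:3]
    D <- M[1:3, 1:3] %*% diag(1 / sp)
    if (!.is_orthonormal(D, tol = 1e-4))
        stop("non-orthonormal direction matrix in ", path,
             " (oblique/sheared transforms are not supported)")
    # re-orthonormalise exactly (header rows are float32)
    sv <- svd(D)
    D <- sv$u %*% t(sv$v)
    vals <- array(as.numeric(img), dim = d)
    if (unit == "label") vals <- round(vals)
    ctVolume(vals,
             gridGeometry(d, spacing = sp, origin = M[1:3, 4], direction = D),
             unit = unit)
}

#' Write a volumetric image as NIfTI
#'
#' Writes a [CTVolume-class] to NIfTI-1 with its full geometry in the
#' sform/qform. With \code{datatype = "double"} (default for non-label
#' data) values round-trip bit-identically through [readVolume()];
#' \code{"int16"} matches clinical CT storage and rounds to whole HU.
#'
#' @param volume a [CTVolume-class].
#' @param path output path (.nii or .nii.gz).
#' @param datatype \code{"auto"} (label -> int16, otherwise double),
#'   \code{"double"}, \code{"float"} or \code{"int16"}.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(volume, path,
                        datatype = c("auto", "double", "float", "int16")) {
    datatype <- match.arg(datatype)
    if (!dir.exists(dirname(path)))
        stop("parent directory does not exist: ", dirname(path))
    g <- volume@geometry
    if (datatype == "auto")
        datatype <- if (volume@unit == "label") "int16" else "double"
    vals <- volume@values
    if (datatype == "int16") vals <- round(vals)
    img <- RNifti::asNifti(vals)
    RNifti::pixdim(img) <- g@spacing
    M <- rbind(cbind(g@direction %*% diag(g@spacing), g@origin), c(0, 0, 0, 1))
    RNifti::sform(img) <- structure(M, code = 2L)
    RNifti::qform(img) <- structure(M, code = 2L)
    RNifti::writeNifti(img, path, datatype = datatype)
    invisible(path)
}

#' Construct a landmark set
#'
#' @param points 5x3 numeric matrix (rows LCC, NCC, RCC, LCO, RCO, world
#'   mm), or a named list of 3-vectors with those names.
#' @return a [LandmarkSet-class].
#' @examples
#' landmarkSet(list(LCC = c(10, 0, 0), NCC = c(-5, 8, 0), RCC = c(-5, -8, 0),
#'                  LCO = c(8, 4, 14), RCO = c(-2, -9, 16)))
#' @export
landmarkSet <- function(points) {
    if (is.list(points)) {
        if (!setequal(names(points), .LANDMARK_CLASSES))
            stop("landmark list must have names ",
                 paste(.LANDMARK_CLASSES, collapse = ", "))
        points <- do.call(rbind, points[.LANDMARK_CLASSES])
    }
    points <- as.matrix(points)
    rownames(points) <- .LANDMARK_CLASSES
    colnames(points) <- c("x", "y", "z")
    new("LandmarkSet", points = points)
}

#' @rdname aortamark-generics
#' @export
setMethod("landmarkPoints", "LandmarkSet", function(object) object@points)

setMethod("show", "LandmarkSet", function(object) {
    cat("LandmarkSet (world mm):\n")
    print(round(object@points, 3))
})

#' Read landmarks from JSON
#'
#' Schema: \code{{"LCC":[x,y,z], "NCC":[...], "RCC":[...], "LCO":[...],
#' "RCO":[...]}} in world mm, RAS+.
#'
#' @param path JSON file path.
#' @return a [LandmarkSet-class].
#' @export
readLandmarks <- function(path) {
    if (!file.exists(path)) stop("landmark file not found: ", path)
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    landmarkSet(lapply(obj[.LANDMARK_CLASSES], as.numeric))
}

#' Write landmarks to JSON
#'
#' @param landmarks a [LandmarkSet-class].
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeLandmarks <- function(landmarks, path) {
    p <- landmarkPoints(landmarks)
    obj <- lapply(seq_len(5), function(i) unname(p[i, ]))
    names(obj) <- rownames(p)
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
    invisible(path)
}
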