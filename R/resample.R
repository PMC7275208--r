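#' Resample a volume to isotropic resolution
#'
#' Resamples onto an isotropic lattice (default 1.0 mm) sharing the input's
#' origin and direction. The output shape is
#' \code{ceiling(shape * spacing / target)} so the full physical extent is
#' retained, and values are obtained by cubic (Catmull-Rom) spline
#' interpolation of the input at the output voxel centres, with mirror
#' boundary handling. The HU scale is preserved; probability volumes are
#' clamped back to [0,1] after interpolation (cubic kernels can overshoot).
#'
#' @param volume a [CTVolume-class] with unit \code{"HU"},
#'   \code{"probability"} or \code{"normalized"}.
#' @param targetSpacing isotropic voxel size in mm (default 1.0).
#' @return a [CTVolume-class] at spacing \code{(t, t, t)}.
#' @export
resampleIsotropic <- function(volume, targetSpacing = 1.0) {
    if (targetSpacing <= 0) stop("targetSpacing must be positive")
    if (volume@unit == "label")
        stop("cubic interpolation is not defined for label volumes")
    g <- volume@geometry
    outShape <- as.integer(ceiling(g@shape * g@spacing / targetSpacing))
    A <- diag(targetSpacing / g@spacing)
    vals <- c_resample_affine(as.numeric(volume@values), g@shape, outShape,
                              A, c(0, 0, 0))
    if (volume@unit %in% c("probability", "normalized"))
        vals <- pmin(pmax(vals, 0), 1)
    dim(vals) <- outShape
    ctVolume(vals,
             gridGeometry(outShape, spacing = targetSpacing,
                          origin = g@origin, direction = g@direction),
             unit = volume@unit)
}

#' Crop a fixed-size cube around a world point
#'
#' Extracts a \code{size}^3 sub-volume from an isotropic volume, centred so
#' that output voxel \code{(size/2, size/2, size/2)} lands on the input
#' voxel whose centre is nearest \code{centerWorld}. Out-of-bounds voxels
#' are filled with \code{fill} (default -1024 HU, air) and a warning is
#' raised; the origin is updated so retained voxels keep their world
#' coordinates.
#'
#' @param volume an isotropic [CTVolume-class].
#' @param centerWorld numeric(3), ROI centre in world mm.
#' @param size cube edge in voxels (default 128).
#' @param fill pad value (default -1024).
#' @return a [CTVolume-class] of shape \code{size}^3.
#' @export
cropCentered <- function(volume, centerWorld, size = 128L, fill = -1024) {
    g <- volume@geometry
    if (diff(range(g@spacing)) > 1e-6)
        stop("cropCentered requires an isotropic volume")
    size <- as.integer(size)
    cIdx <- round(worldToVoxel(g, centerWorld))
    start <- as.integer(cIdx - size %/% 2L)  # 0-based input index of output voxel 0
    lo <- pmax(start, 0L)
    hi <- pmin(start + size - 1L, g@shape - 1L)
    out <- array(fill, dim = rep(size, 3L))
    if (all(lo <= hi)) {
        out[(lo[1] - start[1] + 1L):(hi[1] - start[1] + 1L),
            (lo[2] - start[2] + 1L):(hi[2] - start[2] + 1L),
            (lo[3] - start[3] + 1L):(hi[3] - start[3] + 1L)] <-
            volume@values[(lo[1] + 1L):(hi[1] + 1L),
                          (lo[2] + 1L):(hi[2] + 1L),
                          (lo[3] + 1L):(hi[3] + 1L)]
        nKept <- prod(hi - lo + 1L)
    } else nKept <- 0L
    if (nKept < size^3)
        warning(sprintf("cropCentered: %d of %d voxels padded with %g",
                        size^3 - nKept, size^3, fill))
    ctVolume(out,
             gridGeometry(rep(size, 3L), spacing = g@spacing,
                          origin = voxelToWorld(g, start),
                          direction = g@direction),
             unit = volume@unit)
}

.rotation_matrix <- function(degXYZ) {
    th <- degXYZ * pi / 180
    cx <- cos(th[1]); sx <- sin(th[1])
    cy <- cos(th[2]); sy <- sin(th[2])
    cz <- cos(th[3]); sz <- sin(th[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    Rz %*% Ry %*% Rx
}

#' Random similarity augmentation of a volume and its landmarks
#'
#' Draws one scale perturbation (percent) and three per-axis rotation
#' angles (degrees), each uniform on \code{[-limit, limit]} (default 3),
#' and applies the resulting similarity transform about the volume's world
#' centre to both the image (cubic interpolation, output on the input
#' lattice) and the landmark points. Rotations compose as
#' \code{R = Rz Ry Rx}. Deterministic for a fixed seed; \code{limit = 0} is
#' the exact identity on landmarks.
#'
#' @param volume a [CTVolume-class] (HU or normalised).
#' @param landmarks a [LandmarkSet-class] in the same world frame.
#' @param seed integer seed.
#' @param limit half-width of the uniform parameter range (default 3).
#' @return list with elements \code{volume}, \code{landmarks} and
#'   \code{params} (the drawn scale percentage and angles).
#' @export
randomSimilarityTransform <- function(volume, landmarks, seed, limit = 3) {
    if (limit < 0) stop("limit must be >= 0")
    set.seed(as.integer(seed))
    draws <- stats::runif(4, -limit, limit)
    s <- 1 + draws[1] / 100
    R <- .rotation_matrix(draws[2:4])
    g <- volume@geometry
    C <- gridCenter(g)
    # landmarks: x' = C + s R (x - C)
    P <- landmarkPoints(landmarks)
    Pnew <- t(C + s * (R %*% (t(P) - C)))
    # image: sample input at T^-1(world(out voxel)); compose into index space
    D <- g@direction
    Sm <- diag(g@spacing)
    Sinv <- diag(1 / g@spacing)
    A <- (1 / s) * Sinv %*% t(D) %*% t(R) %*% D %*% Sm
    bWorld <- C + (1 / s) * as.numeric(t(R) %*% (g@origin - C))
    b <- as.numeric(Sinv %*% t(D) %*% (bWorld - g@origin))
    vals <- c_resample_affine(as.numeric(volume@values), g@shape, g@shape,
                              A, b)
    if (volume@unit %in% c("probability", "normalized"))
        vals <- pmin(pmax(vals, 0), 1)
    dim(vals) <- g@shape
    rownames(Pnew) <- rownames(P)
    list(volume = ctVolume(vals, g, unit = volume@unit),
         landmarks = landmarkSet(Pnew),
         params = list(scalePct = draws[1], anglesDeg = draws[2:4],
                       scale = s, rotation = R, center = C))
}
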