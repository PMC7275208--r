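#' Multi-class spherical landmark label mask
#'
#' Builds the label volume used as a detection target: every voxel whose
#' centre lies within \code{radius} mm of a landmark receives that
#' landmark's class code (LCC = 1, NCC = 2, RCC = 3, LCO = 4, RCO = 5); all
#' other voxels are 0. Where spheres overlap, the voxel takes the class of
#' the nearest landmark centre (ties go to the lower class code). The
#' boundary is inclusive (distance <= radius). Radii of 3, 5 and 7 mm are
#' the standard target sizes.
#'
#' @param landmarks a [LandmarkSet-class] (world mm).
#' @param grid a [GridGeometry-class].
#' @param radius sphere radius in mm.
#' @return a [CTVolume-class] with unit \code{"label"}.
#' @export
generateSphereMask <- function(landmarks, grid, radius) {
    if (radius <= 0) stop("radius must be positive")
    grid <- as_geometry(grid)
    P <- landmarkPoints(landmarks)
    lab <- array(0, dim = grid@shape)
    best <- array(Inf, dim = grid@shape)
    for (ci in seq_len(5)) {
        x <- P[ci, ]
        idx <- worldToVoxel(grid, x)
        pad <- radius / grid@spacing + 1
        lo <- pmax(floor(idx - pad), 0)
        hi <- pmin(ceiling(idx + pad), grid@shape - 1)
        if (any(lo > hi)) {
            warning(sprintf("landmark %s lies outside the grid; class %d absent",
                            rownames(P)[ci], ci))
            next
        }
        ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
        box <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
        w <- voxelToWorld(grid, box)
        d2 <- (w[, 1] - x[1])^2 + (w[, 2] - x[2])^2 + (w[, 3] - x[3])^2
        inside <- d2 <= radius^2
        if (!any(inside)) {
            warning(sprintf("no voxel centre within %g mm of landmark %s",
                            radius, rownames(P)[ci]))
            next
        }
        sub <- box[inside, , drop = FALSE] + 1L
        lin <- sub[, 1] + (sub[, 2] - 1L) * grid@shape[1] +
            (sub[, 3] - 1L) * prod(grid@shape[1:2])
        take <- d2[inside] < best[lin]   # strict: ties keep the lower class
        lab[lin[take]] <- ci
        best[lin[take]] <- d2[inside][take]
    }
    ctVolume(lab, grid, unit = "label")
}

#' Recover landmark points from a label mask
#'
#' Per class, the unweighted centroid of the labelled voxel centres in
#' world mm. For an isolated sphere centred on a voxel centre this is exact
#' by symmetry; in general recovery is within half a voxel diagonal.
#'
#' @param mask a label [CTVolume-class] containing all five classes.
#' @return a [LandmarkSet-class].
#' @export
maskToLandmarks <- function(mask) {
    if (mask@unit != "label") stop("mask must have unit 'label'")
    g <- mask@geometry
    pts <- lapply(seq_len(5), function(ci) {
        sel <- which(mask@values == ci, arr.ind = TRUE)
        if (nrow(sel) == 0L)
            stop("class ", .LANDMARK_CLASSES[ci], " is absent from the mask")
        colMeans(voxelToWorld(g, sel - 1L))
    })
    names(pts) <- .LANDMARK_CLASSES
    landmarkSet(pts)
}
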