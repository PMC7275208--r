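#' Single-linkage clustering of candidate points
#'
#' Partitions points by single-linkage agglomerative clustering cut at a
#' Euclidean distance threshold (default 1.1 mm): two points share a
#' cluster iff they are connected by a chain of steps each <= threshold.
#' The partition is unique and independent of point order. On a 1 mm
#' isotropic voxel lattice a 1.1 mm threshold equals 6-connected (face
#' adjacency) component labelling, since 1 < 1.1 < sqrt(2).
#'
#' @param points n x 3 matrix of world-mm points (n >= 1).
#' @param threshold link distance in mm (default 1.1).
#' @return integer vector of cluster ids (1-based, arbitrary order).
#' @export
clusterVoxels <- function(points, threshold = 1.1) {
    points <- rbind(points)
    n <- nrow(points)
    if (n == 0L) stop("clusterVoxels needs at least one point")
    if (n == 1L) return(1L)
    hc <- stats::hclust(stats::dist(points), method = "single")
    # cut strictly above the threshold so exact-threshold links merge
    stats::cutree(hc, h = threshold * (1 + 1e-12))
}

.lm_fail <- function(className, msg) {
    stop(structure(class = c("aortamark_no_candidates", "error", "condition"),
                   list(message = msg, call = NULL, className = className)))
}

#' Extract one landmark from a class probability map
#'
#' The threshold-cluster-centroid postprocessing applied per class: select
#' voxels with probability > \code{low} (0.5); cluster their world
#' coordinates by single linkage at \code{linkThreshold} (1.1 mm); keep the
#' largest cluster (ties go to the cluster containing the most probable
#' voxel, then to the one with the lexicographically smallest voxel index);
#' the landmark is the unweighted centroid of that cluster's voxels with
#' probability > \code{high} (0.9). When no voxel exceeds \code{high}, the
#' centroid of the whole largest cluster is used and the fallback flag set.
#'
#' @param probMap 3D array of class probabilities.
#' @param grid the [GridGeometry-class] of \code{probMap}.
#' @param className landmark class name (for diagnostics/errors).
#' @param low selection threshold (default 0.5).
#' @param high high-confidence threshold (default 0.9).
#' @param linkThreshold clustering distance in mm (default 1.1).
#' @return list with \code{point} (world mm), \code{className} and
#'   \code{diagnostics} (nSelected, nClusters, largestCluster, nHigh,
#'   fallback).
#' @export
extractLandmark <- function(probMap, grid, className = "landmark",
                            low = 0.5, high = 0.9, linkThreshold = 1.1) {
    stopifnot(low >= 0, low < high, high <= 1)
    grid <- as_geometry(grid)
    sel <- which(probMap > low, arr.ind = TRUE)
    if (nrow(sel) == 0L)
        .lm_fail(className, sprintf(
            "no voxel with probability > %g for class %s", low, className))
    p <- probMap[sel]
    # order by voxel index so cluster ids and tie-breaks are enumeration
    # order independent
    ord <- order(sel[, 3], sel[, 2], sel[, 1])
    sel <- sel[ord, , drop = FALSE]
    p <- p[ord]
    w <- voxelToWorld(grid, sel - 1L)
    cl <- clusterVoxels(w, linkThreshold)
    sizes <- tabulate(cl)
    cand <- which(sizes == max(sizes))
    if (length(cand) > 1L) {
        peak <- vapply(cand, function(k) max(p[cl == k]), numeric(1))
        cand <- cand[peak == max(peak)]
        if (length(cand) > 1L)
            cand <- cand[which.min(vapply(cand,
                                          function(k) which(cl == k)[1L],
                                          numeric(1)))]
    }
    keep <- cl == cand[1L]
    highIn <- keep & (p > high)
    fallback <- !any(highIn)
    use <- if (fallback) keep else highIn
    point <- colMeans(w[use, , drop = FALSE])
    list(point = point, className = className,
         diagnostics = data.frame(class = className,
                                  nSelected = nrow(sel),
                                  nClusters = length(sizes),
                                  largestCluster = max(sizes),
                                  nHigh = sum(highIn),
                                  fallback = fallback))
}

#' Detect all five landmarks from fused probability maps
#'
#' Applies [extractLandmark()] to classes 1-5 of a fused
#' [ProbabilityMaps-class] (background ignored). If any class yields no
#' candidate voxel the call fails with an error naming every failing
#' class; there is never a silent zero point.
#'
#' @param fused a [ProbabilityMaps-class].
#' @param low,high,linkThreshold as in [extractLandmark()].
#' @return list with \code{landmarks} (a [LandmarkSet-class]) and
#'   \code{diagnostics} (data.frame, one row per class).
#' @export
detectLandmarks <- function(fused, low = 0.5, high = 0.9,
                            linkThreshold = 1.1) {
    g <- fused@geometry
    preds <- vector("list", 5L)
    failed <- character()
    for (ci in seq_len(5)) {
        res <- tryCatch(
            extractLandmark(fused@maps[, , , ci + 1L], g,
                            className = .LANDMARK_CLASSES[ci],
                            low = low, high = high,
                            linkThreshold = linkThreshold),
            aortamark_no_candidates = function(e) NULL)
        if (is.null(res)) failed <- c(failed, .LANDMARK_CLASSES[ci])
        preds[[ci]] <- res
    }
    if (length(failed))
        stop("landmark detection failed for class(es): ",
             paste(failed, collapse = ", "))
    pts <- lapply(preds, `[[`, "point")
    names(pts) <- .LANDMARK_CLASSES
    list(landmarks = landmarkSet(pts),
         diagnostics = do.call(rbind, lapply(preds, `[[`, "diagnostics")))
}
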