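.cross3 <- function(a, b) {
    c(a[2] * b[3] - a[3] * b[2],
      a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
}

#' Reconstruct the aortic annular plane
#'
#' Fits the plane through the three basal hinge points (LCC, NCC, RCC).
#' The plane point is their centroid; the normal is the normalised cross
#' product of two edge vectors, with its sign chosen so the midpoint of
#' the two coronary ostia has non-negative signed distance (heights come
#' out positive on the ostia side).
#'
#' @param lcc,ncc,rcc numeric(3), hinge points in world mm.
#' @param ostia 2 x 3 matrix (or list of two 3-vectors) with LCO and RCO.
#' @return an [AnnularPlane-class].
#' @export
fitAnnularPlane <- function(lcc, ncc, rcc, ostia) {
    if (is.list(ostia)) ostia <- do.call(rbind, ostia)
    e1 <- ncc - lcc
    e2 <- rcc - lcc
    n <- .cross3(e1, e2)
    area2 <- sqrt(sum(n^2))          # twice the triangle area
    if (area2 / 2 <= 1e-6)
        stop("hinge points are collinear or coincident; no unique plane")
    n <- n / area2
    ctr <- (lcc + ncc + rcc) / 3
    mid <- colMeans(rbind(ostia))
    if (sum((mid - ctr) * n) < 0) n <- -n
    new("AnnularPlane", point = ctr, normal = n)
}

setMethod("show", "AnnularPlane", function(object) {
    cat(sprintf("AnnularPlane point (%s) mm, normal (%s)\n",
                paste(format(object@point, digits = 4), collapse = ", "),
                paste(format(object@normal, digits = 4), collapse = ", ")))
})

#' Perpendicular height of a point above the annular plane
#'
#' Signed point-to-plane distance \eqn{(p - point) \cdot normal}; positive
#' on the ostia side by the orientation rule of [fitAnnularPlane()].
#'
#' @param plane an [AnnularPlane-class].
#' @param ostium numeric(3), world mm.
#' @return height in mm.
#' @export
coronaryHeight <- function(plane, ostium) {
    sum((ostium - plane@point) * plane@normal)
}

#' Derive coronary ostium heights from a landmark set
#'
#' Reconstructs the annular plane from LCC/NCC/RCC and measures the
#' perpendicular heights of the left and right coronary ostia above it -
#' the clinical measurements used to assess coronary obstruction risk.
#'
#' @param landmarks a [LandmarkSet-class].
#' @return named numeric: \code{lco_height_mm}, \code{rco_height_mm}.
#' @export
deriveMeasurements <- function(landmarks) {
    P <- landmarkPoints(landmarks)
    plane <- fitAnnularPlane(P["LCC", ], P["NCC", ], P["RCC", ],
                             P[c("LCO", "RCO"), ])
    c(lco_height_mm = coronaryHeight(plane, P["LCO", ]),
      rco_height_mm = coronaryHeight(plane, P["RCO", ]))
}

#' Write a coronary-height measurements table
#'
#' @param measurements named numeric from [deriveMeasurements()], or a
#'   list of such vectors.
#' @param path CSV output path.
#' @param patientId id column value(s).
#' @return \code{path}, invisibly. Heights are written to 0.1 mm.
#' @export
writeMeasurements <- function(measurements, path, patientId = "case1") {
    if (!is.list(measurements)) measurements <- list(measurements)
    df <- data.frame(
        patient_id = patientId,
        lco_height_mm = round(vapply(measurements, `[[`, numeric(1),
                                     "lco_height_mm"), 1),
        rco_height_mm = round(vapply(measurements, `[[`, numeric(1),
                                     "rco_height_mm"), 1))
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}
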