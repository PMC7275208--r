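#' Construct a voxel-grid geometry
#'
#' @param shape integer(3), voxel counts per axis.
#' @param spacing numeric(3) or scalar, mm per voxel.
#' @param origin numeric(3), world mm of the centre of voxel (0,0,0).
#' @param direction 3x3 orthonormal matrix (columns = world directions of
#'   the voxel axes); identity by default (RAS+ aligned).
#' @return a [GridGeometry-class].
#' @examples
#' g <- gridGeometry(c(64, 64, 64), spacing = 1)
#' voxelToWorld(g, c(5, 6, 7))
#' @export
gridGeometry <- function(shape, spacing = 1, origin = c(0, 0, 0),
                         direction = diag(3)) {
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    new("GridGeometry", shape = as.integer(shape),
        spacing = as.numeric(spacing), origin = as.numeric(origin),
        direction = direction)
}

#' @rdname aortamark-generics
#' @export
setMethod("gridShape", "GridGeometry", function(object) object@shape)
#' @rdname aortamark-generics
#' @export
setMethod("spacing", "GridGeometry", function(object) object@spacing)
#' @rdname aortamark-generics
#' @export
setMethod("origin", "GridGeometry", function(object) object@origin)
#' @rdname aortamark-generics
#' @export
setMethod("direction", "GridGeometry", function(object) object@direction)

#' @rdname aortamark-generics
#' @export
setMethod("geometry", "CTVolume", function(object) object@geometry)
#' @rdname aortamark-generics
#' @export
setMethod("geometry", "ProbabilityMaps", function(object) object@geometry)
#' @rdname aortamark-generics
#' @export
setMethod("gridShape", "CTVolume", function(object) object@geometry@shape)
#' @rdname aortamark-generics
#' @export
setMethod("spacing", "CTVolume", function(object) object@geometry@spacing)
#' @rdname aortamark-generics
#' @export
setMethod("origin", "CTVolume", function(object) object@geometry@origin)
#' @rdname aortamark-generics
#' @export
setMethod("direction", "CTVolume", function(object) object@geometry@direction)
#' @rdname aortamark-generics
#' @export
setMethod("voxelUnit", "CTVolume", function(object) object@unit)
#' @rdname aortamark-generics
#' @export
setMethod("voxelValues", "CTVolume", function(object) object@values)

setMethod("show", "GridGeometry", function(object) {
    cat(sprintf("GridGeometry %s, spacing %s mm, origin (%s) mm\n",
                paste(object@shape, collapse = "x"),
                paste(format(object@spacing), collapse = "x"),
                paste(format(object@origin, digits = 4), collapse = ", ")))
})

setMethod("show", "CTVolume", function(object) {
    v <- range(object@values)
    cat(sprintf("CTVolume [%s] %s, spacing %s mm, values %.4g..%.4g\n",
                object@unit, paste(dim(object@values), collapse = "x"),
                paste(format(object@geometry@spacing), collapse = "x"),
                v[1], v[2]))
})

#' Construct a volumetric image
#'
#' @param values 3D numeric array.
#' @param geometry a [GridGeometry-class]; alternatively pass
#'   \code{spacing}/\code{origin}/\code{direction} to build one.
#' @param unit value scale, one of \code{"HU"}, \code{"probability"},
#'   \code{"label"}, \code{"normalized"}.
#' @param spacing,origin,direction used when \code{geometry} is missing.
#' @return a [CTVolume-class].
#' @export
ctVolume <- function(values, geometry = NULL, unit = "HU", spacing = 1,
                     origin = c(0, 0, 0), direction = diag(3)) {
    if (is.null(geometry))
        geometry <- gridGeometry(dim(values), spacing, origin, direction)
    new("CTVolume", values = values, geometry = geometry, unit = unit)
}

#' Convert fractional voxel indices to world coordinates
#'
#' World position of (possibly fractional, possibly out-of-grid) 0-based
#' voxel indices: \eqn{origin + D (spacing \circ index)}. Exact inverse of
#' [worldToVoxel()].
#'
#' @param grid a [GridGeometry-class] (or an object with a geometry).
#' @param index numeric(3) or an n x 3 matrix of 0-based voxel indices.
#' @return world mm coordinates, same shape as \code{index}.
#' @export
voxelToWorld <- function(grid, index) {
    grid <- as_geometry(grid)
    idx <- rbind(index)
    w <- t(grid@direction %*% (t(idx) * grid@spacing)) +
        rep(grid@origin, each = nrow(idx))
    if (is.matrix(index)) w else drop(w)
}

#' Convert world coordinates to fractional voxel indices
#'
#' @param grid a [GridGeometry-class] (or an object with a geometry).
#' @param point numeric(3) or an n x 3 matrix of world mm points.
#' @return fractional 0-based voxel indices, same shape as \code{point}.
#' @export
worldToVoxel <- function(grid, point) {
    grid <- as_geometry(grid)
    p <- rbind(point)
    idx <- t(crossprod(grid@direction,
                       t(p) - grid@origin) / grid@spacing)
    if (is.matrix(point)) idx else drop(idx)
}

as_geometry <- function(x) {
    if (is(x, "GridGeometry")) x else geometry(x)
}

#' World coordinate of the grid centre
#'
#' Centre of the voxel lattice, i.e. the world position of fractional
#' index (shape - 1) / 2.
#'
#' @param grid a [GridGeometry-class].
#' @return numeric(3) world mm.
#' @export
gridCenter <- function(grid) {
    grid <- as_geometry(grid)
    voxelToWorld(grid, (grid@shape - 1) / 2)
}

# World coordinates of every voxel centre, as three arrays of grid shape.
# Axis-separable fast path when direction is the identity.
.voxel_coord_arrays <- function(grid) {
    s <- grid@shape
    i0 <- seq_len(s[1]) - 1
    i1 <- seq_len(s[2]) - 1
    i2 <- seq_len(s[3]) - 1
    if (max(abs(grid@direction - diag(3))) < 1e-12) {
        x <- grid@origin[1] + grid@spacing[1] * i0
        y <- grid@origin[2] + grid@spacing[2] * i1
        z <- grid@origin[3] + grid@spacing[3] * i2
        list(X = array(x, s),
             Y = array(rep(y, each = s[1]), s),
             Z = array(rep(z, each = s[1] * s[2]), s))
    } else {
        D <- grid@direction
        sx <- grid@spacing[1] * i0
        sy <- grid@spacing[2] * i1
        sz <- grid@spacing[3] * i2
        ax <- function(r) {
            array(D[r, 1] * sx, s) +
                array(rep(D[r, 2] * sy, each = s[1]), s) +
                array(rep(D[r, 3] * sz, each = s[1] * s[2]), s) +
                grid@origin[r]
        }
        list(X = ax(1), Y = ax(2), Z = ax(3))
    }
}

# Squared world distance from every voxel centre to a point.
.voxel_dist2 <- function(grid, point, coords = NULL) {
    if (is.null(coords)) coords <- .voxel_coord_arrays(grid)
    (coords$X - point[1])^2 + (coords$Y - point[2])^2 +
        (coords$Z - point[3])^2
}

.same_geometry <- function(a, b, tol = 1e-6) {
    all(a@shape == b@shape) &&
        max(abs(a@spacing - b@spacing)) < tol &&
        max(abs(a@origin - b@origin)) < tol &&
        max(abs(a@direction - b@direction)) < tol
}
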