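# Independent oracles and small fixtures used across the suite.

# Union-find single-linkage oracle: points share a cluster iff connected by
# a chain of pairwise steps <= threshold.
uf_cluster <- function(points, threshold) {
    n <- nrow(points)
    parent <- seq_len(n)
    find <- function(i) {
        while (parent[i] != i) {
            parent[i] <- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    if (n > 1) {
        d <- as.matrix(dist(points))
        for (i in seq_len(n - 1)) for (j in (i + 1):n) {
            if (d[i, j] <= threshold + 1e-12) {
                ri <- find(i)
                rj <- find(j)
                if (ri != rj) parent[ri] <- rj
            }
        }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    match(roots, unique(roots))
}

# Connected components of a boolean adjacency matrix (BFS).
adjacency_components <- function(adj) {
    n <- nrow(adj)
    comp <- integer(n)
    cur <- 0L
    for (s in seq_len(n)) {
        if (comp[s] != 0L) next
        cur <- cur + 1L
        queue <- s
        comp[s] <- cur
        while (length(queue)) {
            v <- queue[1L]
            queue <- queue[-1L]
            nb <- which(adj[v, ] & comp == 0L)
            comp[nb] <- cur
            queue <- c(queue, nb)
        }
    }
    comp
}

# Two labelings describe the same partition?
same_partition <- function(a, b) {
    identical(as.integer(match(a, unique(a))),
              as.integer(match(b, unique(b))))
}

# Integer lattice points with |x|^2 <= r^2 around the origin (sphere voxel
# count on a 1 mm grid with the landmark on a voxel centre).
lattice_ball_count <- function(r) {
    s <- floor(r)
    g <- expand.grid(x = -s:s, y = -s:s, z = -s:s)
    sum(g$x^2 + g$y^2 + g$z^2 <= r^2)
}

# Inclusive linear-interpolation quantile (independent of stats::quantile):
# h = (n-1)p + 1, linear between order statistics.
quantile_inclusive <- function(x, p) {
    x <- sort(x)
    n <- length(x)
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Exact two-sided Wilcoxon signed-rank p by enumeration of all 2^n sign
# assignments (distinct nonzero |d| assumed).
wilcoxon_exact_p <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    stats <- signs %*% r
    mu <- n * (n + 1) / 4
    mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# A miniature aortic-root-like landmark set (annulus radius 5 mm, ostia
# ~5 mm above the plane) fitting inside a [-10, 10] mm cube.
toy_landmarks <- function() {
    landmarkSet(list(LCC = c(0, 5, -1), NCC = c(-4.35, -2.5, 0.5),
                     RCC = c(4.35, -2.5, -0.2), LCO = c(1, 4, 4.5),
                     RCO = c(-1.5, -4, 5)))
}

# Five points pairwise >= 22 mm apart on integer voxel centres, >= 7 mm
# from the faces of a [-20, 20] mm cube: spheres up to radius 7 fit with
# no overlap, so per-class voxel counts are unclipped.
separated_landmarks <- function() {
    landmarkSet(list(LCC = c(-13, -13, -13), NCC = c(13, 13, -13),
                     RCC = c(13, -13, 13), LCO = c(-13, 13, 13),
                     RCO = c(0, 0, 0)))
}

# Rigid motion: random rotation (QR of a Gaussian matrix, det +1) plus
# translation, applied to the rows of a point matrix.
random_rigid <- function(seed) {
    set.seed(seed)
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    list(R = Q, t = rnorm(3, 0, 20))
}

apply_rigid <- function(rigid, pts) {
    t(rigid$R %*% t(rbind(pts))) + rep(rigid$t, each = nrow(rbind(pts)))
}

transform_landmarks <- function(rigid, landmarks) {
    P <- apply_rigid(rigid, landmarkPoints(landmarks))
    rownames(P) <- rownames(landmarkPoints(landmarks))
    landmarkSet(P)
}

# Small smooth HU phantom-like volume for interpolation tests.
smooth_volume <- function(shape = c(20, 20, 20), spacing = 1,
                          origin = c(0, 0, 0)) {
    g <- gridGeometry(shape, spacing, origin)
    co <- expand.grid(i = seq_len(shape[1]) - 1, j = seq_len(shape[2]) - 1,
                      k = seq_len(shape[3]) - 1)
    w <- voxelToWorld(g, as.matrix(co))
    v <- 100 * sin(w[, 1] / 7) + 80 * cos(w[, 2] / 9) + 5 * w[, 3]
    ctVolume(array(v, shape), g, unit = "HU")
}
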