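# A backend returning the same probabilities everywhere, with a call
# counter, for sliding-window contract tests.
setClass("ConstantBackend", contains = "DetectorBackend",
         representation(probs = "numeric", env = "environment"))
setMethod("predictProbabilities", "ConstantBackend",
    function(backend, volume, ...) {
        backend@env$calls <- backend@env$calls + 1L
        g <- geometry(volume)
        maps <- array(rep(backend@probs, each = prod(gridShape(g))),
                      c(gridShape(g), 6))
        probabilityMaps(maps, g, normalize = FALSE)
    })

test_that("HU window normalisation maps [-1024, 2048] to [0, 1]", {
    mk <- function(x) ctVolume(array(x, c(3, 3, 3)), unit = "HU")
    expect_equal(unique(as.numeric(voxelValues(normalizeVolume(mk(-1024))))), 0)
    expect_equal(unique(as.numeric(voxelValues(normalizeVolume(mk(2048))))), 1)
    expect_equal(unique(as.numeric(voxelValues(normalizeVolume(mk(512))))), 0.5)
    # clipping
    expect_equal(unique(as.numeric(voxelValues(normalizeVolume(mk(-4000))))), 0)
    expect_equal(voxelUnit(normalizeVolume(mk(0))), "normalized")
})

test_that("surrogate probabilities follow the Gaussian score model", {
    g <- gridGeometry(c(21, 21, 21), 1, origin = c(-10, -10, -10))
    lm <- toy_landmarks()
    pm <- surrogatePredict(g, lm, radiusTag = 3, jitterSd = 0, seed = 1)
    # at a voxel on a landmark: p = 1 / (1 + background + tiny others)
    idx <- round(worldToVoxel(g, landmarkPoints(lm)["LCC", ])) + 1
    expect_gt(classMap(pm, 1)[idx[1], idx[2], idx[3]], 0.9)
    expect_equal(classMap(pm, 1)[idx[1], idx[2], idx[3]], 1 / 1.05,
                 tolerance = 1e-3)
    # >= 4 sigma from every landmark the background dominates
    far <- classMap(pm, 0)[1, 1, 21]
    expect_gt(far, 0.99)
    # per-voxel class sums are exactly 1 (full check, all voxels)
    tot <- Reduce(`+`, lapply(0:5, function(ci) classMap(pm, ci)))
    expect_lt(max(abs(tot - 1)), 1e-9)
})

test_that("with zero jitter each class peaks at its landmark voxel", {
    g <- gridGeometry(c(41, 41, 41), 1, origin = c(-20, -20, -20))
    lm <- landmarkSet(landmarkPoints(separated_landmarks()) +
                      matrix(c(0.2, -0.3, 0.1), 5, 3, byrow = TRUE))
    pm <- surrogatePredict(g, lm, radiusTag = 5, jitterSd = 0, seed = 99)
    for (ci in 1:5) {
        peak <- which(classMap(pm, ci) == max(classMap(pm, ci)),
                      arr.ind = TRUE)[1, ] - 1
        nearest <- round(worldToVoxel(g, landmarkPoints(lm)[ci, ]))
        expect_equal(as.numeric(peak), as.numeric(nearest))
    }
})

test_that("surrogate jitter is deterministic per seed and radius", {
    g <- gridGeometry(c(11, 11, 11), 1)
    lm <- landmarkSet(landmarkPoints(toy_landmarks()) / 2 + 5)
    a <- surrogatePredict(g, lm, 3, jitterSd = 0.5, seed = 42)
    b <- surrogatePredict(g, lm, 3, jitterSd = 0.5, seed = 42)
    expect_identical(a@maps, b@maps)
    c3 <- surrogatePredict(g, lm, 5, jitterSd = 0.5, seed = 42)
    expect_false(identical(a@maps, c3@maps))  # independent per radius
})

test_that("sliding-window prediction averages to the constant for a constant backend", {
    v <- ctVolume(array(0.5, c(24, 24, 24)),
                  gridGeometry(c(24, 24, 24), 1), unit = "normalized")
    env <- new.env(); env$calls <- 0L
    be <- new("ConstantBackend", radiusTag = 3,
              probs = c(0.5, 0.1, 0.1, 0.1, 0.1, 0.1), env = env)
    pm <- slidingWindowPredict(v, be, window = 16, stride = 8)
    expect_lt(max(abs(classMap(pm, 0) - 0.5)), 1e-12)
    expect_lt(max(abs(classMap(pm, 3) - 0.1)), 1e-12)
    # placements: starts 0,8 per axis -> 2^3 windows
    expect_equal(env$calls, 8L)
})

test_that("128-voxel axes tile into 3 placements at window 64 stride 32", {
    v <- ctVolume(array(0.1, c(128, 16, 16)),
                  gridGeometry(c(128, 16, 16), 1), unit = "normalized")
    env <- new.env(); env$calls <- 0L
    be <- new("ConstantBackend", radiusTag = 3,
              probs = rep(1 / 6, 6), env = env)
    invisible(slidingWindowPredict(v, be, window = c(64), stride = 32))
    # only the first axis can slide: floor((128-64)/32)+1 = 3 placements
    expect_equal(env$calls, 3L)
})

test_that("sliding-window equals whole-volume prediction for the surrogate", {
    g <- gridGeometry(c(40, 40, 40), 1, origin = c(-20, -20, -20))
    lm <- landmarkSet(landmarkPoints(toy_landmarks()) * 0.8)
    be <- surrogateBackend(5, lm, jitterSd = 0.3, seed = 4)
    v <- ctVolume(array(0.4, c(40, 40, 40)), g, unit = "normalized")
    whole <- predictProbabilities(be, v)
    tiled <- slidingWindowPredict(v, be, window = 20, stride = 10)
    expect_lt(max(abs(whole@maps - tiled@maps)), 1e-9)
})

test_that("volumes smaller than the window are handled as one padded window", {
    g <- gridGeometry(c(10, 10, 10), 1)
    lm <- landmarkSet(landmarkPoints(toy_landmarks()) / 4 + 5)
    be <- surrogateBackend(3, lm, jitterSd = 0, seed = 2)
    v <- ctVolume(array(0.4, c(10, 10, 10)), g, unit = "normalized")
    pm <- slidingWindowPredict(v, be, window = 16, stride = 8)
    expect_equal(dim(pm@maps)[1:3], c(10L, 10L, 10L))
    whole <- predictProbabilities(be, v)
    expect_lt(max(abs(whole@maps - pm@maps)), 1e-9)
})

test_that("fusion is the per-class mean followed by renormalisation", {
    g <- gridGeometry(c(2, 2, 2), 1)
    set.seed(5)
    mk <- function() {
        raw <- array(runif(8 * 6, 0.01, 1), c(2, 2, 2, 6))
        probabilityMaps(raw, g, normalize = TRUE)
    }
    a <- mk(); b <- mk(); c3 <- mk()
    fused <- fuseProbabilityMaps(list(a, b, c3))
    manual <- (a@maps + b@maps + c3@maps) / 3
    # inputs are normalised, so the mean is already normalised
    expect_lt(max(abs(fused@maps - manual)), 1e-12)
    tot <- Reduce(`+`, lapply(0:5, function(ci) classMap(fused, ci)))
    expect_lt(max(abs(tot - 1)), 1e-9)

    same <- fuseProbabilityMaps(list(a, a, a))
    expect_lt(max(abs(same@maps - a@maps)), 1e-12)

    g2 <- gridGeometry(c(2, 2, 2), 2)
    bad <- probabilityMaps(a@maps, g2, normalize = FALSE)
    expect_error(fuseProbabilityMaps(list(a, bad)), "grid")
})
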