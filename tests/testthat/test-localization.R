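test_that("single-linkage clustering matches hand-worked cases", {
    cl <- clusterVoxels(rbind(c(0, 0, 0), c(1, 0, 0), c(3, 3, 3)), 1.1)
    expect_true(same_partition(cl, c(1, 1, 2)))
    # sqrt(2) > 1.1: diagonal neighbours split
    cl2 <- clusterVoxels(rbind(c(0, 0, 0), c(1, 1, 0)), 1.1)
    expect_true(same_partition(cl2, c(1, 2)))
    expect_equal(clusterVoxels(rbind(c(2, 2, 2)), 1.1), 1L)
    # chain: consecutive 1 mm steps connect ends 4 mm apart
    chain <- cbind(0:4, 0, 0)
    expect_true(same_partition(clusterVoxels(chain, 1.1), rep(1, 5)))
    # links at exactly the threshold distance merge (inclusive criterion)
    expect_true(same_partition(
        clusterVoxels(rbind(c(0, 0, 0), c(1.1, 0, 0)), 1.1), c(1, 1)))
    expect_error(clusterVoxels(matrix(numeric(), 0, 3)), "at least one")
})

test_that("clustering equals the union-find oracle on random voxel sets", {
    for (seed in 1:10) {
        set.seed(seed)
        n <- sample(5:120, 1)
        pts <- unique(matrix(sample(0:19, n * 3, TRUE), ncol = 3))
        cl <- clusterVoxels(pts, 1.1)
        expect_true(same_partition(cl, uf_cluster(pts, 1.1)))
    }
})

test_that("landmark extraction reproduces the worked toy grids", {
    g <- gridGeometry(c(4, 4, 4), 1)
    p <- array(0, c(4, 4, 4))
    p[1, 1, 1] <- 0.95; p[2, 1, 1] <- 0.92; p[3, 3, 3] <- 0.6
    res <- extractLandmark(p, g, "LCC")
    expect_equal(res$point, c(0.5, 0, 0))
    expect_false(res$diagnostics$fallback)
    expect_equal(res$diagnostics$nSelected, 3L)
    expect_equal(res$diagnostics$nClusters, 2L)
    expect_equal(res$diagnostics$largestCluster, 2L)

    # fallback: one cluster of three, none above 0.9
    q <- array(0, c(4, 4, 4))
    q[1, 1, 1] <- 0.8; q[2, 1, 1] <- 0.7; q[1, 2, 1] <- 0.6
    res2 <- extractLandmark(q, g, "NCC")
    expect_equal(res2$point, c(1 / 3, 1 / 3, 0))
    expect_true(res2$diagnostics$fallback)

    # nothing above the selection threshold
    expect_error(extractLandmark(array(0.4, c(4, 4, 4)), g, "RCC"),
                 class = "aortamark_no_candidates")
})

test_that("equal-size clusters break ties by peak probability", {
    g <- gridGeometry(c(9, 9, 9), 1)
    p <- array(0, c(9, 9, 9))
    p[1, 1, 1] <- 0.6; p[2, 1, 1] <- 0.96   # cluster A, peak 0.96
    p[8, 8, 8] <- 0.7; p[9, 8, 8] <- 0.8    # cluster B, peak 0.8
    res <- extractLandmark(p, g, "LCO")
    expect_equal(res$point, c(1, 0, 0))     # the single >0.9 voxel of A
})

test_that("the centroid lies inside the selected cluster's bounding box", {
    set.seed(20)
    g <- gridGeometry(c(16, 16, 16), 1)
    for (i in 1:5) {
        p <- array(0, c(16, 16, 16))
        ctr <- sample(4:12, 3, TRUE)
        for (j in 1:30) {
            off <- sample(-2:2, 3, TRUE)
            v <- pmin(pmax(ctr + off, 1), 16)
            p[v[1], v[2], v[3]] <- runif(1, 0.55, 1)
        }
        res <- extractLandmark(p, g, "X")
        sel <- which(p > 0.5, arr.ind = TRUE) - 1
        expect_true(all(res$point >= apply(sel, 2, min) - 1e-12) &&
                    all(res$point <= apply(sel, 2, max) + 1e-12))
    }
})

test_that("detectLandmarks localises all five classes near the truth", {
    g <- gridGeometry(c(41, 41, 41), 1, origin = c(-20, -20, -20))
    # annulus-scale spacing (~11 mm between nearest landmarks)
    lm <- landmarkSet(landmarkPoints(toy_landmarks()) * 2)
    maps <- lapply(c(3, 5, 7), function(r)
        surrogatePredict(g, lm, r, jitterSd = 0, seed = 8))
    fused <- fuseProbabilityMaps(maps)
    det <- detectLandmarks(fused)
    err <- landmarkErrors(det$landmarks, lm)
    expect_lt(max(err), sqrt(3) / 2)  # half a voxel diagonal at 1 mm
    expect_equal(det$diagnostics$class, c("LCC", "NCC", "RCC", "LCO", "RCO"))
})

test_that("integer-voxel shifts of the maps shift predictions exactly", {
    g <- gridGeometry(c(31, 31, 31), 1, origin = c(-15, -15, -15))
    lm <- landmarkSet(landmarkPoints(toy_landmarks()) * 0.6)
    fused <- fuseProbabilityMaps(lapply(c(3, 5, 7), function(r)
        surrogatePredict(g, lm, r, jitterSd = 0.4, seed = 31)))
    det <- detectLandmarks(fused)
    offset <- c(3, -2, 5)
    gShift <- gridGeometry(c(31, 31, 31), 1, origin = c(-15, -15, -15) + offset)
    shifted <- probabilityMaps(fused@maps, gShift, normalize = FALSE)
    detShift <- detectLandmarks(shifted)
    expect_lt(max(abs(landmarkPoints(detShift$landmarks) -
                      (landmarkPoints(det$landmarks) +
                       rep(offset, each = 5)))), 1e-9)
})

test_that("background-only maps fail naming all five classes", {
    g <- gridGeometry(c(8, 8, 8), 1)
    maps <- array(0, c(8, 8, 8, 6))
    maps[, , , 1] <- 1
    flat <- probabilityMaps(maps, g, normalize = FALSE)
    expect_error(detectLandmarks(flat), "LCC, NCC, RCC, LCO, RCO")
})
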