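test_that("the same seed renders bit-identical phantoms", {
    a <- generatePhantom(phantomSpec(9, shape = c(80L, 80L, 80L)))
    b <- generatePhantom(phantomSpec(9, shape = c(80L, 80L, 80L)))
    expect_identical(voxelValues(a$volume), voxelValues(b$volume))
    expect_identical(landmarkPoints(a$landmarks), landmarkPoints(b$landmarks))
})

test_that("noiseless rendering puts exact lumen HU at the landmarks", {
    spec <- phantomSpec(4, shape = c(80L, 80L, 80L), noiseSd = 0,
                        calciumCount = 0)
    ph <- generatePhantom(spec)
    v <- voxelValues(ph$volume)
    expect_setequal(unique(as.numeric(v)), c(spec@tissueHU, spec@lumenHU))
    idx <- round(worldToVoxel(geometry(ph$volume),
                              landmarkPoints(ph$landmarks))) + 1
    for (i in 1:5)
        expect_equal(v[idx[i, 1], idx[i, 2], idx[i, 3]], spec@lumenHU)
    expect_gt(spec@lumenHU, spec@tissueHU)  # detectability precondition
})

test_that("hinge points are coplanar and equidistant from the centre", {
    spec <- phantomSpec(31, shape = c(80L, 80L, 80L))
    ph <- generatePhantom(spec)
    P <- landmarkPoints(ph$landmarks)[1:3, ]
    # the annulus centre is the grid centre (world origin by construction)
    expect_lt(max(abs(sqrt(rowSums(P^2)) - spec@annulusRadius)), 1e-9)
    vcross <- function(a, b) c(a[2]*b[3]-a[3]*b[2],
                                          a[3]*b[1]-a[1]*b[3],
                                          a[1]*b[2]-a[2]*b[1])
    nrm <- vcross(P[2, ] - P[1, ], P[3, ] - P[1, ])
    nrm <- nrm / sqrt(sum(nrm^2))
    expect_lt(abs(sum(P[1, ] * nrm) - sum(P[2, ] * nrm)), 1e-9)
    expect_lt(abs(sum(P[1, ] * nrm) - sum(P[3, ] * nrm)), 1e-9)
})

test_that("motion blur and noise change values but not determinism", {
    base <- generatePhantom(phantomSpec(6, shape = c(48L, 48L, 48L),
                                        lcoHeight = 11, rcoHeight = 11,
                                        noiseSd = 0))
    blurred <- generatePhantom(phantomSpec(6, shape = c(48L, 48L, 48L),
                                           lcoHeight = 11, rcoHeight = 11,
                                           noiseSd = 0, motionBlurSd = 1.5))
    expect_false(identical(voxelValues(base$volume),
                           voxelValues(blurred$volume)))
    # blur preserves the mean (kernel sums to 1) up to boundary effects
    expect_equal(mean(voxelValues(blurred$volume)),
                 mean(voxelValues(base$volume)), tolerance = 0.01)
    noisy <- generatePhantom(phantomSpec(6, shape = c(48L, 48L, 48L),
                                         lcoHeight = 11, rcoHeight = 11))
    expect_equal(sd(voxelValues(noisy$volume) - voxelValues(base$volume)),
                 20, tolerance = 0.05)
})

test_that("landmarks outside the grid are refused", {
    expect_error(generatePhantom(phantomSpec(1, shape = c(24L, 24L, 24L))),
                 "outside")
})

test_that("cohorts are reproducible with the clinical artefact mix", {
    d1 <- tempfile("coh1"); d2 <- tempfile("coh2")
    m1 <- generateCohort(5, 77, d1, shape = c(80L, 80L, 80L),
                         writeVolumes = FALSE)
    m2 <- generateCohort(5, 77, d2, shape = c(80L, 80L, 80L),
                         writeVolumes = FALSE)
    expect_identical(m1[, c("id", "seed", "motion", "noise_heavy",
                            "lco_height", "rco_height")],
                     m2[, c("id", "seed", "motion", "noise_heavy",
                            "lco_height", "rco_height")])
    # landmark JSON files byte-identical across runs
    expect_identical(readBin(m1$landmarks[3], "raw", 1e5),
                     readBin(m2$landmarks[3], "raw", 1e5))
    # pairwise distinct landmark sets
    pts <- lapply(m1$landmarks, function(p) landmarkPoints(readLandmarks(p)))
    for (i in 1:4) for (j in (i + 1):5)
        expect_false(isTRUE(all.equal(pts[[i]], pts[[j]])))

    m10 <- generateCohort(10, 3, tempfile(), shape = c(80L, 80L, 80L),
                          writeVolumes = FALSE)
    expect_equal(sum(m10$motion), 4)       # 40% motion artefacts
    expect_equal(sum(m10$noise_heavy), 4)  # 40% noise artefacts
})
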