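test_that("landmark errors are per-class Euclidean distances", {
    lm <- toy_landmarks()
    expect_equal(unname(landmarkErrors(lm, lm)), rep(0, 5))
    P <- landmarkPoints(lm)
    P["LCC", ] <- P["LCC", ] + c(1, 2, 2)
    expect_equal(landmarkErrors(landmarkSet(P), lm)[["LCC"]], 3)
    # isometry: common rigid motion leaves all errors unchanged
    P2 <- landmarkPoints(lm) + matrix(rnorm(15, 0, 2), 5, 3)
    pred <- landmarkSet(P2)
    e0 <- landmarkErrors(pred, lm)
    rigid <- random_rigid(42)
    e1 <- landmarkErrors(transform_landmarks(rigid, pred),
                         transform_landmarks(rigid, lm))
    expect_equal(e1, e0, tolerance = 1e-12)
})

test_that("distance summaries use inclusive linear-interpolation quartiles", {
    tab <- distanceTable(paste0("c", 1:5), rep("LCC", 5), c(1, 2, 3, 4, 5))
    s <- summarizeDistances(tab)
    lcc <- s[s$class == "LCC", ]
    expect_equal(c(lcc$lq, lcc$median, lcc$uq), c(2, 3, 4))

    one <- summarizeDistances(distanceTable("c1", "RCO", 2.5))
    expect_equal(c(one[1, "lq"], one[1, "median"], one[1, "uq"]),
                 c(2.5, 2.5, 2.5))

    same <- summarizeDistances(distanceTable(paste0("c", 1:4), rep("LCO", 4),
                                             rep(1.2, 4)))
    expect_equal(same[1, "uq"] - same[1, "lq"], 0)
    expect_error(summarizeDistances(distanceTable(character(), character(),
                                                  numeric())), "empty")
})

test_that("quartiles match the sort-and-interpolate oracle on small lists", {
    for (seed in 1:8) {
        set.seed(seed)
        x <- round(runif(sample(2:20, 1), 0, 5), 2)
        s <- summarizeDistances(distanceTable(seq_along(x),
                                              rep("LCC", length(x)), x))
        expect_equal(s[1, "lq"], quantile_inclusive(x, 0.25))
        expect_equal(s[1, "median"], quantile_inclusive(x, 0.5))
        expect_equal(s[1, "uq"], quantile_inclusive(x, 0.75))
    }
})

test_that("the pooled row aggregates all classes", {
    tab <- distanceTable(rep(paste0("c", 1:4), each = 5),
                         rep(c("LCC", "NCC", "RCC", "LCO", "RCO"), 4),
                         seq(0.1, 2, by = 0.1))
    s <- summarizeDistances(tab)
    expect_equal(s$class, c("LCC", "NCC", "RCC", "LCO", "RCO", "All"))
    expect_equal(s[s$class == "All", "n"], 20)
    expect_equal(s[s$class == "All", "median"], median(seq(0.1, 2, 0.1)))
})

test_that("paired difference statistics handle degenerate and shifted data", {
    d <- c(1.2, 0.8, 1.5, 2.1, 0.4, 1.0)
    same <- pairedDifferenceTest(d, d)
    expect_equal(same$mean, 0)
    expect_equal(same$sd, 0)
    expect_equal(same$p, 1)

    shifted <- pairedDifferenceTest(d + 1, d)
    expect_equal(shifted$mean, 1)
    expect_equal(shifted$sd, 0)
    expect_lt(shifted$p, 0.05)
    expect_error(pairedDifferenceTest(d, d[-1]), "equal length")
    expect_error(pairedDifferenceTest(1:3, 1:3), "at least 5")
})

test_that("Wilcoxon p-values match exact sign-assignment enumeration", {
    cases <- list(c(0.3, -0.2, 0.8, 1.1, -0.6, 0.4),
                  c(1.5, 2.2, -0.7, 0.9, 1.8, -1.1, 0.25),
                  c(0.1, 0.2, 0.35, -0.5, 0.7, 1.3, -1.9, 2.4))
    for (d in cases) {
        got <- pairedDifferenceTest(d, rep(0, length(d)))$p
        expect_equal(got, wilcoxon_exact_p(d), tolerance = 1e-12)
    }
})

test_that("Bland-Altman bias and limits follow the closed form", {
    a <- c(10, 12, 14, 9)
    expect_equal(blandAltman(a, a)$bias, 0)
    expect_equal(blandAltman(a, a)$loaLower, 0)
    expect_equal(blandAltman(a, a)$loaUpper, 0)

    ba <- blandAltman(c(1, -1), c(0, 0))
    expect_equal(ba$bias, 0)
    expect_equal(ba$sd, sqrt(2))
    expect_equal(ba$loaUpper, 1.96 * sqrt(2))
    expect_equal(ba$loaLower, -1.96 * sqrt(2))

    set.seed(3)
    x <- rnorm(30, 5); y <- rnorm(30, 4)
    expect_equal(blandAltman(x, y)$bias, mean(x) - mean(y))
})

test_that("r-squared detects perfect, absent and affine-invariant relations", {
    set.seed(9)
    a <- rnorm(40)
    expect_equal(correlationR2(a, 2 * a + 3), 1)
    b <- rnorm(40)
    resid <- residuals(lm(b ~ a))
    expect_lt(correlationR2(a, resid), 1e-12)
    expect_equal(correlationR2(a, b), correlationR2(5 * a - 2, 0.1 * b + 7),
                 tolerance = 1e-12)
    expect_error(correlationR2(a, rep(1, 40)), "variance")
})
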