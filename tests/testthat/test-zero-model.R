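test_that("zero statistics match hand-derived values", {
    m <- rbind(a = c(0, 0, 1, 1),
               b = c(0, 0, 0, 0),
               c = c(0, 0, 0, 10))
    s <- geneZeroStats(m)

    expect_equal(s$mean, c(0.5, 0, 2.5))
    expect_equal(s$zero_prop, c(0.5, 1, 0.75))
    expect_equal(s$expected_zero, exp(-c(0.5, 0, 2.5)))
    # z = (p_hat - exp(-mean)) / sqrt(p_hat (1 - p_hat) / C)
    expect_equal(s$z[1], (0.5 - exp(-0.5)) / sqrt(0.25 / 4))
    expect_equal(s$z[1], -0.42612, tolerance = 1e-4)
    expect_equal(s$z[3], (0.75 - exp(-2.5)) / sqrt(0.75 * 0.25 / 4))
    expect_equal(s$z[3], 3.0850, tolerance = 1e-4)
    # degenerate conventions: all-zero gene and no-zero gene get z = 0
    expect_equal(s$z[2], 0)
    expect_equal(geneZeroStats(rbind(x = c(1, 2, 3)))$z, 0)

    # Table-style magnitude: a gene mean of 25.89 leaves essentially no
    # Poisson zeros
    expect_equal(exp(-25.89), 5.69e-12, tolerance = 0.015)
})

test_that("the null-variance standard error option changes only the scale", {
    m <- rbind(a = c(0, 0, 1, 1))
    sSample <- geneZeroStats(m, se = "sample")
    sNull <- geneZeroStats(m, se = "null")
    ez <- exp(-0.5)
    expect_equal(sNull$z, (0.5 - ez) / sqrt(ez * (1 - ez) / 4))
    expect_equal(sign(sNull$z), sign(sSample$z))
})

test_that("deviance equals the saturated-minus-fitted Poisson gap", {
    expect_equal(devianceStatistic(c(2, 2, 2)), 0)
    expect_equal(devianceStatistic(c(0, 0, 0)), 0)
    expect_equal(devianceStatistic(c(0, 4)),
        2 * ((0 - (0 - 2)) + (4 * log(2) - 2)))
    expect_equal(devianceStatistic(c(0, 4)), 5.54518, tolerance = 1e-5)

    set.seed(5)
    for (i in 1:25) {
        x <- rpois(sample(3:40, 1), runif(1, 0.1, 8))
        sat <- sum(dpois(x, x, log = TRUE))
        fit <- fitPoisson(x)@loglik
        expect_equal(devianceStatistic(x), 2 * (sat - fit),
            tolerance = 1e-10)
        # matrix path agrees with the scalar path
        expect_equal(geneZeroStats(matrix(x, 1))$deviance,
            devianceStatistic(x), tolerance = 1e-10)
    }
})

test_that("feature selection is strict, ordered, and method-aware", {
    stats <- S4Vectors::DataFrame(z = c(3.1, 0.5, 2.0, -4.0),
        deviance = c(10, 3, 0.1, 0))
    expect_identical(selectFeatures(stats, zThreshold = 2), 1L)
    expect_identical(selectFeatures(stats, zThreshold = 10), integer())
    expect_identical(
        selectFeatures(stats, method = "deviance", devianceThreshold = 1),
        c(1L, 2L))
    expect_error(selectFeatures(stats, method = "deviance"), "required")
})

test_that("closed-form zero probabilities follow the model catalogue", {
    expect_equal(expectedZero("poisson", lambda = 0.5625), 0.57,
        tolerance = 0.015)
    expect_equal(expectedZero("nb", lambda = 1, r = 1), 0.5)
    expect_equal(expectedZero("nb", lambda = 3, r = Inf), exp(-3))
    expect_equal(
        expectedZero("zinb", lambda = 5, r = 2, pi0 = 0.3),
        0.3 + 0.7 * (2 / 7)^2)
    mix <- expectedZero("mixture", weights = c(0.5, 0.5), lambdas = c(0, 2))
    expect_equal(mix, 0.5 * (1 + exp(-2)))
    expect_gt(mix, exp(-1))  # Jensen: mixture zeros exceed the pooled Poisson
    expect_error(expectedZero("mixture", weights = c(0.7, 0.5),
        lambdas = c(1, 2)), "sum to 1")
})

test_that("Jensen's inequality holds across random mixtures", {
    set.seed(42)
    for (i in 1:500) {
        k <- sample(2:5, 1)
        w <- runif(k); w <- w / sum(w)
        lam <- exp(runif(k, log(0.01), log(30)))
        expect_gte(expectedZero("mixture", weights = w, lambdas = lam),
            expectedZero("poisson", lambda = sum(w * lam)) - 1e-12)
    }
    # equality iff all component means coincide
    expect_equal(expectedZero("mixture", weights = c(0.3, 0.7),
        lambdas = c(2, 2)), exp(-2))
})

test_that("model variances follow the comparison table", {
    expect_equal(modelVariance("mixture", weights = c(0.5, 0.5),
        lambdas = c(1, 3)), 0.5 * 2 + 0.5 * 12 - 4)
    expect_equal(modelVariance("nb", lambda = 4, r = Inf), 4)
    expect_equal(modelVariance("nb", lambda = 5, r = 2), 17.5)
    expect_equal(modelVariance("zinb", lambda = 5, r = 2, pi0 = 0),
        modelVariance("nb", lambda = 5, r = 2))
    # the ZINB form can dip below the null variance lambda
    expect_lt(modelVariance("zinb", lambda = 2, r = 1e6, pi0 = 0.5), 2)
})

test_that("expected Poisson zero proportion decreases in the gene mean", {
    mu <- sort(exp(runif(50, log(0.01), log(30))))
    ez <- vapply(mu, function(l) expectedZero("poisson", lambda = l),
        numeric(1))
    expect_true(all(diff(ez) < 0))
    expect_true(all(ez > 0 & ez <= 1))
})

test_that("the z test retains almost all genes under a homogeneous null", {
    m <- homogeneousPoisson(nGenes = 600, nCells = 600, seed = 99)
    s <- geneZeroStats(m)
    expect_gte(mean(abs(s$z) < 2), 0.95)
    # one-sided rejections at z > 2 stay within the nominal 5%
    expect_lte(mean(s$z > 2), 0.05)
})

test_that("zero statistics export writes the documented columns", {
    d <- withr::local_tempdir()
    s <- geneZeroStats(rbind(a = c(0, 1, 2), b = c(0, 0, 3)))
    p <- writeZeroStats(s, file.path(d, "stats.tsv"))
    back <- read.delim(p)
    expect_identical(colnames(back),
        c("gene_id", "n_cells", "mean", "zero_prop", "expected_zero",
          "z", "deviance", "p_value", "p_bonferroni"))
    expect_equal(back$expected_zero, exp(-back$mean))
})
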