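test_that("mixture spec validation enforces the ground-truth contract", {
    expect_error(MixtureSpec(c(10, 10), rbind(c(1, 2), c(1, 1))),
        "share one rate")
    expect_error(MixtureSpec(10, matrix(-1, 1, 1)), "nonnegative")
    spec <- MixtureSpec(c(10, 20), rbind(c(1, 2), c(1, 1)),
        heterogeneousGenes = 1L)
    expect_s4_class(spec, "MixtureSpec")
})

test_that("Poisson mixture draws reproduce their generative moments", {
    # single cluster: observed zero fraction within 3 binomial SEs of e^-1
    spec <- MixtureSpec(10000, matrix(1, 1, 1), seed = 71)
    sce <- simulatePoissonMixture(spec)
    zp <- mean(assay(sce)[1, ] == 0)
    se <- sqrt(exp(-1) * (1 - exp(-1)) / 10000)
    expect_lt(abs(zp - exp(-1)), 3 * se)

    # all-zero rates give an all-zero matrix
    z <- simulatePoissonMixture(MixtureSpec(c(5, 5), matrix(0, 3, 2)))
    expect_equal(sum(assay(z)), 0)

    # a (0, 5) gene at equal weights shows the Jensen zero excess and a
    # z statistic far beyond the selection cutoff
    spec2 <- MixtureSpec(c(500, 500), rbind(c(0, 5), c(1, 1)),
        heterogeneousGenes = 1L, seed = 72)
    sce2 <- simulatePoissonMixture(spec2)
    s <- geneZeroStats(sce2)
    expect_equal(s$zero_prop[1], 0.5 * (1 + exp(-5)), tolerance = 0.05)
    expect_gt(s$zero_prop[1], exp(-2.5))
    expect_gt(s$z[1], 2)
})

test_that("mixture output is deterministic given the spec seed", {
    spec <- defaultMixtureSpec(seed = 10, nGenes = 300,
        cellsPerCluster = 50)
    a <- simulatePoissonMixture(spec)
    b <- simulatePoissonMixture(spec)
    expect_identical(as.matrix(assay(a)), as.matrix(assay(b)))
    expect_identical(a$true_label, b$true_label)
})

test_that("gamma-Poisson sampling matches NB mean and variance", {
    x <- simulateNB(50000, lambda = 5, r = 2, seed = 73)
    expect_equal(mean(x), 5, tolerance = 0.05)
    expect_equal(var(x), 17.5, tolerance = 0.05 * 17.5)

    # near-Poisson limit: variance/mean ratio close to 1
    y <- simulateNB(50000, lambda = 3, r = 1e9, seed = 74)
    expect_equal(var(y) / mean(y), 1, tolerance = 0.05)

    expect_equal(simulateNB(100, lambda = 0, r = 2), integer(100))
})

test_that("structural zeros land at the ZINB zero fraction", {
    x <- simulateZINB(50000, lambda = 5, r = 2, pi0 = 0.3, seed = 75)
    target <- 0.3 + 0.7 * (2 / 7)^2
    se <- sqrt(target * (1 - target) / 50000)
    expect_lt(abs(mean(x == 0) - target), 3 * se)

    # pi0 = 0 is byte-identical to the plain NB draw at the same seed
    expect_identical(simulateZINB(1000, 4, 2, 0, seed = 76),
        simulateNB(1000, 4, 2, seed = 76))
    expect_error(simulateZINB(10, 1, 1, 1), "pi0")
})

test_that("per-gene mixture variance matches the closed form", {
    spec <- MixtureSpec(c(3000, 3000), rbind(c(1, 3), c(0.5, 4)),
        heterogeneousGenes = c(1L, 2L), seed = 77)
    sce <- simulatePoissonMixture(spec)
    m <- as.matrix(assay(sce))
    for (g in 1:2) {
        v <- modelVariance("mixture", weights = c(0.5, 0.5),
            lambdas = spec@rates[g, ])
        expect_equal(var(m[g, ]), v, tolerance = 0.1 * v)
    }
})

test_that("null calibration holds on simulated homogeneous output", {
    spec <- MixtureSpec(600, matrix(exp(runif(400, log(0.05), log(20)))),
        seed = 78)
    s <- geneZeroStats(simulatePoissonMixture(spec))
    expect_gte(mean(abs(s$z) < 2), 0.95)
})

test_that("strongly heterogeneous genes are detected with high power", {
    set.seed(79)
    hits <- vapply(1:10, function(s) {
        lamLow <- runif(1, 0.3, 0.8)
        spec <- MixtureSpec(c(300, 300),
            rbind(c(lamLow, 5 * lamLow), c(0.5, 0.5)),
            heterogeneousGenes = 1L, seed = 1000 + s)
        geneZeroStats(simulatePoissonMixture(spec))$z[1] > 2
    }, logical(1))
    expect_gte(mean(hits), 0.95)
})

test_that("simulation fixtures round-trip through the readers", {
    d <- withr::local_tempdir()
    spec <- defaultMixtureSpec(seed = 12, nGenes = 120,
        cellsPerCluster = 25)
    sce <- simulatePoissonMixture(spec)
    writeSimulation(sce, d)
    back <- readUmiMtx(file.path(d, "matrix.mtx"),
        file.path(d, "genes.tsv"), file.path(d, "barcodes.tsv"))
    expect_equal(as.matrix(assay(back)), as.matrix(assay(sce)))
    lab <- readCellLabels(file.path(d, "labels.tsv"))
    expect_identical(lab$label, sce$true_label)
})
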