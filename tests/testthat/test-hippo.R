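test_that("log transform + standardization matches the documented scaling", {
    # a zero count maps to log(1 + 0) = 0 before standardization
    m <- rbind(f1 = c(0, exp(1) - 1), f2 = c(3, 3))
    z <- logTransformStandardize(m)
    expect_equal(dim(z), c(2L, 2L))      # cells x features
    # column (0, 1) after log1p centers and scales to +/- 0.70711
    expect_equal(z[, 1], c(-0.70711, 0.70711), tolerance = 1e-5,
        ignore_attr = TRUE)
    # constant feature: centered, left unscaled -> all zero
    expect_equal(unname(z[, 2]), c(0, 0))
})

test_that("PCA + K-means splits separated groups and is deterministic", {
    set.seed(17)
    counts <- cbind(
        matrix(rpois(40 * 50, 0.2), 40, 50),
        matrix(rpois(40 * 50, 6), 40, 50))
    z <- logTransformStandardize(counts)
    lab <- pcaKmeansSplit(z, nPc = 10, restarts = 10, seed = 4)
    truth <- rep(0:1, each = 50)
    expect_equal(ari(lab, truth), 1)
    expect_identical(lab, pcaKmeansSplit(z, nPc = 10, restarts = 10,
        seed = 4))
    expect_true(all(tabulate(lab + 1L, 2L) > 0))

    # duplicated single cell pattern cannot be split
    same <- matrix(1, 5, 6)
    zs <- logTransformStandardize(same)
    expect_error(pcaKmeansSplit(zs, seed = 1), class = "degenerateSplitError")
})

test_that("intra-cluster variation matches an eigendecomposition oracle", {
    set.seed(23)
    m <- matrix(rpois(20 * 10, 2), 10, 20)  # 10 genes x 20 cells
    expect_equal(intraClusterVariation(m, nPc = 5),
        uncenteredVariationOracle(m, 5), tolerance = 1e-8)
    expect_equal(intraClusterVariation(m, nPc = 50),
        uncenteredVariationOracle(m, 50), tolerance = 1e-8)
    # degenerate clusters carry no variation
    expect_equal(intraClusterVariation(matrix(3, 4, 6)), 0)
    expect_equal(intraClusterVariation(matrix(2, 5, 1)), 0)
})

test_that("clustering recovers a well-separated three-type mixture", {
    sim <- simulatePoissonMixture(defaultMixtureSpec(seed = 2))
    res <- hippo(sim, K = 3, seed = 2)
    expect_identical(stopReason(res), "reached_K")
    expect_equal(nClusters(res), 3L)
    expect_gte(ari(finalLabels(res), sim$true_label), 0.95)
})

test_that("rounds refine labels monotonically and shrink candidate features", {
    sim <- simulatePoissonMixture(defaultMixtureSpec(seed = 13,
        nClusters = 4, cellsPerCluster = 150, nGenes = 1000))
    res <- hippo(sim, K = 4, seed = 13)
    rs <- hippoRounds(res)
    expect_gt(length(rs), 1L)
    for (t in seq_along(rs)) {
        labT <- rs[[t]]$labelsAfter
        expect_equal(length(unique(labT)), t + 1L)
        if (t > 1L) {
            labPrev <- rs[[t - 1L]]$labelsAfter
            # refinement: cells sharing a label now shared one before
            agree <- tapply(labPrev, labT, function(v) length(unique(v)))
            expect_true(all(agree == 1L))
        }
    }
    # a child's selection is drawn from its parent round's features
    parents <- vapply(rs, `[[`, integer(1), "parentCluster")
    for (t in seq_along(rs)[-1]) {
        creator <- max(which(parents[seq_len(t - 1L)] == parents[t]), 0L)
        if (creator > 0L)
            expect_true(all(rs[[t]]$selectedFeatures %in%
                rs[[creator]]$selectedFeatures))
    }
})

test_that("clustering is reproducible under a fixed seed", {
    sim <- simulatePoissonMixture(defaultMixtureSpec(seed = 5,
        nGenes = 600, cellsPerCluster = 100))
    a <- hippo(sim, K = 3, seed = 9)
    b <- hippo(sim, K = 3, seed = 9)
    expect_identical(finalLabels(a), finalLabels(b))
    expect_identical(hippoRounds(a), hippoRounds(b))
})

test_that("K = 1 runs no rounds and leaves one cluster", {
    m <- matrix(rpois(200, 1), 20, 10)
    res <- hippo(m, K = 1)
    expect_length(hippoRounds(res), 0)
    expect_equal(unname(unique(finalLabels(res))), 0L)
})

test_that("the stop rule allows exactly G * o inflated genes", {
    # 30,000 genes at o = 0.01 permit 300; a round with 299 halts
    expect_equal(30000 * 0.01, 300)
    expect_true(299 < 30000 * 0.01)
    expect_false(300 < 30000 * 0.01)
})

test_that("homogeneous data stop before any split", {
    stops <- vapply(1:8, function(s) {
        m <- homogeneousPoisson(nGenes = 500, nCells = 300, seed = 100 + s)
        res <- hippo(m, K = 5, seed = s)
        stopReason(res) == "too_few_inflated_genes" &&
            length(hippoRounds(res)) == 0L
    }, logical(1))
    expect_gte(mean(stops), 0.9)
})

test_that("result export writes labels, features and a manifest", {
    d <- withr::local_tempdir()
    sim <- simulatePoissonMixture(defaultMixtureSpec(seed = 4,
        nGenes = 500, cellsPerCluster = 80))
    res <- hippo(sim, K = 3, seed = 4)
    writeHippoResult(res, d, geneIds = rownames(sim))
    lab <- read.delim(file.path(d, "labels.tsv"))
    expect_equal(nrow(lab), ncol(sim))
    expect_true("label_final" %in% colnames(lab))
    man <- jsonlite::read_json(file.path(d, "manifest.json"))
    expect_identical(man$summary$stop_reason, stopReason(res))
    feats <- read.delim(file.path(d, "features.tsv"))
    expect_true(all(feats$round %in% seq_along(hippoRounds(res))))
})
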