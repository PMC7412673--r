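#' Construct a finite Poisson mixture specification
#'
#' @param nCellsPerCluster integer vector of cells per cluster; the implied
#'   mixing weights are `nCellsPerCluster / sum(nCellsPerCluster)`.
#' @param rates genes x clusters matrix of nonnegative Poisson rates.
#' @param heterogeneousGenes indices of genes whose rates differ across
#'   clusters (every other gene must have one shared rate).
#' @param seed integer seed for count generation.
#' @return a validated [MixtureSpec-class].
#' @seealso [defaultMixtureSpec()] for the standard test-bench spec.
#' @export
MixtureSpec <- function(nCellsPerCluster, rates, heterogeneousGenes = integer(),
                        seed = 1) {
    methods::new("MixtureSpec",
        nCellsPerCluster = as.integer(nCellsPerCluster),
        rates = as.matrix(rates),
        heterogeneousGenes = as.integer(heterogeneousGenes),
        seed = as.integer(seed))
}

#' Default mixed-cell-type simulation spec
#'
#' Emulates a low-UMI droplet experiment with a few transcriptionally
#' distinct cell types: `nClusters` clusters of `cellsPerCluster` cells,
#' `nGenes` genes of which a fraction `hetFraction` differ across clusters.
#' Heterogeneous genes draw one rate per cluster log-uniformly from
#' `hetRange` (UMI counts/cell); the remaining genes share one rate drawn
#' log-uniformly from `sharedRange`, the regime where most genes are lowly
#' expressed and zeros are abundant.
#'
#' @param seed integer seed (drives both the rate draw and, through the
#'   spec, the count draw).
#' @param nClusters number of cell types (default 3).
#' @param cellsPerCluster cells in each cluster (default 300).
#' @param nGenes total genes (default 2000).
#' @param hetFraction fraction of heterogeneous genes (default 0.05).
#' @param hetRange,sharedRange rate ranges (defaults `[0.5, 8]` and
#'   `[0.05, 2]`).
#' @return a [MixtureSpec-class].
#' @examples
#' defaultMixtureSpec(seed = 1, nGenes = 100, cellsPerCluster = 20)
#' @export
defaultMixtureSpec <- function(seed = 1, nClusters = 3, cellsPerCluster = 300,
                               nGenes = 2000, hetFraction = 0.05,
                               hetRange = c(0.5, 8),
                               sharedRange = c(0.05, 2)) {
    set.seed(.childSeed(seed, 1L))
    nHet <- round(hetFraction * nGenes)
    het <- sort(sample.int(nGenes, nHet))
    shared <- exp(stats::runif(nGenes, log(sharedRange[1]),
        log(sharedRange[2])))
    rates <- matrix(shared, nGenes, nClusters)
    rates[het, ] <- exp(stats::runif(nHet * nClusters, log(hetRange[1]),
        log(hetRange[2])))
    MixtureSpec(rep(cellsPerCluster, nClusters), rates, het, seed = seed)
}

#' Simulate counts from a finite Poisson mixture of cell types
#'
#' Cell `c` of cluster `k` draws `X[g, c] ~ Poisson(rates[g, k])`
#' independently. Deterministic given the spec's seed.
#'
#' @param spec a [MixtureSpec-class].
#' @return a `SingleCellExperiment` with assay `"counts"`,
#'   `colData$true_label` holding the 0-based ground-truth cluster of each
#'   cell, and `rowData$heterogeneous` flagging the genes whose rates vary.
#' @export
simulatePoissonMixture <- function(spec) {
    methods::validObject(spec)
    set.seed(.childSeed(spec@seed, 2L))
    G <- nrow(spec@rates)
    blocks <- lapply(seq_along(spec@nCellsPerCluster), function(k) {
        nk <- spec@nCellsPerCluster[k]
        matrix(stats::rpois(G * nk, spec@rates[, k]), nrow = G)
    })
    counts <- do.call(cbind, blocks)
    sce <- umiExperiment(counts)
    sce$true_label <- rep(seq_along(spec@nCellsPerCluster) - 1L,
        spec@nCellsPerCluster)
    SummarizedExperiment::rowData(sce)$heterogeneous <-
        seq_len(G) %in% spec@heterogeneousGenes
    S4Vectors::metadata(sce)$mixture_spec <- spec
    sce
}

#' Simulate negative binomial counts via the Gamma-Poisson construction
#'
#' Each cell's rate is drawn from a Gamma with shape `r` and mean `lambda`,
#' then a Poisson count is drawn at that rate; marginally the counts are
#' NB with mean `lambda` and variance `lambda^2 / r + lambda`. Sampling
#' through the hierarchy (rather than a direct NB sampler) exercises the
#' continuous-mixture construction itself.
#'
#' @param nCells number of draws.
#' @param lambda mean (>= 0; 0 yields all zeros).
#' @param r dispersion (> 0); large `r` approaches Poisson.
#' @param seed optional integer seed.
#' @return integer vector of counts.
#' @export
simulateNB <- function(nCells, lambda, r, seed = NULL) {
    if (r <= 0) stop("r must be positive")
    if (lambda < 0) stop("lambda must be nonnegative")
    if (!is.null(seed)) set.seed(seed)
    if (lambda == 0) return(integer(nCells))
    rateper <- stats::rgamma(nCells, shape = r, rate = r / lambda)
    stats::rpois(nCells, rateper)
}

#' Simulate zero-inflated negative binomial counts
#'
#' Draws NB counts as in [simulateNB()], then replaces a `pi0` fraction of
#' cells (chosen independently) with structural zeros. With `pi0 = 0` the
#' output is identical to [simulateNB()] under the same seed.
#'
#' @inheritParams simulateNB
#' @param pi0 structural-zero probability in `[0, 1)`.
#' @return integer vector of counts.
#' @export
simulateZINB <- function(nCells, lambda, r, pi0, seed = NULL) {
    if (pi0 < 0 || pi0 >= 1) stop("pi0 must be in [0, 1)")
    if (!is.null(seed)) set.seed(seed)
    x <- simulateNB(nCells, lambda, r, seed = NULL)
    structural <- stats::runif(nCells) < pi0
    x[structural] <- 0L
    x
}

#' Write a simulated experiment as a round-trippable fixture
#'
#' Produces the MatrixMarket triplet read by [readUmiMtx()] plus
#' `labels.tsv` with the ground-truth cell labels.
#'
#' @param sce output of [simulatePoissonMixture()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
writeSimulation <- function(sce, dir) {
    paths <- writeUmiMtx(sce, dir)
    labPath <- file.path(dir, "labels.tsv")
    writeCellLabels(sce$true_label, labPath, cellIds = colnames(sce))
    invisible(c(paths, labPath))
}
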