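# File-level commands behind the command-line interface
# (inst/scripts/hippo-cli.R). Each reads standard input formats, runs one
# analysis, and writes its table(s) plus a JSON run manifest; manifests omit
# timestamps so deterministic runs are byte-reproducible.

# Dispatch on file type: a .mtx matrix needs its two annotation files,
# anything else is read as a dense delimited table.
.readCountsInput <- function(input, genes = NULL, barcodes = NULL,
                             delimiter = "\t", genesInRows = TRUE) {
    if (grepl("\\.mtx$", input)) {
        if (is.null(genes) || is.null(barcodes))
            stop("MatrixMarket input needs gene and barcode files")
        readUmiMtx(input, genes, barcodes)
    } else {
        readUmiDense(input, delimiter = delimiter,
            genesInRows = genesInRows)
    }
}

#' Command: per-gene zero statistics and feature selection
#'
#' Reads a count matrix, computes [geneZeroStats()], flags the features
#' passing the chosen selection rule, and writes the statistics TSV (with a
#' `selected` column) plus a manifest next to it.
#'
#' @param input count matrix path (`.mtx` or dense delimited text).
#' @param output output TSV path; the manifest is written to
#'   `<output>.manifest.json`.
#' @param genes,barcodes annotation paths (MatrixMarket input only).
#' @param method,zThreshold,devianceThreshold selection rule, as in
#'   [selectFeatures()].
#' @param minCellsExpressing optional gene filter applied before testing.
#' @return invisibly, the output path.
#' @export
runSelect <- function(input, output, genes = NULL, barcodes = NULL,
                      method = "zero_inflation", zThreshold = 2,
                      devianceThreshold = 300, minCellsExpressing = 0) {
    x <- .readCountsInput(input, genes, barcodes)
    if (minCellsExpressing > 0) x <- filterGenes(x, minCellsExpressing)
    stats <- geneZeroStats(x)
    sel <- selectFeatures(stats, method = method, zThreshold = zThreshold,
        devianceThreshold = devianceThreshold)
    tab <- as.data.frame(stats)
    tab$selected <- seq_len(nrow(tab)) %in% sel
    utils::write.table(tab, output, sep = "\t", quote = FALSE,
        row.names = FALSE)
    .writeManifest(paste0(output, ".manifest.json"), command = "select",
        config = list(method = method, zThreshold = zThreshold,
            devianceThreshold = devianceThreshold,
            minCellsExpressing = minCellsExpressing),
        inputs = list(matrix = input, genes = genes, barcodes = barcodes),
        seed = NULL,
        summary = list(n_genes = nrow(tab), n_selected = length(sel)))
    invisible(output)
}

#' Command: hierarchical heterogeneity clustering
#'
#' Runs [hippo()] and writes labels, per-round features and the manifest
#' via [writeHippoResult()].
#'
#' @inheritParams runSelect
#' @param outDir output directory.
#' @param ... arguments forwarded to [HippoConfig()] (e.g. `K`, `seed`,
#'   `zThreshold`).
#' @return invisibly, the [HippoResult-class].
#' @export
runCluster <- function(input, outDir, genes = NULL, barcodes = NULL, ...) {
    x <- .readCountsInput(input, genes, barcodes)
    res <- hippo(x, config = HippoConfig(...))
    writeHippoResult(res, outDir, geneIds = rownames(x))
    invisible(res)
}

#' Command: two-group differential expression
#'
#' @inheritParams runSelect
#' @param labels path to a two-column labels TSV.
#' @param cluster1,cluster2 the cluster ids to compare.
#' @param test `"lrt"` or `"t"` (feeds the Bonferroni column).
#' @return invisibly, the output path.
#' @export
runDE <- function(input, labels, output, cluster1, cluster2,
                  genes = NULL, barcodes = NULL, test = "lrt") {
    x <- .readCountsInput(input, genes, barcodes)
    lab <- readCellLabels(labels)
    if (!all(c(cluster1, cluster2) %in% lab$label))
        stop("cluster ids ", cluster1, " and ", cluster2,
            " must both occur in ", labels)
    de <- diffExp(x, lab, clusters = c(cluster1, cluster2), test = test)
    writeDETable(de, output)
    .writeManifest(paste0(output, ".manifest.json"), command = "de",
        config = list(cluster1 = cluster1, cluster2 = cluster2,
            test = test),
        inputs = list(matrix = input, labels = labels),
        seed = NULL,
        summary = list(n_genes = nrow(de),
            n_significant = sum(de$p_adj < 0.05)))
    invisible(output)
}

#' Command: simulate a mixed-cell-type fixture
#'
#' Generates counts from [defaultMixtureSpec()] parameters and writes the
#' MatrixMarket triplet, ground-truth labels, and a manifest echoing the
#' generative parameters (including the per-cluster rates of the
#' heterogeneous genes).
#'
#' @param outDir output directory.
#' @param seed integer seed.
#' @param nClusters,cellsPerCluster,nGenes,hetFraction see
#'   [defaultMixtureSpec()].
#' @return invisibly, the simulated `SingleCellExperiment`.
#' @export
runSimulate <- function(outDir, seed = 1, nClusters = 3,
                        cellsPerCluster = 300, nGenes = 2000,
                        hetFraction = 0.05) {
    spec <- defaultMixtureSpec(seed = seed, nClusters = nClusters,
        cellsPerCluster = cellsPerCluster, nGenes = nGenes,
        hetFraction = hetFraction)
    sce <- simulatePoissonMixture(spec)
    writeSimulation(sce, outDir)
    .writeManifest(file.path(outDir, "manifest.json"),
        command = "simulate",
        config = list(nClusters = nClusters,
            cellsPerCluster = cellsPerCluster, nGenes = nGenes,
            hetFraction = hetFraction),
        inputs = list(), seed = seed,
        summary = list(
            heterogeneous_genes = spec@heterogeneousGenes,
            heterogeneous_rates =
                spec@rates[spec@heterogeneousGenes, , drop = FALSE]))
    invisible(sce)
}

#' Command: per-gene count-model diagnostics
#'
#' Fits Poisson, NB and ZINB to every gene ([fitGeneModels()]) and writes
#' the fit/LRT table.
#'
#' @inheritParams runSelect
#' @return invisibly, the output path.
#' @export
runDiagnose <- function(input, output, genes = NULL, barcodes = NULL) {
    x <- .readCountsInput(input, genes, barcodes)
    tab <- fitGeneModels(x)
    utils::write.table(as.data.frame(tab), output, sep = "\t",
        quote = FALSE, row.names = FALSE)
    .writeManifest(paste0(output, ".manifest.json"), command = "diagnose",
        config = list(),
        inputs = list(matrix = input, genes = genes, barcodes = barcodes),
        seed = NULL,
        summary = list(n_genes = nrow(tab),
            n_overdispersed_05 = sum(tab$lrt_nb_p < 0.05)))
    invisible(output)
}
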