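# Fixtures are built in code at test time; nothing binary is stored.

suppressPackageStartupMessages({
    library(SummarizedExperiment)
    library(withr)
})

# Write a tiny MatrixMarket triplet + annotation files, returning the paths.
writeTinyMtx <- function(dir, entries, nrow, ncol,
                         genes = sprintf("g%d", seq_len(nrow)),
                         barcodes = sprintf("c%d", seq_len(ncol))) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    mtx <- file.path(dir, "matrix.mtx")
    header <- c("%%MatrixMarket matrix coordinate integer general",
        sprintf("%d %d %d", nrow, ncol, nrow(entries)))
    body <- apply(entries, 1L, function(e)
        sprintf("%d %d %s", e[1], e[2], format(e[3])))
    writeLines(c(header, body), mtx)
    writeLines(genes, file.path(dir, "genes.tsv"))
    writeLines(barcodes, file.path(dir, "barcodes.tsv"))
    list(matrix = mtx, genes = file.path(dir, "genes.tsv"),
        barcodes = file.path(dir, "barcodes.tsv"))
}

# Dense TSV fixture with gene ids in the first column, cell ids as header.
writeTinyDense <- function(path, m,
                           genes = sprintf("g%d", seq_len(nrow(m))),
                           cells = sprintf("c%d", seq_len(ncol(m)))) {
    df <- data.frame(gene = genes, m, check.names = FALSE)
    colnames(df) <- c("gene", cells)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    path
}

# Homogeneous Poisson matrix: every gene a single rate across all cells.
homogeneousPoisson <- function(nGenes, nCells, seed,
                               rateRange = c(0.05, 20)) {
    set.seed(seed)
    lambda <- exp(runif(nGenes, log(rateRange[1]), log(rateRange[2])))
    matrix(rpois(nGenes * nCells, lambda), nrow = nGenes,
        dimnames = list(sprintf("g%d", seq_len(nGenes)), NULL))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
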