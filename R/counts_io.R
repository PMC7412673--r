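#' Build a validated single-cell count container
#'
#' Wraps a genes x cells matrix of nonnegative integer UMI counts into a
#' [SingleCellExperiment::SingleCellExperiment] with assay `"counts"`.
#' Duplicate gene or cell identifiers are disambiguated by appending a
#' numeric suffix, with a warning: duplicates occur in real feature files and
#' silently collapsing them is worse.
#'
#' @param counts matrix or sparse Matrix of counts (genes in rows).
#' @param geneIds,cellIds identifiers; default to the dimnames of `counts` or
#'   generated `gene%05d` / `cell%05d` names.
#' @return a `SingleCellExperiment`.
#' @examples
#' umiExperiment(matrix(0:3, 2, 2))
#' @export
umiExperiment <- function(counts, geneIds = NULL, cellIds = NULL) {
    .checkCounts(counts)
    if (is.null(geneIds)) geneIds <- .geneIds(counts, counts)
    if (is.null(cellIds)) cellIds <- .cellIds(counts, counts)
    if (length(geneIds) != nrow(counts))
        stop("geneIds length (", length(geneIds),
            ") does not match row count (", nrow(counts), ")")
    if (length(cellIds) != ncol(counts))
        stop("cellIds length (", length(cellIds),
            ") does not match column count (", ncol(counts), ")")
    geneIds <- .dedupIds(as.character(geneIds), "gene")
    cellIds <- .dedupIds(as.character(cellIds), "cell")
    dimnames(counts) <- list(geneIds, cellIds)
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts))
}

.dedupIds <- function(ids, what) {
    if (anyDuplicated(ids)) {
        warning("duplicate ", what,
            " identifiers disambiguated with numeric suffixes")
        ids <- make.unique(ids, sep = "-")
    }
    ids
}

# Annotation files are either plain one-id-per-line text or 10x features.tsv
# with (id, name, type) columns; column 1 is the identifier either way.
.readIdColumn <- function(path) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
        colClasses = "character", quote = "", comment.char = "")
    tab[[1L]]
}

#' Read a 10x-style MatrixMarket count triplet
#'
#' Reads a MatrixMarket coordinate file plus its gene/feature and cell
#' barcode annotation files. Coordinates are 1-based in the file and become
#' 0-based internal row/column indices of the returned matrix. Real-valued
#' entries are accepted only when integral within `1e-9`, then cast.
#'
#' @param matrixPath path to the `.mtx` coordinate file.
#' @param genesPath path to the gene list (plain ids or 10x `features.tsv`).
#' @param barcodesPath path to the barcode list.
#' @return a `SingleCellExperiment` with a sparse `"counts"` assay.
#' @seealso [writeUmiMtx()] for the inverse, [readUmiDense()] for delimited
#'   text.
#' @export
readUmiMtx <- function(matrixPath, genesPath, barcodesPath) {
    m <- Matrix::readMM(matrixPath)
    genes <- .readIdColumn(genesPath)
    cells <- .readIdColumn(barcodesPath)
    if (nrow(m) != length(genes))
        stop("matrix has ", nrow(m), " rows but gene file has ",
            length(genes), " records")
    if (ncol(m) != length(cells))
        stop("matrix has ", ncol(m), " columns but barcode file has ",
            length(cells), " records")
    .checkCounts(m)
    m <- methods::as(
        methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
        "CsparseMatrix")
    m@x <- round(m@x)
    umiExperiment(m, genes, cells)
}

#' Write a count container as MatrixMarket plus annotation files
#'
#' @param x count container accepted by [umiExperiment()] or produced by the
#'   readers.
#' @param dir output directory, created if needed. Files written:
#'   `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @return invisibly, the three paths.
#' @export
writeUmiMtx <- function(x, dir) {
    m <- .countsMatrix(x)
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
    Matrix::writeMM(methods::as(methods::as(m, "sparseMatrix"),
        "CsparseMatrix"), paths[1])
    writeLines(.geneIds(x, m), paths[2])
    writeLines(.cellIds(x, m), paths[3])
    invisible(paths)
}

#' Read a dense delimited count table
#'
#' Expects a header row of cell identifiers and a first column of gene
#' identifiers (or the transpose when `genesInRows = FALSE`); the result is
#' always oriented genes x cells.
#'
#' @param path input file.
#' @param delimiter field separator (default tab).
#' @param genesInRows `TRUE` when rows are genes.
#' @return a `SingleCellExperiment`.
#' @export
readUmiDense <- function(path, delimiter = "\t", genesInRows = TRUE) {
    tab <- utils::read.table(path, sep = delimiter, header = TRUE,
        row.names = 1L, check.names = FALSE, quote = "",
        comment.char = "")
    m <- as.matrix(tab)
    if (!is.numeric(m)) stop("non-numeric entries in dense count table")
    if (!genesInRows) m <- t(m)
    .checkCounts(m)
    storage.mode(m) <- "double"
    m <- round(m)
    umiExperiment(m, rownames(m), colnames(m))
}

#' Keep genes expressed in a minimum number of cells
#'
#' A gene is kept when at least `minCellsExpressing` cells have a count
#' greater than zero. Gene order is preserved; the kept row indices of the
#' input are recorded in `metadata(x)$kept_genes`. A threshold larger than
#' the number of cells empties the result with a warning rather than an
#' error.
#'
#' @param x count container.
#' @param minCellsExpressing nonnegative integer threshold.
#' @return the filtered container.
#' @export
filterGenes <- function(x, minCellsExpressing) {
    if (minCellsExpressing < 0) stop("minCellsExpressing must be >= 0")
    m <- .countsMatrix(x)
    if (minCellsExpressing > ncol(m))
        warning("threshold exceeds the number of cells; no gene can pass")
    nExpr <- Matrix::rowSums(m > 0)
    keep <- which(unname(nExpr) >= minCellsExpressing)
    keep <- as.integer(keep)
    out <- umiExperiment(m[keep, , drop = FALSE],
        .geneIds(x, m)[keep], .cellIds(x, m))
    S4Vectors::metadata(out)$kept_genes <- keep
    out
}

#' Read and write two-column cell label files
#'
#' Labels are stored as a header-less two-column TSV (`cell_id`, integer
#' label). `readCellLabels` relabels to the contiguous set `{0, ..., k-1}`
#' preserving first-appearance order.
#'
#' @param path file path.
#' @return `readCellLabels`: a data.frame with columns `cell_id` and `label`.
#' @export
readCellLabels <- function(path) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
        col.names = c("cell_id", "label"),
        colClasses = c("character", "integer"))
    tab$label <- match(tab$label, unique(tab$label)) - 1L
    tab
}

#' @rdname readCellLabels
#' @param labels integer labels or a named vector; `cellIds` may be given
#'   separately.
#' @param cellIds cell identifiers, defaulting to `names(labels)`.
#' @export
writeCellLabels <- function(labels, path, cellIds = names(labels)) {
    if (is.null(cellIds))
        cellIds <- sprintf("cell%05d", seq_along(labels))
    utils::write.table(
        data.frame(cell_id = cellIds, label = as.integer(labels)),
        path, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE)
    invisible(path)
}
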