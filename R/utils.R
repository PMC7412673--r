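# Internal plumbing shared across modules.

# Extract the genes x cells count matrix from any supported container.
# Accepts a SummarizedExperiment/SingleCellExperiment (assay "counts", else
# the first assay), a base matrix, or a Matrix sparse matrix.
.countsMatrix <- function(x) {
    if (methods::is(x, "SummarizedExperiment")) {
        nm <- SummarizedExperiment::assayNames(x)
        a <- if ("counts" %in% nm) "counts" else 1L
        return(SummarizedExperiment::assay(x, a))
    }
    if (is.matrix(x) || methods::is(x, "Matrix")) return(x)
    stop("unsupported count container: ", class(x)[1])
}

.geneIds <- function(x, m = .countsMatrix(x)) {
    ids <- rownames(m)
    if (is.null(ids)) ids <- sprintf("gene%05d", seq_len(nrow(m)))
    ids
}

.cellIds <- function(x, m = .countsMatrix(x)) {
    ids <- colnames(m)
    if (is.null(ids)) ids <- sprintf("cell%05d", seq_len(ncol(m)))
    ids
}

# Validate nonnegative integral counts; real values within tol of an integer
# are accepted (some exporters write "5.0").
.checkCounts <- function(m, tol = 1e-9) {
    v <- if (methods::is(m, "sparseMatrix")) m@x else as.vector(m)
    if (any(is.na(v))) stop("counts contain missing values")
    if (any(v < 0)) stop("counts must be nonnegative")
    if (any(abs(v - round(v)) > tol))
        stop("counts must be integral (within ", tol, ")")
    invisible(TRUE)
}

# Deterministic child seed derived from a master seed; Lehmer-style step keeps
# the result a valid 32-bit integer so nested rounds never share a stream.
.childSeed <- function(seed, k) {
    as.integer((as.double(seed) %% 2147483647) * 48271 %% 2147483647 + k) %%
        2147483647L
}

# Condition signalled when a cluster cannot be split (identical cells).
.degenerateSplit <- function(msg) {
    stop(structure(
        class = c("degenerateSplitError", "error", "condition"),
        list(message = msg, call = sys.call(-1))
    ))
}

.configAsList <- function(config) {
    nm <- methods::slotNames(config)
    stats::setNames(lapply(nm, function(s) methods::slot(config, s)), nm)
}

# Run manifest: inputs are digested so a run can be audited; no timestamp so
# that repeated deterministic runs are byte-identical.
.writeManifest <- function(path, command, config, inputs, seed, summary) {
    digests <- lapply(inputs, function(p) {
        if (is.character(p) && length(p) == 1L && file.exists(p))
            unname(tools::md5sum(p)) else NULL
    })
    man <- list(
        command = command,
        version = as.character(utils::packageVersion("scHippo")),
        config = config,
        inputs = inputs,
        input_md5 = digests,
        seed = seed,
        summary = summary
    )
    jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
        digits = NA, null = "null")
    invisible(path)
}
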