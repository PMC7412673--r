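#' Two-group differential expression between clusters
#'
#' For each gene the two cell groups are modelled as Poisson with rates
#' \eqn{\lambda_1}, \eqn{\lambda_2} and both of the following are computed:
#'
#' * a two-sample test on means with Poisson plug-in variances,
#'   \eqn{t = (\bar X_1 - \bar X_2) / \sqrt{\bar X_1/|C_1| + \bar
#'   X_2/|C_2|}}, referred two-sided to the standard normal;
#' * the Poisson likelihood-ratio deviance
#'   \eqn{2(\ell_1(\hat\lambda_1) + \ell_2(\hat\lambda_2) -
#'   \ell(\hat\lambda))}, clamped at 0 and referred to the upper tail of
#'   \eqn{\chi^2_1}.
#'
#' Genes with both group means zero get statistic 0 and p-value 1. The
#' Bonferroni-adjusted column uses the p-values of the test chosen by
#' `test`, with family size equal to the number of genes.
#'
#' @param x count container.
#' @param labels integer cluster labels per cell (vector, or a data.frame
#'   from [readCellLabels()] matched to the container's cells by `cell_id`).
#' @param clusters the two cluster ids to compare; defaults to the two
#'   present when the labelling is binary.
#' @param test which p-value feeds the Bonferroni adjustment: `"lrt"`
#'   (default) or `"t"`.
#' @return a [S4Vectors::DataFrame] with columns `gene_id`, `n1`, `n2`,
#'   `mean1`, `mean2`, `mean_pooled`, `t_stat`, `t_p`, `lrt_stat`, `lrt_p`,
#'   `p_adj`, `log2fc` (shrunken by `eps = 1/C`, for reporting only).
#' @examples
#' m <- rbind(g1 = c(0, 0, 2, 2), g2 = c(1, 1, 1, 1))
#' diffExp(m, labels = c(0, 0, 1, 1))
#' @export
diffExp <- function(x, labels, clusters = NULL, test = c("lrt", "t")) {
    test <- match.arg(test)
    m <- .countsMatrix(x)
    cellIds <- .cellIds(x, m)
    if (is.data.frame(labels)) {
        idx <- match(cellIds, labels$cell_id)
        if (anyNA(idx)) stop("labels are missing some cells of the matrix")
        labels <- labels$label[idx]
    }
    if (length(labels) != ncol(m))
        stop("one label per cell is required")
    if (is.null(clusters)) {
        clusters <- sort(unique(labels))
        if (length(clusters) != 2L)
            stop("labels contain ", length(clusters),
                " clusters; supply the two ids to compare")
    }
    g1 <- which(labels == clusters[1L])
    g2 <- which(labels == clusters[2L])
    if (!length(g1) || !length(g2))
        stop("cluster ids ", paste(clusters, collapse = ", "),
            " must both be present in the labels")
    n1 <- length(g1)
    n2 <- length(g2)
    s1 <- as.numeric(Matrix::rowSums(m[, g1, drop = FALSE]))
    s2 <- as.numeric(Matrix::rowSums(m[, g2, drop = FALSE]))
    mu1 <- s1 / n1
    mu2 <- s2 / n2
    mu <- (s1 + s2) / (n1 + n2)

    den <- sqrt(mu1 / n1 + mu2 / n2)
    tStat <- ifelse(den == 0, 0, (mu1 - mu2) / den)
    tP <- ifelse(den == 0, 1, 2 * stats::pnorm(-abs(tStat)))

    # Poisson LRT deviance; the factorial terms cancel between the pooled
    # and split fits, and 0 * log(0) = 0 covers empty groups.
    xlogy <- function(s, lam) ifelse(s == 0, 0, s * log(lam))
    lrt <- pmax(0, 2 * (xlogy(s1, mu1) + xlogy(s2, mu2) -
        xlogy(s1 + s2, mu)))
    lrtP <- stats::pchisq(lrt, df = 1L, lower.tail = FALSE)

    chosen <- if (test == "lrt") lrtP else tP
    eps <- 1 / ncol(m)
    S4Vectors::DataFrame(
        gene_id = .geneIds(x, m),
        n1 = n1, n2 = n2,
        mean1 = mu1, mean2 = mu2, mean_pooled = mu,
        t_stat = tStat, t_p = tP,
        lrt_stat = lrt, lrt_p = lrtP,
        p_adj = bonferroniAdjust(chosen, nrow(m)),
        log2fc = log2((mu1 + eps) / (mu2 + eps)),
        row.names = .geneIds(x, m))
}

#' Bonferroni adjustment at an explicit family size
#'
#' Multiplies each p-value by `familySize` and caps at 1, so the family can
#' be larger than the vector actually passed (e.g. all genes tested, not
#' only those reported).
#'
#' @param p numeric p-values.
#' @param familySize number of tests in the family (>= `length(p)`).
#' @return adjusted p-values in `[0, 1]`.
#' @export
bonferroniAdjust <- function(p, familySize = length(p)) {
    if (familySize < length(p))
        stop("familySize must be at least length(p)")
    stats::p.adjust(p, method = "bonferroni", n = familySize)
}

#' Export a differential-expression table as TSV
#'
#' @param de output of [diffExp()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeDETable <- function(de, path) {
    utils::write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}
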