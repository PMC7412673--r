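#' Per-gene zero-proportion statistics and the zero-inflation z test
#'
#' For every gene the observed zero proportion \eqn{\hat p_g} is compared to
#' the proportion \eqn{e^{-\bar X_g}} expected if that gene's counts were
#' homogeneous Poisson with rate equal to the gene mean. The test statistic
#' is
#' \deqn{z_g = \frac{\hat p_g - e^{-\bar X_g}}
#'                  {\sqrt{\hat p_g (1 - \hat p_g) / C}}}
#' which is referred to a standard normal; the one-sided alternative is
#' excess zeros, the signature of a mixture of cell types. The gene mean is
#' treated as fixed. Degenerate zero proportions (\eqn{\hat p_g \in \{0,1\}})
#' make the standard error zero and such genes get `z = 0` by convention:
#' a gene with no zeros cannot be zero inflated, and a gene with only zeros
#' has mean 0 and a zero numerator.
#'
#' @param x count container (matrix, sparse Matrix, or
#'   SummarizedExperiment-like with a `"counts"` assay).
#' @param se `"sample"` (default) uses the plug-in standard error
#'   \eqn{\sqrt{\hat p(1-\hat p)/C}}; `"null"` uses the standard error
#'   implied by the Poisson null, \eqn{\sqrt{e^{-\bar X}(1-e^{-\bar X})/C}}.
#' @return a [S4Vectors::DataFrame] with one row per gene and columns
#'   `gene_id`, `n_cells`, `mean`, `zero_prop`, `expected_zero`, `z`,
#'   `deviance`, `p_value` (one-sided normal) and `p_bonferroni`
#'   (family size = number of genes).
#' @examples
#' m <- rbind(a = c(0, 0, 1, 1), b = c(0, 0, 0, 10))
#' geneZeroStats(m)
#' @seealso [selectFeatures()], [devianceStatistic()], [writeZeroStats()]
#' @export
geneZeroStats <- function(x, se = c("sample", "null")) {
    se <- match.arg(se)
    m <- .countsMatrix(x)
    if (nrow(m) < 1L || ncol(m) < 2L)
        stop("need at least 1 gene and 2 cells")
    C <- ncol(m)
    mu <- as.numeric(Matrix::rowMeans(m))
    zp <- 1 - as.numeric(Matrix::rowSums(m > 0)) / C
    ez <- exp(-mu)
    v <- if (se == "sample") zp * (1 - zp) else ez * (1 - ez)
    z <- (zp - ez) / sqrt(v / C)
    z[zp <= 0 | zp >= 1] <- 0
    dev <- .devianceRows(m, mu)
    p <- stats::pnorm(z, lower.tail = FALSE)
    S4Vectors::DataFrame(
        gene_id = .geneIds(x, m),
        n_cells = C,
        mean = mu,
        zero_prop = zp,
        expected_zero = ez,
        z = z,
        deviance = dev,
        p_value = p,
        p_bonferroni = pmin(1, p * nrow(m)),
        row.names = .geneIds(x, m)
    )
}

# Row-wise Poisson deviance; the linear term sums to zero against the row
# mean so only x * log(x / mean) contributes, with 0 log 0 = 0.
.devianceRows <- function(m, mu = as.numeric(Matrix::rowMeans(m))) {
    v <- as.matrix(m)
    ratio <- v / mu                       # recycles mu down rows (genes)
    term <- v * log(ratio)
    term[v == 0] <- 0
    d <- 2 * rowSums(term)
    pmax(d, 0)
}

#' Poisson deviance of a single gene's counts
#'
#' Twice the gap between the saturated and fitted Poisson log-likelihoods,
#' \deqn{d = 2 \sum_c \left( X_c \log(X_c / \bar X) - (X_c - \bar X)
#' \right),} with the convention \eqn{0 \log 0 = 0}. Zero iff all counts are
#' equal; an all-zero vector returns 0. Used as the alternative
#' feature-selection score for high-UMI data where zeros alone are
#' uninformative.
#'
#' @param counts nonnegative integer vector, length >= 2.
#' @return nonnegative scalar.
#' @examples
#' devianceStatistic(c(0, 4)) # 2 * (2 + 4 * log(2) - 2)
#' @export
devianceStatistic <- function(counts) {
    if (length(counts) < 2L) stop("need at least 2 cells")
    mu <- mean(counts)
    if (mu == 0) return(0)
    term <- ifelse(counts == 0, -(0 - mu),
        counts * log(counts / mu) - (counts - mu))
    max(0, 2 * sum(term))
}

#' Rank and select heterogeneity features
#'
#' Selects genes whose statistic strictly exceeds the threshold, returning
#' their indices in order of descending statistic. For the zero-inflation
#' method the statistic is the one-sided `z` (alternative: more zeros than
#' Poisson predicts); for the deviance method it is `d_g`.
#'
#' @param stats output of [geneZeroStats()].
#' @param method `"zero_inflation"` (default) or `"deviance"`.
#' @param zThreshold cutoff on `z` (default 2).
#' @param devianceThreshold cutoff on `deviance`; must be supplied for the
#'   deviance method.
#' @return integer vector of row indices into `stats` (possibly empty).
#' @export
selectFeatures <- function(stats, method = c("zero_inflation", "deviance"),
                           zThreshold = 2, devianceThreshold = NULL) {
    method <- match.arg(method)
    if (method == "zero_inflation") {
        val <- stats$z
        thr <- zThreshold
    } else {
        if (is.null(devianceThreshold))
            stop("devianceThreshold is required for the deviance method")
        val <- stats$deviance
        thr <- devianceThreshold
    }
    if (!is.finite(thr)) stop("selection threshold must be finite")
    idx <- which(val > thr)
    idx[order(val[idx], decreasing = TRUE)]
}

#' Closed-form zero probability under candidate count models
#'
#' Probability of a zero count under a homogeneous Poisson, a finite Poisson
#' mixture, a negative binomial (variance \eqn{\lambda^2/r + \lambda}), or a
#' zero-inflated negative binomial \eqn{\pi_0 \delta_0 + (1-\pi_0)
#' NB(\lambda, r)}. For any mixture the zero probability
#' \eqn{\sum_k \pi_k e^{-\lambda_k}} is at least \eqn{e^{-\sum_k \pi_k
#' \lambda_k}} (Jensen), which is why excess zeros flag heterogeneity.
#'
#' @param model one of `"poisson"`, `"nb"`, `"zinb"`, `"mixture"`.
#' @param lambda mean parameter (Poisson/NB/ZINB).
#' @param r NB dispersion; `Inf` gives the Poisson limit.
#' @param pi0 structural-zero weight for `"zinb"`.
#' @param weights,lambdas mixing weights (summing to 1 within `1e-9`) and
#'   component means for `"mixture"`.
#' @return zero probability in `[0, 1]`.
#' @examples
#' expectedZero("poisson", lambda = 0.5625)
#' expectedZero("mixture", weights = c(0.5, 0.5), lambdas = c(0, 2))
#' @export
expectedZero <- function(model = c("poisson", "nb", "zinb", "mixture"),
                         lambda = NULL, r = NULL, pi0 = NULL,
                         weights = NULL, lambdas = NULL) {
    model <- match.arg(model)
    nbZero <- function(lambda, r) {
        if (is.infinite(r)) return(exp(-lambda))
        if (r <= 0) stop("r must be positive")
        exp(r * (log(r) - log(r + lambda)))
    }
    switch(model,
        poisson = {
            if (is.null(lambda) || lambda < 0)
                stop("poisson requires lambda >= 0")
            exp(-lambda)
        },
        nb = {
            if (is.null(lambda) || is.null(r))
                stop("nb requires lambda and r")
            nbZero(lambda, r)
        },
        zinb = {
            if (is.null(lambda) || is.null(r) || is.null(pi0))
                stop("zinb requires lambda, r and pi0")
            if (pi0 < 0 || pi0 >= 1) stop("pi0 must be in [0, 1)")
            pi0 + (1 - pi0) * nbZero(lambda, r)
        },
        mixture = {
            if (is.null(weights) || is.null(lambdas) ||
                length(weights) != length(lambdas))
                stop("mixture requires weights and lambdas of equal length")
            if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
                stop("mixture weights must be nonnegative and sum to 1")
            if (any(lambdas < 0)) stop("lambdas must be nonnegative")
            sum(weights * exp(-lambdas))
        })
}

#' Count variance under candidate heterogeneity models
#'
#' Variance of the count distribution under each alternative model, in the
#' comparison form used to argue that high gene variance is a poor
#' heterogeneity indicator: mixture
#' \eqn{\sum_k \pi_k(\lambda_k + \lambda_k^2) - (\sum_k \pi_k \lambda_k)^2},
#' NB \eqn{\lambda^2/r + \lambda}, ZINB
#' \eqn{(1-\pi_0)^2 (\lambda^2/r + \lambda)} — the last can fall below the
#' null variance \eqn{\lambda}, so variance ranking can miss heterogeneous
#' genes. The null (homogeneous Poisson) variance is always `lambda`.
#'
#' @inheritParams expectedZero
#' @return variance (nonnegative scalar).
#' @export
modelVariance <- function(model = c("poisson", "nb", "zinb", "mixture"),
                          lambda = NULL, r = NULL, pi0 = NULL,
                          weights = NULL, lambdas = NULL) {
    model <- match.arg(model)
    nbVar <- function(lambda, r) {
        if (is.infinite(r)) return(lambda)
        if (r <= 0) stop("r must be positive")
        lambda^2 / r + lambda
    }
    switch(model,
        poisson = {
            if (is.null(lambda) || lambda < 0)
                stop("poisson requires lambda >= 0")
            lambda
        },
        nb = {
            if (is.null(lambda) || is.null(r))
                stop("nb requires lambda and r")
            nbVar(lambda, r)
        },
        zinb = {
            if (is.null(lambda) || is.null(r) || is.null(pi0))
                stop("zinb requires lambda, r and pi0")
            if (pi0 < 0 || pi0 >= 1) stop("pi0 must be in [0, 1)")
            (1 - pi0)^2 * nbVar(lambda, r)
        },
        mixture = {
            if (is.null(weights) || is.null(lambdas) ||
                length(weights) != length(lambdas))
                stop("mixture requires weights and lambdas of equal length")
            if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
                stop("mixture weights must be nonnegative and sum to 1")
            sum(weights * (lambdas + lambdas^2)) - sum(weights * lambdas)^2
        })
}

#' Export per-gene zero statistics as TSV
#'
#' Columns: `gene_id`, `n_cells`, `mean`, `zero_prop`, `expected_zero`, `z`,
#' `deviance`, `p_value`, `p_bonferroni`. The `mean` / `zero_prop` /
#' `expected_zero` triple doubles as the diagnostic export for plotting the
#' observed zero proportions against the Poisson curve \eqn{e^{-\bar X}}.
#'
#' @param stats output of [geneZeroStats()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeZeroStats <- function(stats, path) {
    utils::write.table(as.data.frame(stats), path, sep = "\t",
        quote = FALSE, row.names = FALSE)
    invisible(path)
}
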