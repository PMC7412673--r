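#' @import methods
#' @importFrom stats var sd prcomp kmeans optimize dpois dnbinom pchisq pnorm
#'   p.adjust rpois rgamma runif setNames
#' @importFrom utils read.table write.table packageVersion
NULL

#' Configuration for hierarchical heterogeneity clustering
#'
#' Holds every tunable of the iterative feature-selection + binary-split
#' procedure run by [hippo()].
#'
#' @slot K maximum number of clusters (>= 1); the algorithm stops once this
#'   many clusters exist.
#' @slot zThreshold zero-inflation z-score cutoff for feature selection
#'   (strict inequality; default 2).
#' @slot outlierProportion proportion `o` in `[0, 1)` of genes allowed to be
#'   zero inflated in a homogeneous population; a round selecting fewer than
#'   `G * o` features stops the algorithm (default 0.01).
#' @slot nPcCluster number of principal components fed to K-means (default 10,
#'   capped by matrix rank at run time).
#' @slot nPcVariation number of uncentered, unscaled principal components used
#'   for intra-cluster variability (default 10).
#' @slot kmRestarts number of K-means restarts; the solution with the lowest
#'   within-cluster sum of squares is kept (default 10).
#' @slot seed master seed; one child seed is derived per round so earlier
#'   rounds never reshuffle later rounds' randomness.
#' @slot featureMethod `"zero_inflation"` or `"deviance"`.
#' @slot devianceThreshold cutoff on the per-gene Poisson deviance, used only
#'   when `featureMethod == "deviance"`.
#' @slot inheritFeatures if `TRUE` (default) a child cluster's candidate genes
#'   are the features selected in the round that created it, re-tested within
#'   the child's cells; if `FALSE` every round re-tests all genes.
#' @slot splitCriterion `"uncentered_pca"` (default) scores clusters by the
#'   summed sample variance of their leading uncentered, unscaled PC
#'   embeddings; `"centroid_distance"` scores them by the mean Euclidean
#'   distance of cells from their centroid in the round's standardized
#'   feature space.
#'
#' @seealso [HippoConfig()] for the user-facing constructor.
#' @export
setClass("HippoConfig",
    representation(
        K = "integer",
        zThreshold = "numeric",
        outlierProportion = "numeric",
        nPcCluster = "integer",
        nPcVariation = "integer",
        kmRestarts = "integer",
        seed = "integer",
        featureMethod = "character",
        devianceThreshold = "numeric",
        inheritFeatures = "logical",
        splitCriterion = "character"
    ),
    prototype(
        K = 2L, zThreshold = 2, outlierProportion = 0.01,
        nPcCluster = 10L, nPcVariation = 10L, kmRestarts = 10L,
        seed = 1L, featureMethod = "zero_inflation",
        devianceThreshold = 300, inheritFeatures = TRUE,
        splitCriterion = "uncentered_pca"
    )
)

setValidity("HippoConfig", function(object) {
    msg <- character()
    if (length(object@K) != 1L || is.na(object@K) || object@K < 1L)
        msg <- c(msg, "K must be a single integer >= 1")
    if (!is.finite(object@zThreshold))
        msg <- c(msg, "zThreshold must be finite")
    if (!is.finite(object@devianceThreshold))
        msg <- c(msg, "devianceThreshold must be finite")
    if (object@outlierProportion < 0 || object@outlierProportion >= 1)
        msg <- c(msg, "outlierProportion must be in [0, 1)")
    if (object@nPcCluster < 1L || object@nPcVariation < 1L)
        msg <- c(msg, "numbers of principal components must be >= 1")
    if (object@kmRestarts < 1L)
        msg <- c(msg, "kmRestarts must be >= 1")
    if (!object@featureMethod %in% c("zero_inflation", "deviance"))
        msg <- c(msg, "featureMethod must be 'zero_inflation' or 'deviance'")
    if (!object@splitCriterion %in% c("uncentered_pca", "centroid_distance"))
        msg <- c(msg,
            "splitCriterion must be 'uncentered_pca' or 'centroid_distance'")
    if (length(msg)) msg else TRUE
})

#' Result of the hierarchical heterogeneity clustering
#'
#' An ordered audit trail of clustering rounds plus the final cell labels.
#' Each element of `rounds` is a list with entries `roundIndex`,
#' `parentCluster`, `selectedFeatures` (gene indices, descending statistic),
#' `nInflated`, `childLabels` (0 = child keeping the parent id, 1 = new
#' child, over the parent's cells), `intraVariation` (named vector over all
#' clusters after the split) and `labelsAfter` (full-length 0-based labels).
#'
#' @slot config the [HippoConfig-class] used.
#' @slot rounds list of per-round records (see Description).
#' @slot finalLabels integer 0-based cluster label per cell.
#' @slot cellIds character cell identifiers, parallel to `finalLabels`.
#' @slot stopReason `"reached_K"` or `"too_few_inflated_genes"`.
#'
#' @seealso [hippo()], [finalLabels()], [stopReason()], [hippoRounds()]
#' @export
setClass("HippoResult",
    representation(
        config = "HippoConfig",
        rounds = "list",
        finalLabels = "integer",
        cellIds = "character",
        stopReason = "character"
    )
)

setValidity("HippoResult", function(object) {
    msg <- character()
    if (length(object@rounds) > object@config@K - 1L)
        msg <- c(msg, "more rounds than K - 1")
    if (length(object@cellIds) != length(object@finalLabels))
        msg <- c(msg, "cellIds and finalLabels lengths differ")
    if (!object@stopReason %in% c("reached_K", "too_few_inflated_genes"))
        msg <- c(msg, "unknown stopReason")
    k <- length(object@rounds)
    if (k > 0L) {
        last <- object@rounds[[k]]$labelsAfter
        if (!identical(as.integer(last), object@finalLabels))
            msg <- c(msg, "finalLabels must equal labelsAfter of last round")
        nlab <- vapply(object@rounds,
            function(r) length(unique(r$labelsAfter)), integer(1))
        if (!identical(nlab, seq_len(k) + 1L))
            msg <- c(msg, "round t must have exactly t + 1 clusters")
    } else if (any(object@finalLabels != 0L)) {
        msg <- c(msg, "no rounds implies a single cluster labelled 0")
    }
    if (length(msg)) msg else TRUE
})

#' Maximum-likelihood fit of a count distribution to one gene
#'
#' @slot model `"poisson"`, `"nb"` or `"zinb"`.
#' @slot lambda mean parameter (for `zinb`, the mean of the NB component).
#' @slot r NB dispersion, parameterized so the variance is
#'   `lambda^2 / r + lambda`; `Inf` marks the Poisson boundary and `NA` means
#'   the parameter is absent from the model.
#' @slot pi0 structural-zero weight in `[0, 1)`; `NA` when absent.
#' @slot loglik maximized log-likelihood.
#' @slot nParams 1 (poisson), 2 (nb) or 3 (zinb).
#' @slot converged optimizer convergence flag.
#' @export
setClass("ModelFit",
    representation(
        model = "character", lambda = "numeric", r = "numeric",
        pi0 = "numeric", loglik = "numeric", nParams = "integer",
        converged = "logical"
    )
)

setValidity("ModelFit", function(object) {
    msg <- character()
    if (!object@model %in% c("poisson", "nb", "zinb"))
        msg <- c(msg, "model must be poisson, nb or zinb")
    if (object@model == "poisson" && (!is.na(object@r) || !is.na(object@pi0)))
        msg <- c(msg, "poisson fit must have r and pi0 absent (NA)")
    if (object@model == "nb" && !is.na(object@pi0))
        msg <- c(msg, "nb fit must have pi0 absent (NA)")
    if (!is.na(object@r) && !(object@r > 0))
        msg <- c(msg, "r must be positive when present")
    if (!is.na(object@pi0) && (object@pi0 < 0 || object@pi0 >= 1))
        msg <- c(msg, "pi0 must lie in [0, 1) when present")
    if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Likelihood-ratio test between two nested count-model fits
#'
#' @slot nullModel,altModel model names of the nested pair.
#' @slot stat `max(0, 2 * (loglik_alt - loglik_null))`.
#' @slot df degrees of freedom (1 for each single-parameter extension).
#' @slot pValue upper-tail chi-squared probability.
#' @export
setClass("LRTResult",
    representation(
        nullModel = "character", altModel = "character",
        stat = "numeric", df = "integer", pValue = "numeric"
    )
)

setValidity("LRTResult", function(object) {
    msg <- character()
    if (object@stat < 0) msg <- c(msg, "stat must be >= 0")
    if (object@pValue < 0 || object@pValue > 1)
        msg <- c(msg, "pValue must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Ground truth for a finite Poisson mixture of cell types
#'
#' Describes the generative model sampled by [simulatePoissonMixture()]:
#' cells fall into clusters with sizes `nCellsPerCluster` (implying mixing
#' weights `pi_k = n_k / C`) and cell `c` of cluster `k` draws
#' `X[g, c] ~ Poisson(rates[g, k])` independently.
#'
#' @slot nCellsPerCluster integer cells per cluster.
#' @slot rates genes x clusters matrix of nonnegative Poisson rates
#'   (UMI counts per cell).
#' @slot heterogeneousGenes indices of genes whose rates differ across
#'   clusters; all other genes must have identical rates in every cluster.
#' @slot seed integer seed governing count generation.
#'
#' @seealso [MixtureSpec()], [defaultMixtureSpec()]
#' @export
setClass("MixtureSpec",
    representation(
        nCellsPerCluster = "integer",
        rates = "matrix",
        heterogeneousGenes = "integer",
        seed = "integer"
    )
)

setValidity("MixtureSpec", function(object) {
    msg <- character()
    if (any(object@nCellsPerCluster < 1L))
        msg <- c(msg, "every cluster needs at least one cell")
    if (ncol(object@rates) != length(object@nCellsPerCluster))
        msg <- c(msg, "rates must have one column per cluster")
    if (any(object@rates < 0)) msg <- c(msg, "rates must be nonnegative")
    hom <- setdiff(seq_len(nrow(object@rates)), object@heterogeneousGenes)
    if (length(hom) && ncol(object@rates) > 1L) {
        spread <- apply(object@rates[hom, , drop = FALSE], 1L,
            function(x) diff(range(x)))
        if (any(spread > 0))
            msg <- c(msg,
                "genes outside heterogeneousGenes must share one rate")
    }
    if (any(object@heterogeneousGenes < 1L) ||
        any(object@heterogeneousGenes > nrow(object@rates)))
        msg <- c(msg, "heterogeneousGenes out of range")
    if (length(msg)) msg else TRUE
})
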