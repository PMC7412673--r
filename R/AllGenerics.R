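#' Accessors for clustering results and model fits
#'
#' `finalLabels()` returns the 0-based cluster assignment per cell,
#' `stopReason()` the termination cause, `hippoRounds()` the per-round audit
#' records, and `nClusters()` the number of clusters in the final labelling.
#'
#' @param object a [HippoResult-class].
#' @return `finalLabels`: named integer vector; `stopReason`: character;
#'   `hippoRounds`: list; `nClusters`: integer.
#' @examples
#' sim <- simulatePoissonMixture(defaultMixtureSpec(seed = 1, nGenes = 200,
#'     cellsPerCluster = 40))
#' res <- hippo(sim, K = 2, seed = 1)
#' table(finalLabels(res))
#' stopReason(res)
#' @name HippoResult-accessors
NULL

#' @rdname HippoResult-accessors
#' @export
setGeneric("finalLabels", function(object) standardGeneric("finalLabels"))

#' @rdname HippoResult-accessors
#' @export
setGeneric("stopReason", function(object) standardGeneric("stopReason"))

#' @rdname HippoResult-accessors
#' @export
setGeneric("hippoRounds", function(object) standardGeneric("hippoRounds"))

#' @rdname HippoResult-accessors
#' @export
setGeneric("nClusters", function(object) standardGeneric("nClusters"))

#' @rdname HippoResult-accessors
setMethod("finalLabels", "HippoResult", function(object)
    setNames(object@finalLabels, object@cellIds))

#' @rdname HippoResult-accessors
setMethod("stopReason", "HippoResult", function(object) object@stopReason)

#' @rdname HippoResult-accessors
setMethod("hippoRounds", "HippoResult", function(object) object@rounds)

#' @rdname HippoResult-accessors
setMethod("nClusters", "HippoResult", function(object)
    length(unique(object@finalLabels)))

#' @describeIn ModelFit-class maximized log-likelihood with `df` attribute.
#' @param object a `ModelFit`.
#' @export
setMethod("logLik", "ModelFit", function(object) {
    structure(object@loglik, df = object@nParams, class = "logLik")
})

setMethod("show", "HippoConfig", function(object) {
    cat("HippoConfig: K =", object@K,
        "| feature =", object@featureMethod,
        "| threshold =",
        if (object@featureMethod == "zero_inflation") object@zThreshold
        else object@devianceThreshold,
        "| o =", object@outlierProportion,
        "| seed =", object@seed, "\n")
})

setMethod("show", "HippoResult", function(object) {
    cat("HippoResult with", length(object@rounds), "round(s),",
        nClusters(object), "cluster(s) over", length(object@cellIds),
        "cells\n")
    cat("  stop reason:", object@stopReason, "\n")
    if (length(object@rounds)) {
        for (r in object@rounds) {
            cat(sprintf(
                "  round %d: split cluster %d (%d inflated features) -> %s\n",
                r$roundIndex, r$parentCluster, r$nInflated,
                paste(sprintf("%d cells", table(r$labelsAfter)),
                      collapse = " / ")))
        }
    }
})

setMethod("show", "ModelFit", function(object) {
    cat(sprintf("ModelFit [%s] lambda = %.4g", object@model, object@lambda))
    if (!is.na(object@r)) cat(sprintf(", r = %.4g", object@r))
    if (!is.na(object@pi0)) cat(sprintf(", pi0 = %.4g", object@pi0))
    cat(sprintf(", loglik = %.4f (%s)\n", object@loglik,
        if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "LRTResult", function(object) {
    cat(sprintf("LRT %s vs %s: stat = %.4f, df = %d, p = %.4g\n",
        object@nullModel, object@altModel, object@stat, object@df,
        object@pValue))
})

setMethod("show", "MixtureSpec", function(object) {
    cat("MixtureSpec:", nrow(object@rates), "genes,",
        length(object@nCellsPerCluster), "cluster(s) of sizes",
        paste(object@nCellsPerCluster, collapse = "/"),
        "|", length(object@heterogeneousGenes), "heterogeneous genes\n")
})
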