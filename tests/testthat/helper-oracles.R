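# Independent oracles: brute-force enumerations kept deliberately separate
# from the package's optimization paths.

# NB log-likelihood maximized by dense grid over the dispersion (the mean's
# MLE is the sample mean for any fixed dispersion).
nbGridLoglik <- function(x, rGrid = 10^seq(-3, 6, length.out = 6001)) {
    lam <- mean(x)
    lls <- vapply(rGrid,
        function(r) sum(dnbinom(x, size = r, mu = lam, log = TRUE)),
        numeric(1))
    max(lls, sum(dpois(x, lam, log = TRUE)))  # r = Inf boundary
}

# ZINB log-likelihood by two-stage dense grid over (pi0, log10 r) with the
# component mean profiled by 1-d optimization at each grid point.
zinbGridLoglik <- function(x) {
    zeros <- x == 0
    ll <- function(pi0, r, lam) {
        dens <- dnbinom(x, size = r, mu = lam)
        sum(log(pi0 * zeros + (1 - pi0) * dens))
    }
    profLam <- function(pi0, r) {
        lamMax <- max(mean(x) / max(1 - pi0, 1e-3), 1e-3) * 4
        optimize(function(l) ll(pi0, r, l), c(1e-6, lamMax),
            maximum = TRUE, tol = 1e-9)$objective
    }
    best <- -Inf
    bestP <- c(0, 0)
    pis <- seq(0, 0.9, by = 0.05)
    lrs <- seq(-3, 3, by = 0.25)
    for (p in pis) for (lr in lrs) {
        v <- profLam(p, 10^lr)
        if (v > best) { best <- v; bestP <- c(p, lr) }
    }
    pis2 <- pmax(0, pmin(1 - 1e-6, bestP[1] + seq(-0.05, 0.05, by = 0.002)))
    lrs2 <- pmax(-3, pmin(3, bestP[2] + seq(-0.25, 0.25, by = 0.01)))
    for (p in pis2) for (lr in lrs2) {
        v <- profLam(p, 10^lr)
        if (v > best) best <- v
    }
    max(best, nbGridLoglik(x))  # pi0 = 0 boundary
}

# Sum of sample variances of the first npc uncentered PC embeddings,
# computed through the eigendecomposition of the feature Gram matrix
# (independent of the svd route used by the package).
uncenteredVariationOracle <- function(counts, npc) {
    y <- t(log1p(as.matrix(counts)))
    eg <- eigen(crossprod(y), symmetric = TRUE)
    k <- min(npc, ncol(y), nrow(y))
    emb <- y %*% eg$vectors[, seq_len(k), drop = FALSE]
    sum(apply(emb, 2, var))
}
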