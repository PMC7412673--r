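---
title: "Zero-inflation screening and heterogeneity-driven clustering of UMI counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zero-inflation screening and heterogeneity-driven clustering of UMI counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scHippo)
```

## The model

For a genes × cells matrix of UMI counts $X_{gc}$, scHippo starts from the
observation that a *homogeneous* cell population produces, for each gene,
counts that are well described by a single Poisson distribution: the UMI
protocol collapses PCR duplicates, so the count is a thinned molecule count
and the technical noise is close to Poisson sampling noise. Under that null
the zero proportion of gene $g$ is pinned to its mean,

$$H_0:\; p_g = e^{-\lambda_g}.$$

If instead the cells are a mixture of $K_g$ types with type-specific rates
$\lambda_{kg}$ and weights $\pi_k$, the zero proportion becomes
$\sum_k \pi_k e^{-\lambda_{kg}}$, which by Jensen's inequality is *at least*
$e^{-\sum_k\pi_k\lambda_{kg}}$, with equality only when all rates coincide.
Excess zeros relative to the Poisson curve are therefore a signature of
cell-type heterogeneity, not merely of technical "drop-out". The same
direction of excess holds when the alternative is a negative binomial
(zero probability $(r/(r+\lambda))^r$) or a zero-inflated negative binomial
($\pi_0 + (1-\pi_0)(r/(r+\lambda))^r$), which is what makes the zero
proportion a robust heterogeneity statistic: it does not require choosing
among these alternatives. `expectedZero()` implements all four closed
forms. One note on the ZINB form: for the distribution
$\pi_0\delta_0 + (1-\pi_0)\mathrm{NB}(\lambda, r)$ the zero probability
carries the factor $(1-\pi_0)$ on the NB term; scHippo uses this exact
expression. Likewise `modelVariance()` reports the comparison forms used to
argue that gene *variance* is a poor heterogeneity indicator — for the ZINB
row the published comparison form $(1-\pi_0)^2(\lambda^2/r+\lambda)$, which
can dip below the null variance $\lambda$ (the exact ZINB variance
$(1-\pi_0)(\lambda^2/r+\lambda+\lambda^2)-(1-\pi_0)^2\lambda^2$ differs;
the comparison form is retained because the point being made — variance can
*decrease* under heterogeneity — is the same).

## The zero-inflation test

`geneZeroStats()` computes, per gene, the observed zero proportion
$\hat p_g = \sum_c \mathbf 1\{X_{gc}=0\}/C$, the mean
$\bar X_g = \sum_c X_{gc}/C$ (treated as fixed; its own sampling
variability is deliberately ignored, which in practice makes the test
conservative because $\hat p_g$ and $e^{-\bar X_g}$ co-vary positively
under the null), and the statistic

$$z_g = \frac{\hat p_g - e^{-\bar X_g}}
             {\sqrt{\hat p_g(1-\hat p_g)/C}},$$

referred to a standard normal with the one-sided alternative
$p_g > e^{-\lambda_g}$. Two details are deliberate:

* **Standard error, not variance.** The normal law for $\hat p_g$ has
  variance $\hat p_g(1-\hat p_g)/C$; dividing by its square root is the
  only choice under which $z_g$ is standard normal, and the implementation
  does so. A `se = "null"` option replaces $\hat p_g(1-\hat p_g)$ with the
  null-implied $e^{-\bar X}(1-e^{-\bar X})$.
* **Degenerate proportions.** $\hat p_g \in \{0, 1\}$ makes the standard
  error zero. Such genes get $z_g = 0$: a gene with no zeros carries no
  zero-inflation information (zero inflation is meaningless without
  zeros), and a gene with only zeros has mean 0 and a zero numerator.
  These genes are never selected.

Feature selection (`selectFeatures()`) takes genes with $z_g$ *strictly*
greater than the threshold (default 2, matching the one-sided 5% scale),
ordered by descending statistic. For data with high UMI counts, where few
zeros remain and the $z$ statistic saturates at 0, the per-gene Poisson
deviance

$$d_g = 2\sum_c\left(X_{gc}\log\frac{X_{gc}}{\bar X_g} -
(X_{gc}-\bar X_g)\right)$$

is available as an alternative score (`devianceStatistic()`; equal to twice
the saturated-minus-fitted Poisson log-likelihood gap, with $0\log 0 = 0$).
Its threshold is data-scale dependent and must be chosen by the user.

## Per-gene model diagnostics

`fitPoisson()`, `fitNB()` and `fitZINB()` maximize the likelihood of the
three nested candidate models; `modelLRT()` compares adjacent pairs with a
$\chi^2_1$ likelihood-ratio test (statistic clamped at 0, no boundary
correction — the uncorrected test is conservative at the $r = \infty$ and
$\pi_0 = 0$ boundaries). Numerical choices:

* NB dispersion $r$ (variance $\lambda^2/r + \lambda$) is profiled on a log
  scale over $[10^{-3}, 10^{6}]$ with `optimize()` at tolerance $10^{-8}$;
  the mean's MLE is the sample mean for every fixed $r$, so the 1-d search
  attains the joint maximum. When the sample variance does not exceed the
  mean the Poisson boundary is reported as `r = Inf` with the Poisson
  log-likelihood.
* The ZINB fit alternates fractional assignment of zeros to the structural
  component with re-estimation of $(\lambda, r)$ under those weights (an
  EM), capped at 500 iterations, converged when the observed
  log-likelihood improves by less than $10^{-8}$. With no zeros the fit is
  the NB fit with $\pi_0 = 0$; if the NB likelihood is higher the
  $\pi_0 = 0$ boundary is reported. Test oracles confirm the maximized
  log-likelihoods against dense grid searches to $10^{-3}$ on vectors of
  length ≤ 50.

## The clustering algorithm

`hippo()` resolves heterogeneity hierarchically. Each round:

1. within the cluster chosen for splitting, recompute the selection
   statistic over that cluster's candidate genes and keep features with
   statistic above the threshold;
2. transform the selected submatrix by $\log(1+X)$ (the finite reading of
   a log transform that must accept zeros), center and scale each feature
   to unit *sample* variance (zero-variance features stay centered,
   unscaled), project cells onto the top `nPcCluster` principal components
   (default 10, capped by rank), and split in two by K-means with
   `kmRestarts` restarts (default 10), keeping the lowest
   within-cluster sum of squares;
3. score every cluster's intra-cluster variability and mark the highest
   as the next split candidate.

Variability (`intraClusterVariation()`) is the sum of sample variances of
the first `nPcVariation` (default 10) cell embeddings of an *uncentered,
unscaled* PCA of the cluster's $\log(1+X)$ submatrix over the features of
the round that created it. Scaling is deliberately avoided: later rounds
see fewer cells, and scaled embeddings would make small clusters look
artificially spread out. A `splitCriterion = "centroid_distance"` option
scores clusters by the mean Euclidean distance of their cells from the
cluster centroid in the round's standardized feature space instead; the
uncentered-PCA criterion is the default because it is the one whose
rationale (population-size bias) is explicit.

Stopping: the algorithm halts when `K` clusters exist, or when a round
selects fewer than $G \times o$ inflated genes, where $G$ is the total
gene count of the input matrix (constant across rounds) and $o$ is the
`outlierProportion` (default 0.01) — with 30,000 genes and $o = 1\%$,
up to 300 genes are allowed to look inflated in a homogeneous population
before the algorithm keeps splitting. The comparison is strict.

Other determinism and bookkeeping choices: a master seed spawns one child
seed per round, so re-running is bit-identical and inserting a round never
reshuffles later randomness; ties across K-means restarts resolve by
lowest within-cluster sum of squares, ties in variability by lower cluster
id; after a split the larger child keeps the parent's id (ties: the child
holding the lowest cell index) and the smaller child takes the next unused
id, so labels of untouched clusters never change and round $t$ has exactly
$t+1$ clusters. By default a child's candidate genes are the features its
parent round selected, re-tested within the child — candidate sets shrink
along every lineage; `inheritFeatures = FALSE` re-tests all genes each
round. A cluster whose cells are indistinguishable in the selected feature
space is marked unsplittable and the next most variable cluster is tried;
if none remain the run stops.

Whether K-means should see a fixed number of components or all of them is
genuinely open; scHippo uses 10, symmetric with the 10-dimension
variability computation, and caps both by matrix rank.

## Differential expression

`diffExp()` compares two clusters per gene under Poisson models with rates
$\lambda_1, \lambda_2$, reporting both a two-sample test on means with
plug-in variances,

$$t = \frac{\bar X_1 - \bar X_2}
           {\sqrt{\bar X_1/|C_1| + \bar X_2/|C_2|}},$$

referred *two-sided* to the standard normal (two-sided because the
alternative is $\lambda_1 \neq \lambda_2$), and the Poisson
likelihood-ratio deviance
$2(\ell_1(\hat\lambda_1)+\ell_2(\hat\lambda_2)-\ell(\hat\lambda))$ against
$\chi^2_1$. Genes with both group means zero get statistic 0 and p-value
1; a zero denominator with unequal means cannot occur. Bonferroni
adjustment multiplies by the full family size (all genes tested), capped
at 1; which test feeds the adjusted column is a user choice since neither
is privileged.

## The simulator

`simulatePoissonMixture()` draws $X_{gc} \sim
\mathrm{Poisson}(\lambda_{kg})$ for cell $c$ in cluster $k$ from a
`MixtureSpec`, the package's ground-truth object. The default spec
(`defaultMixtureSpec()`) emulates a low-UMI droplet experiment: 3 clusters
of 300 cells, 2,000 genes, 5% heterogeneous genes with per-cluster rates
log-uniform on $[0.5, 8]$ UMI/cell and shared genes log-uniform on
$[0.05, 2]$ — the regime where most genes are lowly expressed and zeros
carry the signal. `simulateNB()` samples through the Gamma–Poisson
hierarchy (cell rate $\sim \Gamma(r, r/\lambda)$, then Poisson), so the
continuous-mixture construction that links NB to Poisson mixing is itself
exercised; `simulateZINB()` adds independent structural zeros.

What the simulator does *not* emulate: library-size variation across
cells, batch effects, protocol-specific noise, gene–gene correlation, or
doublets. Passing tests therefore demonstrate correctness of the method
under its own generative assumptions, not performance on any real tissue.
Two further honest limitations: (i) the zero-inflation statistic is
powerless for genes whose rates are high in *all* clusters (no zeros ever
appear, $z = 0$ by convention) — such heterogeneity is only visible to the
deviance score; power statements in the test suite use mixtures whose
lower rate is ≥ 0.3 UMI/cell for that reason; and (ii) the z test is
conservative (null retention well above 95%) because the estimated mean's
variability is ignored.

## Problem sizes used by the test suite

Simulation-backed checks run at sizes chosen to make their statistical
assertions stable: null calibration at 2,000 genes × 1,000 cells, DE
type-I error at 2,000 genes × 500 cells per group with rates log-uniform
on $[0.5, 10]$ (a regime where the $\chi^2_1$/normal asymptotics apply),
cluster recovery on the default 900-cell fixture across 10 seeds,
parameter recovery of $r$ and $\pi_0$ at $n = 20{,}000$ draws, and grid
oracles on vectors of length ≤ 50.

## A worked run

```{r example}
sim <- simulatePoissonMixture(defaultMixtureSpec(seed = 1))
res <- hippo(sim, K = 3, seed = 1)
res
table(finalLabels(res), sim$true_label)
de <- diffExp(sim, finalLabels(res), clusters = c(0, 1))
head(as.data.frame(de[order(de$p_adj), c("mean1", "mean2", "lrt_stat",
    "p_adj")]), 3)
```
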