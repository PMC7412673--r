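#' Construct a clustering configuration
#'
#' User-facing constructor for [HippoConfig-class]; see that class for the
#' meaning and defaults of every field.
#'
#' @param K maximum number of clusters.
#' @param zThreshold z-score selection cutoff.
#' @param outlierProportion allowed proportion of inflated genes under
#'   homogeneity.
#' @param nPcCluster,nPcVariation numbers of principal components.
#' @param kmRestarts K-means restarts.
#' @param seed master seed.
#' @param featureMethod `"zero_inflation"` or `"deviance"`.
#' @param devianceThreshold deviance cutoff (deviance method only).
#' @param inheritFeatures restrict a child's candidate genes to its parent
#'   round's selection.
#' @param splitCriterion `"uncentered_pca"` or `"centroid_distance"`.
#' @return a validated `HippoConfig`.
#' @examples
#' HippoConfig(K = 3, seed = 7)
#' @export
HippoConfig <- function(K = 2, zThreshold = 2, outlierProportion = 0.01,
                        nPcCluster = 10, nPcVariation = 10, kmRestarts = 10,
                        seed = 1, featureMethod = "zero_inflation",
                        devianceThreshold = 300, inheritFeatures = TRUE,
                        splitCriterion = "uncentered_pca") {
    methods::new("HippoConfig",
        K = as.integer(K), zThreshold = as.numeric(zThreshold),
        outlierProportion = as.numeric(outlierProportion),
        nPcCluster = as.integer(nPcCluster),
        nPcVariation = as.integer(nPcVariation),
        kmRestarts = as.integer(kmRestarts), seed = as.integer(seed),
        featureMethod = featureMethod,
        devianceThreshold = as.numeric(devianceThreshold),
        inheritFeatures = isTRUE(inheritFeatures),
        splitCriterion = splitCriterion)
}

#' Log-transform and standardize a feature submatrix
#'
#' Counts are transformed by `log(1 + x)` and each feature (gene) is
#' centered to mean 0 and scaled to unit sample variance. Features with zero
#' variance are centered but left unscaled (an all-zero column). The result
#' is oriented cells x features, ready for PCA.
#'
#' @param sub count container restricted to the selected features and cells.
#' @return numeric matrix, cells x features.
#' @export
logTransformStandardize <- function(sub) {
    m <- as.matrix(.countsMatrix(sub))
    if (ncol(m) < 2L || nrow(m) < 1L)
        stop("need at least 2 cells and 1 feature")
    y <- t(log1p(m))                      # cells x features
    y <- sweep(y, 2L, colMeans(y))
    sds <- apply(y, 2L, stats::sd)
    pos <- which(sds > 0)
    if (length(pos))
        y[, pos] <- sweep(y[, pos, drop = FALSE], 2L, sds[pos], "/")
    y
}

#' Binary PCA + K-means split of a standardized cell matrix
#'
#' Projects cells onto the top `nPc` principal components (capped at
#' `min(cells - 1, features)`) and runs 2-means with `restarts` random
#' starts, keeping the solution with the lowest within-cluster sum of
#' squares. Deterministic for a fixed seed. Refuses to split degenerate
#' input (fewer than two distinct cell profiles).
#'
#' @param z cells x features matrix from [logTransformStandardize()].
#' @param nPc number of components.
#' @param restarts K-means restarts.
#' @param seed RNG seed for the K-means starts.
#' @return integer vector of 0/1 labels, both groups nonempty.
#' @export
pcaKmeansSplit <- function(z, nPc = 10, restarts = 10, seed = 1) {
    if (nrow(z) < 2L) .degenerateSplit("fewer than 2 cells")
    npc <- max(1L, min(as.integer(nPc), nrow(z) - 1L, ncol(z)))
    pc <- stats::prcomp(z, center = FALSE, scale. = FALSE, rank. = npc)
    scores <- pc$x[, seq_len(min(npc, ncol(pc$x))), drop = FALSE]
    if (nrow(unique(scores)) < 2L)
        .degenerateSplit("all cells identical in the selected feature space")
    set.seed(seed)
    km <- tryCatch(
        stats::kmeans(scores, centers = 2L, nstart = restarts,
            iter.max = 100L),
        error = function(e) .degenerateSplit(conditionMessage(e)))
    as.integer(km$cluster) - 1L
}

#' Intra-cluster variability from uncentered, unscaled PCA
#'
#' Computes the `log(1 + x)` matrix of one cluster's cells over one round's
#' features, takes its singular value decomposition without centering or
#' scaling (centering/scaling would inflate small clusters' embeddings
#' relative to large ones), and returns the sum of the sample variances of
#' the first `nPc` cell-embedding components. Clusters with a single cell or
#' identical cells return 0.
#'
#' @param sub count container restricted to one cluster's cells and the
#'   round's features.
#' @param nPc number of leading components (default 10, capped by the matrix
#'   dimensions).
#' @return nonnegative scalar.
#' @export
intraClusterVariation <- function(sub, nPc = 10) {
    m <- as.matrix(.countsMatrix(sub))
    y <- t(log1p(m))                      # cells x features
    if (nrow(y) < 2L) return(0)
    npc <- max(1L, min(as.integer(nPc), nrow(y), ncol(y)))
    sv <- svd(y, nu = 0L, nv = npc)
    emb <- y %*% sv$v[, seq_len(npc), drop = FALSE]
    sum(apply(emb, 2L, stats::var))
}

# Mean Euclidean distance of each cell from its cluster centroid in the
# round's standardized feature space (the alternative split criterion).
.centroidDistance <- function(z) {
    if (nrow(z) < 2L) return(0)
    ctr <- colMeans(z)
    mean(sqrt(rowSums(sweep(z, 2L, ctr)^2)))
}

#' Iterative heterogeneity-driven hierarchical clustering
#'
#' Starting from all cells in one cluster, each round (i) selects the genes
#' whose zero-inflation z (or deviance) statistic strictly exceeds the
#' threshold within the cluster chosen for splitting, (ii) log-transforms
#' and standardizes those features and splits the cluster's cells in two by
#' PCA + K-means, and (iii) scores every resulting cluster's intra-cluster
#' variability; the most variable cluster is split next. The algorithm stops
#' when `K` clusters exist (`"reached_K"`) or when a round selects fewer
#' than `G * o` inflated genes, `G` being the total gene count of the input
#' matrix (`"too_few_inflated_genes"`). A cluster whose cells cannot be
#' separated is marked unsplittable and the next most variable cluster is
#' tried.
#'
#' By default a child cluster inherits its parent round's selected features
#' as its candidate set and re-tests them within its own cells, so candidate
#' sets shrink along every lineage; set `inheritFeatures = FALSE` in the
#' config to re-test all genes each round. The parent cluster's id is kept
#' by the larger child (ties: the child holding the lowest cell index); the
#' smaller child receives the next unused id, so labels of non-split
#' clusters never change.
#'
#' @param x count container (`G >= 2` genes, `C >= 4` cells).
#' @param K maximum number of clusters (ignored when `config` is given).
#' @param ... further arguments passed to [HippoConfig()].
#' @param config a ready-made [HippoConfig-class]; overrides `K` and `...`.
#' @return a [HippoResult-class].
#' @examples
#' sim <- simulatePoissonMixture(defaultMixtureSpec(seed = 3, nGenes = 300,
#'     cellsPerCluster = 50, nClusters = 2))
#' res <- hippo(sim, K = 2, seed = 3)
#' res
#' @export
hippo <- function(x, K = 2, ..., config = NULL) {
    if (is.null(config)) config <- HippoConfig(K = K, ...)
    m <- .countsMatrix(x)
    G <- nrow(m)
    C <- ncol(m)
    if (C < 4L || G < 2L) stop("need at least 4 cells and 2 genes")
    allowed <- G * config@outlierProportion
    labels <- rep(0L, C)
    clusters <- list(list(id = 0L, cells = seq_len(C),
        genes = seq_len(G), variation = NA_real_, splittable = TRUE))
    rounds <- list()
    stop_reason <- "reached_K"

    while (length(clusters) < config@K) {
        roundIndex <- length(rounds) + 1L
        progressed <- FALSE
        repeat {
            cand <- Filter(function(cl) cl$splittable &&
                length(cl$cells) >= 2L, clusters)
            if (!length(cand)) {
                stop_reason <- "too_few_inflated_genes"
                break
            }
            vs <- vapply(cand, `[[`, numeric(1), "variation")
            ids <- vapply(cand, `[[`, integer(1), "id")
            vs[is.na(vs)] <- Inf       # an unscored cluster (round 1 root)
            pick <- ids[order(-vs, ids)][1L]
            ci <- which(vapply(clusters, `[[`, integer(1), "id") == pick)
            cl <- clusters[[ci]]

            stats <- geneZeroStats(m[cl$genes, cl$cells, drop = FALSE])
            sel <- selectFeatures(stats, method = config@featureMethod,
                zThreshold = config@zThreshold,
                devianceThreshold = config@devianceThreshold)
            nInflated <- length(sel)
            if (nInflated < allowed) {
                stop_reason <- "too_few_inflated_genes"
                break
            }
            if (nInflated == 0L) {      # only reachable when allowed == 0
                clusters[[ci]]$splittable <- FALSE
                next
            }
            features <- cl$genes[sel]
            split <- tryCatch({
                zmat <- logTransformStandardize(
                    m[features, cl$cells, drop = FALSE])
                lab2 <- pcaKmeansSplit(zmat, nPc = config@nPcCluster,
                    restarts = config@kmRestarts,
                    seed = .childSeed(config@seed, roundIndex))
                list(zmat = zmat, lab2 = lab2)
            }, degenerateSplitError = function(e) NULL)
            if (is.null(split)) {
                clusters[[ci]]$splittable <- FALSE
                next
            }
            lab2 <- split$lab2
            sizes <- tabulate(lab2 + 1L, 2L)
            keepSide <- if (sizes[1L] != sizes[2L]) {
                which.max(sizes) - 1L
            } else {
                lab2[1L]               # tie: side holding the first cell
            }
            childLabels <- as.integer(lab2 != keepSide)
            newId <- length(clusters)  # ids are 0 .. n-1, next unused
            labels[cl$cells[childLabels == 1L]] <- newId

            childGenes <- if (config@inheritFeatures) features
                else seq_len(G)
            scoreChild <- function(cells, side) {
                if (config@splitCriterion == "uncentered_pca") {
                    intraClusterVariation(
                        m[features, cells, drop = FALSE],
                        nPc = config@nPcVariation)
                } else {
                    .centroidDistance(
                        split$zmat[childLabels == side, , drop = FALSE])
                }
            }
            keptCells <- cl$cells[childLabels == 0L]
            newCells <- cl$cells[childLabels == 1L]
            clusters[[ci]] <- list(id = cl$id, cells = keptCells,
                genes = childGenes, variation = scoreChild(keptCells, 0L),
                splittable = TRUE)
            clusters[[length(clusters) + 1L]] <- list(id = newId,
                cells = newCells, genes = childGenes,
                variation = scoreChild(newCells, 1L), splittable = TRUE)

            intra <- vapply(clusters, `[[`, numeric(1), "variation")
            names(intra) <- vapply(clusters, `[[`, integer(1), "id")
            rounds[[roundIndex]] <- list(
                roundIndex = roundIndex,
                parentCluster = cl$id,
                selectedFeatures = features,
                nInflated = nInflated,
                childLabels = childLabels,
                intraVariation = intra[order(as.integer(names(intra)))],
                labelsAfter = labels)
            progressed <- TRUE
            break
        }
        if (!progressed) break
    }

    methods::new("HippoResult", config = config, rounds = rounds,
        finalLabels = labels, cellIds = .cellIds(x, m),
        stopReason = stop_reason)
}

#' Export a clustering result
#'
#' Writes three artifacts into `dir`: `labels.tsv` (cell id plus the label
#' after each round), `features.tsv` (round index, rank, gene index and gene
#' id of every selected feature) and `manifest.json` (configuration, seed,
#' stop reason and per-round diagnostics).
#'
#' @param result a [HippoResult-class].
#' @param dir output directory, created if needed.
#' @param geneIds optional gene identifiers for the feature table.
#' @return invisibly, the paths written.
#' @export
writeHippoResult <- function(result, dir, geneIds = NULL) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    labPath <- file.path(dir, "labels.tsv")
    featPath <- file.path(dir, "features.tsv")
    manPath <- file.path(dir, "manifest.json")

    lab <- data.frame(cell_id = result@cellIds)
    for (r in result@rounds)
        lab[[sprintf("label_round_%d", r$roundIndex)]] <- r$labelsAfter
    lab$label_final <- result@finalLabels
    utils::write.table(lab, labPath, sep = "\t", quote = FALSE,
        row.names = FALSE)

    feats <- do.call(rbind, lapply(result@rounds, function(r)
        data.frame(round = r$roundIndex,
            rank = seq_along(r$selectedFeatures),
            gene_index = r$selectedFeatures,
            gene_id = if (is.null(geneIds)) NA_character_
                else geneIds[r$selectedFeatures])))
    if (is.null(feats))
        feats <- data.frame(round = integer(), rank = integer(),
            gene_index = integer(), gene_id = character())
    utils::write.table(feats, featPath, sep = "\t", quote = FALSE,
        row.names = FALSE)

    diag <- lapply(result@rounds, function(r) list(
        round = r$roundIndex, parent_cluster = r$parentCluster,
        n_inflated = r$nInflated,
        cluster_sizes = as.vector(table(r$labelsAfter)),
        intra_variation = as.list(r$intraVariation)))
    .writeManifest(manPath, command = "cluster",
        config = .configAsList(result@config), inputs = list(),
        seed = result@config@seed,
        summary = list(stop_reason = result@stopReason,
            n_clusters = nClusters(result), rounds = diag))
    invisible(c(labPath, featPath, manPath))
}
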