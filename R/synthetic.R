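#' @include AllClasses.R
NULL

# Synthetic data with the statistical structure the pipeline assumes:
# a preferential-attachment "ground truth" network, expression whose
# pairwise dependencies follow the network, hallmark/CGC-like gene sets,
# and dependency scores that are a noisy monotone function of planted
# network features.

#' Synthetic dataset configuration
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' package's recovery tests: a 500-gene preferential-attachment network
#' (2 attachment edges, MI-like weights in [0.5, 8]), one lineage of 30
#' samples, 25 CGC-like genes and ten 15-gene hallmark-like sets sampled
#' disjointly with hub bias 1, dependency driven by degree and one
#' hallmark neighbour count (effect sizes 1 and 0.6), Gaussian noise with
#' sd 0.25, and 15% of genes dependent.
#'
#' @slot nGenes number of genes
#' @slot nSamplesPerLineage samples (cell lines) per lineage (>= 3)
#' @slot nLineages number of lineages
#' @slot attachmentEdges preferential-attachment edges per new node
#' @slot weightLow,weightHigh MI-like edge-weight range (> 0)
#' @slot nCgc number of planted cancer-census-like genes
#' @slot hallmarkSizes integer vector of exactly 10 set sizes
#' @slot hubBias exponent biasing gene-set sampling toward high-degree
#'   genes (0 = unbiased null)
#' @slot plantedFeatures feature column names driving dependency
#' @slot plantedEffectSizes numeric effect size per planted feature
#' @slot noiseSd Gaussian noise sd for both the expression structural
#'   scheme and the per-(gene, sample) dependency score noise
#' @slot geneNoiseSd sd of the feature-independent per-gene score
#'   scatter, emulating screen noise and biology unrelated to network
#'   features (concentrated around the nonessential anchor at 0)
#' @slot signalQuantile quantile of the planted signal below which scores
#'   are feature-driven; genes above it sit flat at the nonessential
#'   anchor, emulating the feature-independent nonessential bulk of
#'   gene-effect screens. Must exceed \code{dependencyFraction}; 1
#'   disables the flattening
#' @slot dependencyFraction target fraction of dependent genes, in (0, 1)
#' @slot seed integer master seed
#' @export
setClass("SyntheticConfig",
         slots = c(nGenes = "integer", nSamplesPerLineage = "integer",
                   nLineages = "integer", attachmentEdges = "integer",
                   weightLow = "numeric", weightHigh = "numeric",
                   nCgc = "integer", hallmarkSizes = "integer",
                   hubBias = "numeric", plantedFeatures = "character",
                   plantedEffectSizes = "numeric", noiseSd = "numeric",
                   geneNoiseSd = "numeric", signalQuantile = "numeric",
                   dependencyFraction = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  if (object@nGenes < 2) return("nGenes must be >= 2")
  if (object@nSamplesPerLineage < 1) return("nSamplesPerLineage must be >= 1")
  if (object@nLineages < 1) return("nLineages must be >= 1")
  if (object@attachmentEdges < 1) return("attachmentEdges must be >= 1")
  if (object@weightLow <= 0 || object@weightHigh < object@weightLow)
    return("need 0 < weightLow <= weightHigh")
  if (object@nCgc >= object@nGenes) return("nCgc must be < nGenes")
  if (length(object@hallmarkSizes) != 10)
    return("hallmarkSizes must have exactly 10 entries")
  if (object@nCgc + sum(object@hallmarkSizes) > object@nGenes)
    return("disjoint CGC and hallmark sets exceed the gene universe")
  if (length(object@plantedFeatures) != length(object@plantedEffectSizes))
    return("one effect size per planted feature required")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@geneNoiseSd < 0) return("geneNoiseSd must be >= 0")
  if (object@dependencyFraction <= 0 || object@dependencyFraction >= 1)
    return("dependencyFraction must be in (0, 1)")
  if (object@signalQuantile <= object@dependencyFraction ||
      object@signalQuantile > 1)
    return("signalQuantile must be in (dependencyFraction, 1]")
  TRUE
})

#' Construct a SyntheticConfig
#'
#' @param nGenes,nSamplesPerLineage,nLineages,attachmentEdges see
#'   \linkS4class{SyntheticConfig}
#' @param weightLow,weightHigh,nCgc,hallmarkSizes,hubBias see
#'   \linkS4class{SyntheticConfig}
#' @param plantedFeatures,plantedEffectSizes,noiseSd,geneNoiseSd see
#'   \linkS4class{SyntheticConfig}
#' @param signalQuantile,dependencyFraction,seed see
#'   \linkS4class{SyntheticConfig}
#' @return a \linkS4class{SyntheticConfig}
#' @examples
#' syntheticConfig(nGenes = 60, nCgc = 5, hallmarkSizes = rep(3L, 10))
#' @export
syntheticConfig <- function(nGenes = 500L, nSamplesPerLineage = 30L,
                            nLineages = 1L, attachmentEdges = 2L,
                            weightLow = 0.5, weightHigh = 8,
                            nCgc = 25L, hallmarkSizes = rep(15L, 10),
                            hubBias = 1,
                            plantedFeatures = c("degree", "hallmark_01"),
                            plantedEffectSizes = c(1, 0.6),
                            noiseSd = 0.25, geneNoiseSd = 0.15,
                            signalQuantile = 0.3,
                            dependencyFraction = 0.15,
                            seed = 1L) {
  new("SyntheticConfig", nGenes = as.integer(nGenes),
      nSamplesPerLineage = as.integer(nSamplesPerLineage),
      nLineages = as.integer(nLineages),
      attachmentEdges = as.integer(attachmentEdges),
      weightLow = weightLow, weightHigh = weightHigh,
      nCgc = as.integer(nCgc), hallmarkSizes = as.integer(hallmarkSizes),
      hubBias = hubBias, plantedFeatures = plantedFeatures,
      plantedEffectSizes = plantedEffectSizes, noiseSd = noiseSd,
      geneNoiseSd = geneNoiseSd, signalQuantile = signalQuantile,
      dependencyFraction = dependencyFraction, seed = as.integer(seed))
}

#' Synthetic dataset bundle
#'
#' Holds the ground-truth network together with everything generated from
#' it, including the feature table the dependency signal was planted on
#' and the truth labels obtained by binarizing the generated scores with
#' the labeling module.
#'
#' @slot config the generating \linkS4class{SyntheticConfig}
#' @slot network ground-truth \linkS4class{GeneNetwork}
#' @slot expression \linkS4class{ExpressionMatrix}
#' @slot geneSets \linkS4class{GeneSetCollection}
#' @slot features network \linkS4class{FeatureTable} on the true network
#' @slot scores \linkS4class{DependencyScores}
#' @slot truthLabels \linkS4class{DependencyLabels}
#' @slot truthFeatureWeights named numeric planted effect sizes
#' @export
setClass("SyntheticDataset",
         slots = c(config = "SyntheticConfig", network = "GeneNetwork",
                   expression = "ExpressionMatrix",
                   geneSets = "GeneSetCollection",
                   features = "FeatureTable", scores = "DependencyScores",
                   truthLabels = "DependencyLabels",
                   truthFeatureWeights = "numeric"))

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset:", numNodes(object@network), "genes,",
      ncol(object@expression), "samples,",
      length(lineages(object@expression)), "lineage(s)\n")
  t <- labelTable(object@truthLabels)
  cat("  dependent:", sum(t$label == "dependent"), "of", nrow(t),
      "(gene, lineage) pairs\n")
})

.geneIds <- function(n) sprintf("g%0*d", nchar(n), seq_len(n))

.sampleIds <- function(cfg) {
  unlist(lapply(seq_len(cfg@nLineages), function(l)
    sprintf("L%d_S%0*d", l, nchar(cfg@nSamplesPerLineage),
            seq_len(cfg@nSamplesPerLineage))))
}

.sampleLineageMap <- function(cfg) {
  stats::setNames(rep(paste0("lineage_", seq_len(cfg@nLineages)),
                      each = cfg@nSamplesPerLineage), .sampleIds(cfg))
}

#' Generate a ground-truth gene network
#'
#' Preferential attachment (Barabasi-Albert) with
#' \code{attachmentEdges} edges per incoming node, giving the heavy-tailed
#' degree distribution typical of inferred regulatory networks, with edge
#' weights drawn uniformly from the MI-like range
#' [\code{weightLow}, \code{weightHigh}]. Deterministic for a fixed seed.
#'
#' @param cfg a \linkS4class{SyntheticConfig}; requires
#'   \code{nGenes >= attachmentEdges + 1}
#' @return a \linkS4class{GeneNetwork}
#' @export
generateNetwork <- function(cfg) {
  stopIfNot(cfg@nGenes >= cfg@attachmentEdges + 1,
            "nGenes must be at least attachmentEdges + 1")
  withSeed(cfg@seed, {
    g <- igraph::sample_pa(cfg@nGenes, power = 1, m = cfg@attachmentEdges,
                           directed = FALSE)
    ids <- .geneIds(cfg@nGenes)
    el <- igraph::as_edgelist(g, names = FALSE)
    w <- stats::runif(nrow(el), cfg@weightLow, cfg@weightHigh)
    GeneNetwork(ids, data.frame(from = ids[el[, 1]], to = ids[el[, 2]],
                                weight = w))
  })
}

#' Sample CGC-like and hallmark-like gene sets
#'
#' Samples \code{nCgc} cancer-census-like genes and ten disjoint
#' hallmark-like sets (all disjoint from the CGC set) without
#' replacement, with selection probability proportional to
#' degree^\code{hubBias} -- cancer genes are often network hubs; bias 0
#' gives the unbiased null. Hallmark sets are named
#' \code{hallmark_01 ... hallmark_10}.
#'
#' @param net the ground-truth \linkS4class{GeneNetwork}
#' @param cfg a \linkS4class{SyntheticConfig}
#' @return a \linkS4class{GeneSetCollection}
#' @export
generateGeneSets <- function(net, cfg) {
  withSeed(cfg@seed + 1L, {
    ids <- genes(net)
    deg <- igraph::degree(asIgraph(net))[ids]
    pool <- ids
    draw <- function(size) {
      p <- (deg[pool] + 1e-9)^cfg@hubBias
      picked <- sample(pool, size, prob = p / sum(p))
      pool <<- setdiff(pool, picked)
      picked
    }
    cgc <- draw(cfg@nCgc)
    hall <- lapply(cfg@hallmarkSizes, draw)
    names(hall) <- sprintf("hallmark_%02d", seq_len(10))
    GeneSetCollection(hall, cgc,
                      tiers = rep_len(c(1L, 2L), length(cgc)))
  })
}

#' Generate expression following the network
#'
#' Linear-Gaussian structural scheme over the acyclic orientation given
#' by node age in the preferential-attachment construction (an older
#' gene regulates the younger genes that attached to it, so every gene
#' has at most \code{attachmentEdges} regulators): in topological order,
#' each gene's value is the edge-weight-proportional mix of its
#' regulators plus independent Gaussian noise (sd \code{noiseSd}), then
#' standardized per gene. The bounded in-degree guarantees detectable
#' statistical dependence along every true edge; adjacent genes correlate
#' more strongly than non-adjacent pairs in expectation, and as
#' \code{noiseSd} approaches 0 the correlation along single-regulator
#' edges approaches 1. Samples are grouped into lineages; lineages share
#' the orientation but draw independent samples.
#'
#' @param net the ground-truth \linkS4class{GeneNetwork}
#' @param cfg a \linkS4class{SyntheticConfig}; requires
#'   \code{nSamplesPerLineage >= 3}
#' @return an \linkS4class{ExpressionMatrix}
#' @export
generateExpression <- function(net, cfg) {
  stopIfNot(numNodes(net) > 0, "network must be nonempty")
  stopIfNot(cfg@nSamplesPerLineage >= 3,
            "nSamplesPerLineage must be >= 3 (lineages with fewer cell ",
            "lines are excluded from analysis)")
  withSeed(cfg@seed + 2L, {
    ids <- genes(net)
    n <- length(ids)
    ord <- ids  # generation order = attachment age (ids are age-ordered)
    pos <- stats::setNames(seq_len(n), ord)
    adj <- .adjacencyList(net)
    e <- edgeTable(net)
    wkey <- stats::setNames(e$weight, paste(e$from, e$to))
    edgeW <- function(a, b) unname(wkey[paste(min(a, b), max(a, b))])
    ns <- cfg@nSamplesPerLineage
    lineageBlocks <- lapply(seq_len(cfg@nLineages), function(l) {
      X <- matrix(0, nrow = ns, ncol = n, dimnames = list(NULL, ids))
      for (gname in ord) {
        parents <- adj[[gname]][pos[adj[[gname]]] < pos[gname]]
        if (length(parents) == 0) {
          x <- stats::rnorm(ns)
        } else {
          w <- vapply(parents, function(p) edgeW(gname, p), numeric(1))
          mix <- as.vector(X[, parents, drop = FALSE] %*% (w / sum(w)))
          x <- mix + cfg@noiseSd * stats::rnorm(ns)
        }
        s <- stats::sd(x)
        X[, gname] <- if (is.finite(s) && s > 0) (x - mean(x)) / s else x
      }
      X
    })
    values <- t(do.call(rbind, lineageBlocks))
    colnames(values) <- .sampleIds(cfg)
    ExpressionMatrix(values, .sampleLineageMap(cfg))
  })
}

#' Generate dependency scores from planted features
#'
#' Per-gene gene-effect signal built as minus a linear combination of the
#' z-scored planted feature columns, flattened above its
#' \code{signalQuantile} quantile (nonessential genes score near 0
#' regardless of network position, as in real gene-effect screens), plus
#' feature-independent per-gene scatter (sd \code{geneNoiseSd}). The
#' signal is affinely calibrated onto the gene-effect scale -- its median
#' maps to 0 (the nonessential anchor) and its
#' \code{dependencyFraction} quantile maps to -1 (the essential anchor)
#' -- then perturbed per sample with i.i.d. Gaussian noise (sd
#' \code{noiseSd}). The fraction of genes whose lineage-mean score falls
#' at or below -1 therefore matches \code{dependencyFraction} up to
#' noise, and scores are a noisy monotone-decreasing function of the
#' planted feature combination.
#'
#' @param net the ground-truth \linkS4class{GeneNetwork} (supplies the
#'   gene universe)
#' @param features a \linkS4class{FeatureTable} computed on \code{net};
#'   must contain every planted feature column
#' @param cfg a \linkS4class{SyntheticConfig}
#' @return a \linkS4class{DependencyScores}
#' @export
generateDependency <- function(net, features, cfg) {
  missing <- setdiff(cfg@plantedFeatures, colnames(as.matrix(features)))
  stopIfNot(length(missing) == 0,
            "planted feature(s) absent from the feature table: ",
            paste(missing, collapse = ", "))
  withSeed(cfg@seed + 3L, {
    M <- as.matrix(features)
    Z <- zscore(M[, cfg@plantedFeatures, drop = FALSE])
    s <- -as.vector(Z %*% cfg@plantedEffectSizes)
    q0 <- unname(stats::quantile(s, cfg@signalQuantile, type = 1))
    s <- pmin(s, q0)  # nonessential side flattened at the anchor
    s <- s + stats::rnorm(nrow(M), sd = cfg@geneNoiseSd)
    m <- stats::median(s)
    qf <- unname(stats::quantile(s, cfg@dependencyFraction, type = 1))
    span <- m - qf
    if (span <= 0) span <- 1  # degenerate signal (e.g. all effects 0)
    t <- (s - m) / span
    smp <- .sampleIds(cfg)
    noise <- matrix(stats::rnorm(length(t) * length(smp), sd = cfg@noiseSd),
                    nrow = length(t))
    values <- t + noise
    dimnames(values) <- list(rownames(M), smp)
    DependencyScores(values, .sampleLineageMap(cfg))
  })
}

#' Generate a complete synthetic dataset
#'
#' Runs the full generator chain -- network, gene sets, expression,
#' network features on the true network, dependency scores -- and records
#' the truth labels produced by binarizing the generated scores with the
#' labeling module at cutoff -1, plus the planted feature weights.
#' Deterministic for a fixed seed.
#'
#' @param cfg a \linkS4class{SyntheticConfig}
#' @return a \linkS4class{SyntheticDataset}
#' @examples
#' ds <- generateSyntheticDataset(
#'   syntheticConfig(nGenes = 80, nCgc = 6, hallmarkSizes = rep(4L, 10),
#'                   nSamplesPerLineage = 10))
#' ds
#' @export
generateSyntheticDataset <- function(cfg) {
  net <- generateNetwork(cfg)
  sets <- generateGeneSets(net, cfg)
  expr <- generateExpression(net, cfg)
  feat <- networkFeatures(net, sets)
  scores <- generateDependency(net, feat, cfg)
  truth <- dependencyLabels(scores, cutoff = -1,
                            minLines = min(3, cfg@nSamplesPerLineage))
  new("SyntheticDataset", config = cfg, network = net, expression = expr,
      geneSets = sets, features = feat, scores = scores,
      truthLabels = truth,
      truthFeatureWeights = stats::setNames(cfg@plantedEffectSizes,
                                            cfg@plantedFeatures))
}
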