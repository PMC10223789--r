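# Mutual-information network inference: per-lineage dense MI graph,
# data-processing-inequality pruning, and edge-weight cutoff pruning.

# Equal-frequency discretization, invariant to sample order (quantile
# breaks; duplicate breaks collapsed, so heavily tied vectors get fewer
# occupied bins).
.discretize <- function(x, nBins) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = nBins + 1)))
  if (length(br) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

# Plug-in MI (nats) from a pair of integer bin vectors, with Miller-Madow
# bias correction and clipping at 0.
.miFromBins <- function(bx, by, nBins) {
  n <- length(bx)
  joint <- tabulate(bx + (by - 1L) * nBins, nbins = nBins * nBins)
  px <- tabulate(bx, nbins = nBins)
  py <- tabulate(by, nbins = nBins)
  h <- function(cnt) {
    p <- cnt[cnt > 0] / n
    -sum(p * log(p))
  }
  mm <- function(cnt) (sum(cnt > 0) - 1) / (2 * n)
  mi <- (h(px) + mm(px)) + (h(py) + mm(py)) - (h(joint) + mm(joint))
  max(mi, 0)
}

# Gaussian-copula MI: Spearman correlation mapped to the Pearson
# correlation of the underlying bivariate normal, then the closed form
# -0.5 * log(1 - rho^2).
.miGaussianCopula <- function(x, y) {
  rs <- stats::cor(x, y, method = "spearman")
  rho <- 2 * sin(pi * rs / 6)
  rho <- max(min(rho, 1 - 1e-12), -(1 - 1e-12))
  max(-0.5 * log1p(-rho^2), 0)
}

#' Mutual information between two expression profiles
#'
#' Estimates the mutual information (in nats) between two continuous
#' vectors. The default estimator discretizes both vectors into
#' equal-frequency bins (cube-root rule, ceiling of n^(1/3), unless
#' overridden -- few enough bins that the Miller-Madow correction can
#' remove the finite-sample bias, so independent vectors score near 0)
#' and applies the Miller-Madow bias correction; the alternative maps the
#' Spearman correlation through the Gaussian copula closed form
#' -0.5 * log(1 - rho^2). Negative estimates are clipped at 0. A constant
#' vector yields 0 with a warning.
#'
#' @param x,y numeric vectors of equal length (>= 3)
#' @param config an \code{\link{inferenceConfig}} selecting the estimator
#'   and bin count
#' @return nonnegative mutual information estimate in nats
#' @examples
#' set.seed(1)
#' x <- rnorm(200)
#' mutualInformation(x, x + rnorm(200, sd = 0.2))
#' @export
mutualInformation <- function(x, y, config = inferenceConfig()) {
  stopIfNot(length(x) == length(y),
            "x and y must have equal length, got ",
            length(x), " and ", length(y))
  stopIfNot(length(x) >= 3, "need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: mutual information set to 0")
    return(0)
  }
  if (config@miEstimator == "spearman_gaussian")
    return(.miGaussianCopula(x, y))
  nBins <- if (config@nBins > 0) config@nBins else ceiling(length(x)^(1 / 3))
  .miFromBins(.discretize(x, nBins), .discretize(y, nBins), nBins)
}

#' Dense mutual-information network for one lineage
#'
#' Computes pairwise mutual information between all genes over the samples
#' of one lineage, returning the fully dense MI graph. Genes with constant
#' expression within the lineage are dropped with a message, since their MI
#' is undefined. Pair order and sample order do not affect the result.
#'
#' @param expr an \linkS4class{ExpressionMatrix}
#' @param lineage lineage name; must have at least 3 samples
#' @param config an \code{\link{inferenceConfig}}
#' @return a dense \linkS4class{GeneNetwork} with MI edge weights
#' @seealso \code{\link{applyDPI}}, \code{\link{pruneNetwork}}
#' @export
estimateMINetwork <- function(expr, lineage, config = inferenceConfig()) {
  lin <- sampleLineages(expr)
  stopIfNot(lineage %in% lin, "unknown lineage: ", lineage)
  smp <- names(lin)[lin == lineage]
  stopIfNot(length(smp) >= 3,
            "lineage '", lineage, "' has fewer than 3 samples")
  m <- assay(expr, "exprs")[, smp, drop = FALSE]
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    msg("dropping ", sum(sds == 0),
        " constant-expression gene(s) from lineage '", lineage, "'")
    m <- m[sds > 0, , drop = FALSE]
  }
  g <- nrow(m)
  stopIfNot(g >= 2, "need at least 2 non-constant genes")
  n <- ncol(m)
  if (config@miEstimator == "binned") {
    nBins <- if (config@nBins > 0) config@nBins else ceiling(n^(1 / 3))
    bins <- t(apply(m, 1, .discretize, nBins = nBins))
    pair <- function(i, j) .miFromBins(bins[i, ], bins[j, ], nBins)
  } else {
    ranks <- t(apply(m, 1, rank))
    pair <- function(i, j) {
      rho <- 2 * sin(pi * stats::cor(ranks[i, ], ranks[j, ]) / 6)
      rho <- max(min(rho, 1 - 1e-12), -(1 - 1e-12))
      max(-0.5 * log1p(-rho^2), 0)
    }
  }
  idx <- which(upper.tri(matrix(0, g, g)), arr.ind = TRUE)
  w <- vapply(seq_len(nrow(idx)),
              function(k) pair(idx[k, 1], idx[k, 2]), numeric(1))
  GeneNetwork(rownames(m),
              data.frame(from = rownames(m)[idx[, 1]],
                         to = rownames(m)[idx[, 2]], weight = w))
}

#' Data-processing-inequality pruning
#'
#' For every fully connected gene triple, the edge with the strictly
#' smallest mutual information is flagged as a likely indirect interaction
#' and removed when its weight is below the minimum of the other two edges
#' minus \code{tolerance}. Flags are computed on the input network and all
#' flagged edges are removed simultaneously, so the strongest edge of a
#' triangle is never removed and surviving weights are unchanged.
#'
#' @param net a \linkS4class{GeneNetwork} with MI weights
#' @param tolerance additive tolerance >= 0; a tolerance at or above the
#'   maximum weight disables pruning, as does \code{NA}
#' @return the pruned \linkS4class{GeneNetwork}
#' @export
applyDPI <- function(net, tolerance = 0) {
  if (is.na(tolerance)) return(net)
  stopIfNot(tolerance >= 0, "tolerance must be >= 0")
  e <- edgeTable(net)
  if (nrow(e) == 0) return(net)
  nodes <- genes(net)
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  i <- match(e$from, nodes); j <- match(e$to, nodes)
  W[cbind(i, j)] <- e$weight
  W[cbind(j, i)] <- e$weight
  drop <- logical(nrow(e))
  for (k in seq_len(nrow(e))) {
    both <- pmin(W[i[k], ], W[j[k], ])
    both[c(i[k], j[k])] <- 0
    m <- max(both)  # 0 when (i,j) closes no triangle
    drop[k] <- m > 0 && e$weight[k] < m - tolerance
  }
  GeneNetwork(nodes, e[!drop, , drop = FALSE])
}

#' Remove edges below a mutual-information cutoff
#'
#' Keeps exactly the edges with weight greater than or equal to
#' \code{miCutoff} ("edges with weights under the cutoff are removed").
#' Nodes are retained even when they become isolated, so network
#' membership is preserved. Pruning is idempotent and monotone in the
#' cutoff.
#'
#' @param net a \linkS4class{GeneNetwork}
#' @param miCutoff nonnegative cutoff on the MI edge weight
#' @return the pruned \linkS4class{GeneNetwork}
#' @export
pruneNetwork <- function(net, miCutoff) {
  stopIfNot(miCutoff >= 0, "miCutoff must be >= 0")
  e <- edgeTable(net)
  GeneNetwork(genes(net), e[e$weight >= miCutoff, , drop = FALSE])
}
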