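# Hyperparameter sweeps: dependency-cutoff and network-pruning-cutoff
# robustness curves.

#' Default dependency-cutoff sweep grid
#'
#' Cutoffs from -1.5 to 0.1 in 0.1 increments (17 points). The wider
#' -1.5 to 0.25 grid used in exploratory plots is available via
#' \code{extended = TRUE}.
#'
#' @param extended extend the grid to 0.25
#' @return increasing numeric grid
#' @export
dependencyCutoffGrid <- function(extended = FALSE) {
  grid <- seq(-1.5, 0.1, by = 0.1)
  if (extended) grid <- c(grid, 0.2, 0.25)
  grid
}

#' Default pruning-cutoff sweep grid
#'
#' The MI edge-weight cutoffs 0, 0.5, 1, 1.5, 2, 3, 4, 5, 10, 15, 20, 25.
#' These values live on the scale of the MI estimator that produced the
#' network weights; rescale when using a different estimator.
#'
#' @return increasing numeric grid
#' @export
pruningCutoffGrid <- function() c(0, 0.5, 1, 1.5, 2, 3, 4, 5, 10, 15, 20, 25)

#' Sweep the dependency binarization cutoff
#'
#' For each cutoff of the grid the lineage-mean scores are re-binarized
#' and the model re-trained and cross-validated. Cutoffs yielding a
#' degenerate class split (fewer than k instances of a class) are
#' recorded as missing rather than aborting the sweep.
#'
#' @param scores a \linkS4class{DependencyScores}
#' @param features a \linkS4class{FeatureTable} (or named per-lineage
#'   list) of predictors
#' @param spec a \code{\link{modelSpec}}
#' @param grid numeric cutoffs (sorted internally)
#' @param k folds
#' @param seed integer seed
#' @param lineage optional lineage restriction
#' @param minLines minimum cell lines per lineage
#' @return data.frame with one row per grid point: \code{cutoff},
#'   \code{f1_mean}, \code{f1_sd}, \code{n_dependent}, \code{status}
#' @export
sweepDependencyCutoff <- function(scores, features, spec,
                                  grid = dependencyCutoffGrid(), k = 5,
                                  seed = 1, lineage = NULL, minLines = 3) {
  stopIfNot(length(grid) > 0, "empty sweep grid")
  grid <- sort(unique(grid))
  rows <- lapply(grid, function(cut) {
    tryCatch({
      labels <- dependencyLabels(scores, cutoff = cut, minLines = minLines)
      cv <- crossvalF1(features, labels, spec, k, seed, lineage)
      data.frame(cutoff = cut, f1_mean = cv$f1_mean, f1_sd = cv$f1_sd,
                 n_dependent = cv$n_dependent, status = "ok")
    }, error = function(e) {
      data.frame(cutoff = cut, f1_mean = NA_real_, f1_sd = NA_real_,
                 n_dependent = NA_integer_, status = conditionMessage(e))
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sweep the network pruning cutoff
#'
#' Builds the dense per-lineage MI network once (with optional DPI
#' pruning), then for each cutoff of the grid re-prunes the network,
#' recomputes the four network feature classes, and re-trains and
#' cross-validates the model. Cutoffs leaving an empty network are
#' recorded as missing with a warning.
#'
#' @param expr an \linkS4class{ExpressionMatrix}
#' @param lineage lineage whose network is swept
#' @param scores a \linkS4class{DependencyScores}
#' @param geneSets a \linkS4class{GeneSetCollection}
#' @param spec a \code{\link{modelSpec}}
#' @param grid numeric nonnegative cutoffs (sorted internally)
#' @param config an \code{\link{inferenceConfig}} (its \code{miCutoff} is
#'   superseded by the grid)
#' @param labelCutoff dependency binarization cutoff (default -1)
#' @param pathMode passed to \code{\link{smallestWeightPathFeatures}}
#' @param k folds
#' @param seed integer seed
#' @return data.frame with one row per grid point: \code{cutoff},
#'   \code{n_edges}, \code{f1_mean}, \code{f1_sd}, \code{status}
#' @export
sweepPruningCutoff <- function(expr, lineage, scores, geneSets, spec,
                               grid = pruningCutoffGrid(),
                               config = inferenceConfig(),
                               labelCutoff = -1, pathMode = "raw",
                               k = 5, seed = 1) {
  stopIfNot(length(grid) > 0, "empty sweep grid")
  stopIfNot(all(grid >= 0), "pruning cutoffs must be >= 0")
  grid <- sort(unique(grid))
  dense <- estimateMINetwork(expr, lineage, config)
  dense <- applyDPI(dense, config@dpiTolerance)
  means <- aggregateScores(scores, lineage)
  rows <- lapply(grid, function(cut) {
    tryCatch({
      net <- pruneNetwork(dense, cut)
      if (numEdges(net) == 0) {
        warning("pruning cutoff ", cut, " leaves an empty network")
        stop("empty network at cutoff ", cut)
      }
      ft <- networkFeatures(net, geneSets, pathMode = pathMode)
      labels <- binarizeDependency(means, cutoff = labelCutoff, lineage)
      cv <- crossvalF1(ft, labels, spec, k, seed)
      data.frame(cutoff = cut, n_edges = numEdges(net),
                 f1_mean = cv$f1_mean, f1_sd = cv$f1_sd, status = "ok")
    }, error = function(e) {
      data.frame(cutoff = cut, n_edges = NA_integer_, f1_mean = NA_real_,
                 f1_sd = NA_real_, status = conditionMessage(e))
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
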