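# F1 scoring and stratified cross-validated evaluation of the model zoo.

.NETWORK_CLASSES <- c("traditional", "hallmark", "shortest_path",
                      "smallest_path")

#' F1 score from confusion counts
#'
#' F1 = 2PR/(P+R) with precision P = tp/(tp+fp) and recall
#' R = tp/(tp+fn), computed on the positive (dependent) class. When there
#' are no true positives but errors exist the score is 0; the degenerate
#' all-zero case returns 0 with a warning.
#'
#' @param tp,fp,fn nonnegative true-positive, false-positive and
#'   false-negative counts
#' @return F1 in [0, 1]
#' @examples
#' f1Score(12, 3, 8)  # precision 0.8, recall 0.6 -> 0.6857
#' @export
f1Score <- function(tp, fp, fn) {
  stopIfNot(tp >= 0 && fp >= 0 && fn >= 0, "counts must be nonnegative")
  if (tp == 0 && fp == 0 && fn == 0) {
    warning("f1Score undefined for tp = fp = fn = 0; returning 0")
    return(0)
  }
  if (tp == 0) return(0)
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

.f1FromPredictions <- function(truth, pred) {
  tp <- sum(pred == "dependent" & truth == "dependent")
  fp <- sum(pred == "dependent" & truth != "dependent")
  fn <- sum(pred != "dependent" & truth == "dependent")
  if (tp + fp + fn == 0) 0 else f1Score(tp, fp, fn)
}

# Stratified k-fold assignment: classes shuffled independently under the
# seed, then dealt round-robin so fold sizes and class balance are even.
.stratifiedFolds <- function(y, k, seed) {
  counts <- table(y)
  if (any(counts < k))
    stop("stratified ", k, "-fold CV needs at least ", k,
         " instances of each class; got ",
         paste(names(counts), counts, sep = "=", collapse = ", "),
         ". Lower k or revisit the dependency cutoff.", call. = FALSE)
  fold <- integer(length(y))
  withSeed(seed, {
    for (cl in names(counts)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Build a design matrix from features and labels
#'
#' Matches label rows to feature rows by gene id. \code{features} may be a
#' single \linkS4class{FeatureTable} (every labeled lineage reuses its
#' rows) or a named list of per-lineage tables, in which case instances
#' are (gene, lineage) pairs concatenated across lineages (the pooled
#' "pan-cancer" design). Labeled genes absent from the feature table --
#' e.g. genes dropped from the pruned network -- are excluded with a
#' message, not zero-imputed, since their network features are undefined.
#'
#' @param features a \linkS4class{FeatureTable} or named list of them
#'   keyed by lineage
#' @param labels a \linkS4class{DependencyLabels}
#' @param lineage optional lineage name(s) restricting the instances
#' @return list with the numeric matrix \code{X}, character \code{y},
#'   and the \code{gene} / \code{lineage} of every instance
#' @export
designMatrix <- function(features, labels, lineage = NULL) {
  tab <- labelTable(labels)
  if (!is.null(lineage)) tab <- tab[tab$lineage %in% lineage, , drop = FALSE]
  stopIfNot(nrow(tab) > 0, "no label instances selected")
  if (is(features, "FeatureTable")) {
    keep <- tab$gene %in% genes(features)
    if (any(!keep))
      msg("dropping ", sum(!keep), " labeled gene(s) absent from the ",
          "feature table")
    tab <- tab[keep, , drop = FALSE]
    X <- as.matrix(features)[tab$gene, , drop = FALSE]
  } else {
    stopIfNot(is.list(features) && !is.null(names(features)),
              "features must be a FeatureTable or a named list of them")
    pieces <- lapply(unique(tab$lineage), function(l) {
      stopIfNot(l %in% names(features),
                "no feature table for lineage: ", l)
      sub <- tab[tab$lineage == l, , drop = FALSE]
      keep <- sub$gene %in% genes(features[[l]])
      if (any(!keep))
        msg("lineage '", l, "': dropping ", sum(!keep),
            " labeled gene(s) absent from the feature table")
      sub <- sub[keep, , drop = FALSE]
      list(tab = sub,
           X = as.matrix(features[[l]])[sub$gene, , drop = FALSE])
    })
    tab <- do.call(rbind, lapply(pieces, `[[`, "tab"))
    X <- do.call(rbind, lapply(pieces, `[[`, "X"))
  }
  stopIfNot(nrow(tab) > 0, "no labeled genes present in the feature table")
  list(X = X, y = tab$label, gene = tab$gene, lineage = tab$lineage)
}

# Per-fold fits with train-fold-only z-scoring; shared by crossvalF1 and
# permutationImportance.
.cvFits <- function(X, y, spec, k, seed) {
  fold <- .stratifiedFolds(y, k, seed)
  lapply(seq_len(k), function(f) {
    tr <- fold != f
    ctr <- colMeans(X[tr, , drop = FALSE])
    scl <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    Xtr <- zscore(X[tr, , drop = FALSE], ctr, scl)
    Xte <- zscore(X[!tr, , drop = FALSE], ctr, scl)
    foldSpec <- spec
    foldSpec@seed <- as.integer((spec@seed * 131L + f) %% .Machine$integer.max)
    fit <- fitModel(foldSpec, Xtr, y[tr])
    list(fit = fit, Xtest = Xte, ytest = y[!tr])
  })
}

#' Cross-validated F1 of one model on one feature/label set
#'
#' Stratified k-fold cross-validation with folds shuffled under the seed.
#' Features are z-scored with means and standard deviations fit on each
#' training fold only; F1 is computed per fold on the positive
#' (dependent) class. Identical seeds give identical fold scores.
#'
#' @param features a \linkS4class{FeatureTable} or named list of them (see
#'   \code{\link{designMatrix}})
#' @param labels a \linkS4class{DependencyLabels}
#' @param spec a \code{\link{modelSpec}}
#' @param k number of folds (default 5)
#' @param seed integer seed for fold assignment and stochastic training
#' @param lineage optional lineage restriction
#' @return list with \code{f1_mean}, \code{f1_sd}, \code{fold_scores},
#'   \code{n_instances}, \code{n_dependent}
#' @export
crossvalF1 <- function(features, labels, spec, k = 5, seed = 1,
                       lineage = NULL) {
  d <- designMatrix(features, labels, lineage)
  folds <- .cvFits(d$X, d$y, spec, k, seed)
  scores <- vapply(folds, function(f)
    .f1FromPredictions(f$ytest, predictModel(f$fit, f$Xtest)), numeric(1))
  list(f1_mean = mean(scores), f1_sd = stats::sd(scores),
       fold_scores = scores, n_instances = nrow(d$X),
       n_dependent = sum(d$y == "dependent"))
}

.selectFeatureSet <- function(features, featureSet) {
  cls <- switch(featureSet,
                network = .NETWORK_CLASSES,
                expression = "expression",
                combined = c(.NETWORK_CLASSES, "expression"),
                stop("unknown feature set: ", featureSet))
  pick <- function(ft) {
    out <- selectClass(ft, cls)
    stopIfNot(ncol(out) > 0, "feature set '", featureSet,
              "' selects no columns (is the expression class present?)")
    out
  }
  if (is(features, "FeatureTable")) pick(features) else lapply(features, pick)
}

#' Run the ten-model zoo across feature sets
#'
#' Evaluates every requested model on every requested feature set
#' (\code{network} = the four engineered classes, \code{expression} =
#' per-gene expression summaries, \code{combined} = both) with
#' \code{\link{crossvalF1}}. Failures in individual grid cells are
#' recorded and do not abort the grid.
#'
#' @param features a \linkS4class{FeatureTable} (or named per-lineage
#'   list) containing the classes the requested feature sets need
#' @param labels a \linkS4class{DependencyLabels}
#' @param models character vector of zoo model names
#' @param featureSets subset of \code{c("network", "expression",
#'   "combined")}
#' @param k folds (default 5)
#' @param seed integer seed
#' @param lineage optional lineage restriction
#' @return data.frame with one row per model x feature set: \code{model},
#'   \code{feature_set}, \code{f1_mean}, \code{f1_sd}, fold scores,
#'   instance counts and a \code{status} column (\code{"ok"} or the error
#'   message)
#' @export
runModelZoo <- function(features, labels, models = modelZooNames(),
                        featureSets = c("network", "expression", "combined"),
                        k = 5, seed = 1, lineage = NULL) {
  bad <- setdiff(models, modelZooNames())
  stopIfNot(length(bad) == 0, "unknown model(s): ", paste(bad, collapse = ", "))
  grid <- expand.grid(model = models, feature_set = featureSets,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    mod <- grid$model[i]; fs <- grid$feature_set[i]
    res <- tryCatch({
      ft <- .selectFeatureSet(features, fs)
      cv <- crossvalF1(ft, labels, modelSpec(mod, seed = seed), k, seed,
                       lineage)
      data.frame(model = mod, feature_set = fs, f1_mean = cv$f1_mean,
                 f1_sd = cv$f1_sd,
                 t(stats::setNames(cv$fold_scores,
                                   paste0("fold", seq_along(cv$fold_scores)))),
                 n_instances = cv$n_instances,
                 n_dependent = cv$n_dependent, status = "ok")
    }, error = function(e) {
      data.frame(model = mod, feature_set = fs, f1_mean = NA_real_,
                 f1_sd = NA_real_,
                 t(stats::setNames(rep(NA_real_, k), paste0("fold", 1:k))),
                 n_instances = NA_integer_, n_dependent = NA_integer_,
                 status = conditionMessage(e))
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
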