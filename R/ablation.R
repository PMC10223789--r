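# Feature-class and single-feature ablations, and permutation importance.

.applyToFeatures <- function(features, f) {
  if (is(features, "FeatureTable")) f(features) else lapply(features, f)
}

#' Feature-class ablation
#'
#' Retrains and cross-validates the model with one (arity 1) or a pair
#' (arity 2) of the four engineered network feature classes removed,
#' using folds identical to the full model so the F1 delta isolates the
#' contribution of the removed class(es).
#'
#' @param features a \linkS4class{FeatureTable} (or named per-lineage
#'   list) carrying the four network classes
#' @param labels a \linkS4class{DependencyLabels}
#' @param spec a \code{\link{modelSpec}}
#' @param arity 1 (4 single ablations) or 2 (6 pairwise ablations)
#' @param k folds
#' @param seed integer seed (shared with the full-model run)
#' @param lineage optional lineage restriction
#' @return data.frame with one row per removed subset: \code{removed},
#'   \code{f1_mean}, \code{f1_sd}, \code{delta_vs_full}
#' @export
ablateClasses <- function(features, labels, spec, arity = 1, k = 5,
                          seed = 1, lineage = NULL) {
  stopIfNot(arity %in% c(1, 2), "arity must be 1 or 2")
  full <- crossvalF1(features, labels, spec, k, seed, lineage)
  subsets <- utils::combn(.NETWORK_CLASSES, arity, simplify = FALSE)
  rows <- lapply(subsets, function(rm) {
    ft <- .applyToFeatures(features, function(x) dropClasses(x, rm))
    cv <- crossvalF1(ft, labels, spec, k, seed, lineage)
    data.frame(removed = paste(rm, collapse = "+"),
               f1_mean = cv$f1_mean, f1_sd = cv$f1_sd,
               delta_vs_full = cv$f1_mean - full$f1_mean)
  })
  out <- do.call(rbind, rows)
  attr(out, "full_f1_mean") <- full$f1_mean
  attr(out, "full_f1_sd") <- full$f1_sd
  out
}

#' Single-feature ablation
#'
#' Retrains and cross-validates the model with one feature column removed
#' at a time, optionally restricted to the columns of one feature class.
#'
#' @inheritParams ablateClasses
#' @param classFilter optional feature class whose columns are ablated;
#'   default ablates every column
#' @return data.frame with one row per removed feature: \code{removed},
#'   \code{f1_mean}, \code{f1_sd}, \code{delta_vs_full}
#' @export
ablateSingleFeatures <- function(features, labels, spec, classFilter = NULL,
                                 k = 5, seed = 1, lineage = NULL) {
  proto <- if (is(features, "FeatureTable")) features else features[[1]]
  cls <- featureClasses(proto)
  cols <- if (is.null(classFilter)) names(cls) else {
    stopIfNot(all(classFilter %in% cls),
              "unknown feature class: ", paste(classFilter, collapse = ", "))
    names(cls)[cls %in% classFilter]
  }
  full <- crossvalF1(features, labels, spec, k, seed, lineage)
  rows <- lapply(cols, function(col) {
    ft <- .applyToFeatures(features, function(x) dropFeatures(x, col))
    cv <- crossvalF1(ft, labels, spec, k, seed, lineage)
    data.frame(removed = col, f1_mean = cv$f1_mean, f1_sd = cv$f1_sd,
               delta_vs_full = cv$f1_mean - full$f1_mean)
  })
  out <- do.call(rbind, rows)
  attr(out, "full_f1_mean") <- full$f1_mean
  out
}

#' Permutation feature importance
#'
#' For each cross-validation fold the model is fit on the training fold;
#' each feature column of the held-out fold is then shuffled
#' \code{nRepeats} times and the importance of the feature is the mean
#' drop in held-out F1 across folds and repeats. Deterministic under a
#' fixed seed.
#'
#' @inheritParams ablateClasses
#' @param nRepeats number of shuffles per feature per fold (>= 2)
#' @return data.frame with one row per feature: \code{feature},
#'   \code{class}, \code{importance_mean}, \code{importance_sd},
#'   \code{n_repeats}
#' @export
permutationImportance <- function(features, labels, spec, nRepeats = 10,
                                  k = 5, seed = 1, lineage = NULL) {
  stopIfNot(nRepeats >= 2, "nRepeats must be >= 2")
  d <- designMatrix(features, labels, lineage)
  folds <- .cvFits(d$X, d$y, spec, k, seed)
  p <- ncol(d$X)
  drops <- array(NA_real_, dim = c(length(folds), p, nRepeats))
  for (f in seq_along(folds)) {
    fl <- folds[[f]]
    base <- .f1FromPredictions(fl$ytest, predictModel(fl$fit, fl$Xtest))
    nte <- nrow(fl$Xtest)
    withSeed(seed * 7919L + f, {
      for (j in seq_len(p)) {
        for (r in seq_len(nRepeats)) {
          Xp <- fl$Xtest
          Xp[, j] <- Xp[sample.int(nte), j]
          drops[f, j, r] <- base -
            .f1FromPredictions(fl$ytest, predictModel(fl$fit, Xp))
        }
      }
    })
  }
  proto <- if (is(features, "FeatureTable")) features else features[[1]]
  cls <- featureClasses(proto)
  data.frame(
    feature = colnames(d$X),
    class = unname(cls[colnames(d$X)]),
    importance_mean = vapply(seq_len(p), function(j) mean(drops[, j, ]),
                             numeric(1)),
    importance_sd = vapply(seq_len(p), function(j) stats::sd(drops[, j, ]),
                           numeric(1)),
    n_repeats = nRepeats)
}
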