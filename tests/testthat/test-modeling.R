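# Shared small dataset with a strong planted signal, reused across blocks.
sepData <- local({
  cfg <- syntheticConfig(nGenes = 200L, nSamplesPerLineage = 12L,
                         nCgc = 8L, hallmarkSizes = rep(4L, 10),
                         plantedFeatures = "degree",
                         plantedEffectSizes = 2, noiseSd = 0.02,
                         geneNoiseSd = 0, signalQuantile = 1,
                         dependencyFraction = 0.2, seed = 21)
  generateSyntheticDataset(cfg)
})

test_that("f1Score matches closed forms and rejects bad counts", {
  expect_equal(f1Score(10, 0, 0), 1)
  expect_equal(f1Score(0, 5, 5), 0)
  expect_equal(f1Score(12, 3, 8), 2 * 0.48 / 1.4)  # P=0.8, R=0.6
  expect_error(f1Score(-1, 0, 0), "nonnegative")
  expect_warning(z <- f1Score(0, 0, 0), "undefined")
  expect_equal(z, 0)
})

test_that("f1Score agrees with a confusion-matrix oracle on random cases", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    truth <- rbinom(n, 1, 0.4)
    pred <- rbinom(n, 1, 0.5)
    tp <- sum(truth & pred); fp <- sum(!truth & pred)
    fn <- sum(truth & !pred)
    if (tp + fp + fn == 0) next
    expect_equal(f1Score(tp, fp, fn), bruteF1(truth, pred))
  }
})

test_that("cross-validation is deterministic and recovers a separable signal", {
  spec <- modelSpec("logistic_regression", seed = 2)
  ft <- selectClass(sepData@features, "traditional")
  a <- crossvalF1(ft, sepData@truthLabels, spec, seed = 5)
  b <- crossvalF1(ft, sepData@truthLabels, spec, seed = 5)
  expect_identical(a$fold_scores, b$fold_scores)
  expect_gte(a$f1_mean, 0.95)
  expect_equal(a$f1_mean, mean(a$fold_scores))
})

test_that("randomly permuted labels drop F1 to a prevalence-level baseline", {
  tl <- sepData@truthLabels
  t <- labelTable(tl)
  set.seed(8)
  t$label <- sample(t$label)
  t$mean_score <- ifelse(t$label == "dependent",
                         dependencyCutoff(tl) - 0.1,
                         dependencyCutoff(tl) + 0.1)
  shuffled <- new("DependencyLabels", table = t,
                  cutoff = dependencyCutoff(tl))
  cv <- crossvalF1(sepData@features, shuffled,
                   modelSpec("logistic_regression", seed = 3), seed = 3)
  expect_lt(cv$f1_mean, 0.5)
})

test_that("cross-validation demands enough instances of both classes", {
  t <- labelTable(sepData@truthLabels)
  t2 <- rbind(t[t$label == "dependent", ][1:3, ],
              t[t$label == "non_dependent", ][1:20, ])
  few <- new("DependencyLabels", table = t2,
             cutoff = dependencyCutoff(sepData@truthLabels))
  expect_error(
    crossvalF1(sepData@features, few, modelSpec("decision_tree")),
    "at least 5")
})

test_that("every zoo model is constructible and learns the separable signal", {
  # distance/kernel learners need the informative directions to dominate
  # the space, so the zoo runs on the hub-correlated topology class
  zoo <- runModelZoo(selectClass(sepData@features, "traditional"),
                     sepData@truthLabels, featureSets = "network", seed = 13)
  expect_equal(nrow(zoo), 10)
  expect_true(all(zoo$status == "ok"))
  expect_true(all(zoo$f1_mean >= 0.85),
              info = paste(zoo$model, round(zoo$f1_mean, 3), collapse = "; "))
  expect_gte(sum(zoo$f1_mean >= 0.9), 8)
})

test_that("feature-set selection drives the evaluation grid shape", {
  full <- assembleFeatures(list(sepData@features),
                           expressionSummaryFeatures(sepData@expression))
  one <- runModelZoo(full, sepData@truthLabels,
                     models = "decision_tree",
                     featureSets = c("network", "expression", "combined"),
                     seed = 4)
  expect_equal(nrow(one), 3)
  expect_setequal(one$feature_set, c("network", "expression", "combined"))
  expect_error(runModelZoo(full, sepData@truthLabels, models = "not_a_model"),
               "unknown model")
})

test_that("class ablation enumerates 4 single and 6 pairwise subsets", {
  spec <- modelSpec("logistic_regression", seed = 6)
  a1 <- ablateClasses(sepData@features, sepData@truthLabels, spec,
                      arity = 1, seed = 6)
  a2 <- ablateClasses(sepData@features, sepData@truthLabels, spec,
                      arity = 2, seed = 6)
  expect_equal(nrow(a1), 4)
  expect_equal(nrow(a2), 6)
  expect_setequal(a1$removed, c("traditional", "hallmark", "shortest_path",
                                "smallest_path"))
  expect_error(ablateClasses(sepData@features, sepData@truthLabels, spec,
                             arity = 3), "arity")
})

test_that("single-feature ablation covers the filtered class and tolerates redundancy", {
  spec <- modelSpec("logistic_regression", seed = 7)
  res <- ablateSingleFeatures(sepData@features, sepData@truthLabels, spec,
                              classFilter = "traditional", seed = 7)
  expect_equal(nrow(res), 5)
  expect_setequal(res$removed,
                  colnames(as.matrix(selectClass(sepData@features,
                                                 "traditional"))))

  # a perfectly collinear duplicate of a feature is expendable
  m <- as.matrix(sepData@features)
  dup <- cbind(m, degree_copy = m[, "degree"])
  ftDup <- FeatureTable(dup, c(featureClasses(sepData@features),
                               "traditional"))
  resDup <- ablateSingleFeatures(ftDup, sepData@truthLabels, spec,
                                 classFilter = "traditional", seed = 7)
  expect_lt(abs(resDup$delta_vs_full[resDup$removed == "degree_copy"]), 0.02)
  expect_error(ablateSingleFeatures(sepData@features, sepData@truthLabels,
                                    spec, classFilter = "bogus"), "unknown")
})

test_that("permutation importance is deterministic, null for noise, high for drivers", {
  spec <- modelSpec("logistic_regression", seed = 10)
  m <- as.matrix(selectClass(sepData@features, c("traditional", "hallmark")))
  set.seed(123)
  m <- cbind(m, pure_noise = rnorm(nrow(m)))
  ft <- FeatureTable(m, c(rep("traditional", 5), rep("hallmark", 10),
                          "expression"))
  imp1 <- permutationImportance(ft, sepData@truthLabels, spec,
                                nRepeats = 5, seed = 10)
  imp2 <- permutationImportance(ft, sepData@truthLabels, spec,
                                nRepeats = 5, seed = 10)
  expect_identical(imp1$importance_mean, imp2$importance_mean)
  expect_lt(abs(imp1$importance_mean[imp1$feature == "pure_noise"]), 0.02)
  expect_gt(imp1$importance_mean[imp1$feature == "degree"],
            max(imp1$importance_mean[imp1$feature == "pure_noise"], 0.05))
  expect_error(permutationImportance(ft, sepData@truthLabels, spec,
                                     nRepeats = 1), ">= 2")
})

test_that("dependency-cutoff sweep has the documented grid and a faithful single point", {
  expect_equal(length(dependencyCutoffGrid()), 17)
  expect_equal(dependencyCutoffGrid()[c(1, 17)], c(-1.5, 0.1))
  expect_equal(max(dependencyCutoffGrid(extended = TRUE)), 0.25)

  spec <- modelSpec("logistic_regression", seed = 2)
  sw <- sweepDependencyCutoff(sepData@scores, sepData@features, spec,
                              grid = -1, seed = 2,
                              minLines = 3)
  base <- crossvalF1(sepData@features,
                     dependencyLabels(sepData@scores, cutoff = -1),
                     spec, seed = 2)
  expect_equal(sw$f1_mean, base$f1_mean)
})

test_that("pruning sweep normalizes its grid and matches the unpruned baseline at zero", {
  cfg <- syntheticConfig(nGenes = 40L, nSamplesPerLineage = 30L, nCgc = 4L,
                         hallmarkSizes = rep(2L, 10), noiseSd = 0.4,
                         seed = 31)
  ds <- generateSyntheticDataset(cfg)
  spec <- modelSpec("logistic_regression", seed = 31)
  icfg <- inferenceConfig(miEstimator = "spearman_gaussian")
  sw <- sweepPruningCutoff(ds@expression, "lineage_1", ds@scores,
                           ds@geneSets, spec, grid = c(0.4, 0, 0.2),
                           config = icfg, seed = 31)
  expect_equal(sw$cutoff, c(0, 0.2, 0.4))

  dense <- applyDPI(estimateMINetwork(ds@expression, "lineage_1", icfg), 0)
  ft <- networkFeatures(dense, ds@geneSets)
  labels <- binarizeDependency(aggregateScores(ds@scores, "lineage_1"),
                               -1, "lineage_1")
  base <- crossvalF1(ft, labels, spec, seed = 31)
  expect_equal(sw$f1_mean[sw$cutoff == 0], base$f1_mean)
})
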