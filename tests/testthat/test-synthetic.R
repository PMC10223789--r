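test_that("preferential attachment with m=1 yields a tree, deterministically", {
  cfg <- syntheticConfig(nGenes = 4L, attachmentEdges = 1L, nCgc = 1L,
                         hallmarkSizes = rep(0L, 10), seed = 7)
  net <- generateNetwork(cfg)
  expect_equal(numEdges(net), 3)
  expect_equal(edgeTable(generateNetwork(cfg)), edgeTable(net))
  w <- edgeTable(net)$weight
  expect_true(all(w >= cfg@weightLow & w <= cfg@weightHigh))
  expect_error(generateNetwork(
    syntheticConfig(nGenes = 2L, attachmentEdges = 2L, nCgc = 1L,
                    hallmarkSizes = rep(0L, 10))),
    "attachmentEdges")
})

test_that("the degree distribution is heavy-tailed across seeds", {
  hits <- vapply(1:20, function(s) {
    net <- generateNetwork(syntheticConfig(nGenes = 500L, seed = s))
    deg <- igraph::degree(asIgraph(net))
    max(deg) >= 5 * stats::median(deg)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("gene sets are disjoint, sized as configured, and hub-biased", {
  cfg <- syntheticConfig(seed = 3)
  net <- generateNetwork(cfg)
  sets <- generateGeneSets(net, cfg)
  all10 <- hallmarkSets(sets)
  expect_equal(lengths(all10), setNames(rep(15L, 10), names(all10)))
  members <- c(cgcGenes(sets), unlist(all10))
  expect_false(anyDuplicated(members) > 0)

  deg <- igraph::degree(asIgraph(net))
  expect_gt(mean(deg[cgcGenes(sets)]), mean(deg))
})

test_that("expression on an edgeless network is independent noise", {
  cfg <- tinyConfig(nGenes = 20L, nSamplesPerLineage = 100L, nCgc = 2L,
                    hallmarkSizes = rep(1L, 10), seed = 5)
  net <- GeneNetwork(sprintf("g%02d", 1:20))
  expr <- generateExpression(net, cfg)
  cc <- cor(t(SummarizedExperiment::assay(expr, "exprs")))
  offDiag <- abs(cc[upper.tri(cc)])
  expect_lt(mean(offDiag), 3 / sqrt(100))
})

test_that("adjacent genes correlate more than non-adjacent genes across seeds", {
  wins <- vapply(1:10, function(s) {
    cfg <- syntheticConfig(nGenes = 50L, nSamplesPerLineage = 200L,
                           nCgc = 5L, hallmarkSizes = rep(2L, 10),
                           noiseSd = 0.5, seed = s)
    net <- generateNetwork(cfg)
    expr <- generateExpression(net, cfg)
    cc <- abs(cor(t(SummarizedExperiment::assay(expr, "exprs"))))
    e <- edgeTable(net)
    adj <- cc[cbind(e$from, e$to)]
    mask <- matrix(FALSE, 50, 50, dimnames = dimnames(cc))
    mask[cbind(e$from, e$to)] <- TRUE
    mask <- mask | t(mask)
    nonAdj <- cc[upper.tri(cc) & !mask]
    mean(adj) > mean(nonAdj)
  }, logical(1))
  expect_true(all(wins))
})

test_that("edge correlation approaches 1 as structural noise vanishes", {
  cfg <- tinyConfig(nGenes = 2L, nCgc = 1L, hallmarkSizes = rep(0L, 10),
                    nSamplesPerLineage = 50L, noiseSd = 1e-4, seed = 2)
  net <- GeneNetwork(c("g1", "g2"),
                     data.frame(from = "g1", to = "g2", weight = 2))
  expr <- generateExpression(net, cfg)
  m <- SummarizedExperiment::assay(expr, "exprs")
  expect_gt(abs(cor(m["g1", ], m["g2", ])), 0.999)
})

test_that("expression generation enforces the minimum lineage size", {
  cfg <- tinyConfig(seed = 1)
  net <- generateNetwork(cfg)
  cfgSmall <- tinyConfig(nSamplesPerLineage = 3L, seed = 1)
  expect_s4_class(generateExpression(net, cfgSmall), "ExpressionMatrix")
  cfgBad <- tinyConfig(seed = 1)
  cfgBad@nSamplesPerLineage <- 2L
  expect_error(generateExpression(net, cfgBad), "nSamplesPerLineage")
})

test_that("scores are a noiseless monotone function of a single planted feature", {
  cfg <- tinyConfig(plantedFeatures = "degree", plantedEffectSizes = 1,
                    noiseSd = 0, geneNoiseSd = 0, signalQuantile = 1,
                    seed = 4)
  net <- generateNetwork(cfg)
  sets <- generateGeneSets(net, cfg)
  feat <- networkFeatures(net, sets)
  # expression needs noiseSd > 0 is not required; scores come from features
  scores <- generateDependency(net, feat, cfg)
  m <- rowMeans(SummarizedExperiment::assay(scores, "score"))
  deg <- as.matrix(feat)[, "degree"][names(m)]
  ord <- order(deg)
  expect_true(all(diff(m[ord]) <= 1e-9))
})

test_that("the dependent fraction is calibrated within binomial tolerance", {
  cfg <- syntheticConfig(nGenes = 500L, dependencyFraction = 0.1, seed = 6)
  ds <- generateSyntheticDataset(cfg)
  nDep <- sum(labelTable(ds@truthLabels)$label == "dependent")
  expect_gte(nDep, 25)
  expect_lte(nDep, 75)
})

test_that("a planted feature missing from the table is rejected", {
  cfg <- tinyConfig(plantedFeatures = "not_a_feature",
                    plantedEffectSizes = 1, seed = 2)
  net <- generateNetwork(cfg)
  feat <- networkFeatures(net, generateGeneSets(net, cfg))
  expect_error(generateDependency(net, feat, cfg), "absent")
})

test_that("zero planted effects give chance-level downstream performance", {
  cfg <- syntheticConfig(nGenes = 250L, nSamplesPerLineage = 12L,
                         nCgc = 8L, hallmarkSizes = rep(4L, 10),
                         plantedEffectSizes = c(0, 0), seed = 17)
  ds <- generateSyntheticDataset(cfg)
  cv <- crossvalF1(ds@features, ds@truthLabels,
                   modelSpec("logistic_regression", seed = 17), seed = 17)
  expect_lt(cv$f1_mean, 0.5)
})

test_that("the full generator chain is deterministic under a fixed seed", {
  cfg <- tinyConfig(seed = 12)
  d1 <- generateSyntheticDataset(cfg)
  d2 <- generateSyntheticDataset(cfg)
  expect_identical(SummarizedExperiment::assay(d1@scores, "score"),
                   SummarizedExperiment::assay(d2@scores, "score"))
  expect_identical(SummarizedExperiment::assay(d1@expression, "exprs"),
                   SummarizedExperiment::assay(d2@expression, "exprs"))
  expect_identical(edgeTable(d1@network), edgeTable(d2@network))
  expect_identical(labelTable(d1@truthLabels), labelTable(d2@truthLabels))
})
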