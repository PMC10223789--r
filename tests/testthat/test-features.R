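pathABC <- GeneNetwork(c("a", "b", "c"),
                       data.frame(from = c("a", "b"), to = c("b", "c"),
                                  weight = c(1, 1)))

test_that("traditional features match hand-derived values on canonical graphs", {
  ft <- as.matrix(traditionalFeatures(pathABC))
  expect_equal(ft["b", "betweenness"], 1)
  expect_equal(ft["a", "betweenness"], 0)
  expect_equal(ft["b", "closeness"], 1)        # 2 reachable / 2 hops
  expect_equal(ft["a", "closeness"], 2 / 3)

  tri <- GeneNetwork(c("x", "y", "z"),
                     data.frame(from = c("x", "x", "y"),
                                to = c("y", "z", "z"), weight = rep(1, 3)))
  tm <- as.matrix(traditionalFeatures(tri))
  expect_equal(unname(tm[, "degree"]), rep(2, 3))
  expect_equal(unname(tm[, "sum_adjacent_weights"]), rep(2, 3))
  expect_equal(unname(tm[, "closeness"]), rep(1, 3))

  star <- GeneNetwork(c("hub", paste0("leaf", 1:4)),
                      data.frame(from = rep("hub", 4),
                                 to = paste0("leaf", 1:4),
                                 weight = 1:4))
  sm <- as.matrix(traditionalFeatures(star))
  expect_equal(sm["hub", "degree"], 4)
  expect_equal(sm["hub", "sum_adjacent_weights"], 10)
  expect_equal(sm["leaf1", "avg_neighbor_degree"], 4)
  expect_equal(sm["hub", "avg_neighbor_degree"], 1)
})

test_that("isolated nodes get zero for every traditional feature", {
  net <- GeneNetwork(c("a", "b", "lonely"),
                     data.frame(from = "a", to = "b", weight = 2))
  m <- as.matrix(traditionalFeatures(net))
  expect_equal(unname(m["lonely", ]), rep(0, 5))
})

test_that("hallmark neighbour counts equal a neighbour-by-neighbour tally", {
  net <- GeneNetwork(c("g", "A", "B", "C"),
                     data.frame(from = rep("g", 3), to = c("A", "B", "C"),
                                weight = rep(1, 3)))
  sets <- GeneSetCollection(
    c(list(h1 = c("A", "C")), setNames(rep(list("zzz"), 9),
                                        paste0("h", 2:10))),
    cgcGenes = "A")
  counts <- as.matrix(hallmarkNeighborCounts(net, sets))
  expect_equal(counts["g", "h1"], 2)
  expect_equal(sum(counts["A", ]), 0)

  for (s in 1:5) {
    g <- randomGraph(10, p = 0.4, seed = s)
    rs <- randomSets(g, seed = s + 100, setSize = 4)
    got <- as.matrix(hallmarkNeighborCounts(g, rs))
    adj <- depnet:::.adjacencyList(g)
    deg <- lengths(adj)
    for (v in genes(g)) {
      for (h in names(hallmarkSets(rs))) {
        tally <- 0
        for (nb in adj[[v]]) if (nb %in% hallmarkSets(rs)[[h]])
          tally <- tally + 1
        expect_equal(got[v, h], tally)
      }
      expect_true(all(got[v, ] <= deg[[v]]))
    }
  }
})

test_that("hop-path features match the path-graph example and use the sentinel", {
  sets <- GeneSetCollection(setNames(rep(list("c"), 10),
                                     paste0("h", 1:10)), cgcGenes = "c")
  m <- as.matrix(shortestPathFeatures(pathABC, sets))
  expect_equal(unname(m[, "sp_c"]), c(2, 1, 0))

  disc <- GeneNetwork(c("a", "b", "far"),
                      data.frame(from = "a", to = "b", weight = 1))
  # 'c' absent from the network entirely -> sentinel |nodes| everywhere
  md <- as.matrix(shortestPathFeatures(disc, sets))
  expect_equal(unname(md[, "sp_c"]), rep(3, 3))
})

test_that("hop-path features equal BFS on random graphs", {
  for (s in 1:8) {
    n <- sample(8:15, 1)
    net <- randomGraph(n, p = 0.25, seed = s)
    cgc <- genes(net)[1:3]
    sets <- GeneSetCollection(setNames(rep(list(cgc[1]), 10),
                                       paste0("h", 1:10)), cgcGenes = cgc)
    got <- as.matrix(shortestPathFeatures(net, sets))
    for (target in cgc) {
      d <- bruteBFS(net, target)
      d[is.infinite(d)] <- numNodes(net)
      expect_equal(unname(got[, paste0("sp_", target)]),
                   unname(d[genes(net)]), info = sprintf("seed %d", s))
    }
  }
})

test_that("smallest-weight paths minimize summed cost in both modes", {
  # two routes a->b->d (2.5) and a->c->d (3.0)
  net <- GeneNetwork(letters[1:4],
                     data.frame(from = c("a", "b", "a", "c"),
                                to = c("b", "d", "c", "d"),
                                weight = c(1, 1.5, 1, 2)))
  sets <- GeneSetCollection(setNames(rep(list("d"), 10),
                                     paste0("h", 1:10)), cgcGenes = "d")
  raw <- as.matrix(smallestWeightPathFeatures(net, sets, "raw"))
  expect_equal(raw["a", "wp_d"], 2.5)

  single <- GeneNetwork(c("u", "v"),
                        data.frame(from = "u", to = "v", weight = 4))
  ss <- GeneSetCollection(setNames(rep(list("v"), 10),
                                   paste0("h", 1:10)), cgcGenes = "v")
  expect_equal(
    as.matrix(smallestWeightPathFeatures(single, ss, "raw"))["u", "wp_v"], 4)
  expect_equal(
    as.matrix(smallestWeightPathFeatures(single, ss, "inverse"))["u", "wp_v"],
    0.25)

  bad <- GeneNetwork(c("u", "v"), data.frame(from = "u", to = "v",
                                             weight = 0))
  expect_error(smallestWeightPathFeatures(bad, ss), "positive")
})

test_that("smallest-weight paths equal exhaustive simple-path enumeration", {
  for (s in 1:6) {
    n <- sample(6:10, 1)
    net <- randomGraph(n, p = 0.35, seed = s + 50)
    cgc <- genes(net)[1:2]
    sets <- GeneSetCollection(setNames(rep(list(cgc[1]), 10),
                                       paste0("h", 1:10)), cgcGenes = cgc)
    for (mode in c("raw", "inverse")) {
      got <- as.matrix(smallestWeightPathFeatures(net, sets, mode))
      pol <- selectClass(smallestWeightPathFeatures(net, sets, mode),
                         "smallest_path")@sentinelPolicy$smallest_path
      for (target in cgc) {
        for (v in genes(net)) {
          expected <- bruteMinPath(net, v, target,
                                   invert = (mode == "inverse"))
          if (is.infinite(expected)) expected <- pol
          expect_equal(got[v, paste0("wp_", target)], expected,
                       info = sprintf("seed %d %s %s->%s", s, mode, v,
                                      target))
        }
      }
    }
  }
})

test_that("hop distances obey the triangle inequality on reachable triples", {
  net <- randomGraph(12, p = 0.3, seed = 9)
  cgc <- genes(net)[1:4]
  sets <- GeneSetCollection(setNames(rep(list(cgc[1]), 10),
                                     paste0("h", 1:10)), cgcGenes = cgc)
  m <- as.matrix(shortestPathFeatures(net, sets))
  sent <- numNodes(net)
  for (t1 in cgc) for (t2 in cgc) {
    d12 <- m[t1, paste0("sp_", t2)]
    if (d12 >= sent) next
    reach <- m[, paste0("sp_", t1)] < sent & m[, paste0("sp_", t2)] < sent
    expect_true(all(m[reach, paste0("sp_", t2)] <=
                      m[reach, paste0("sp_", t1)] + d12))
  }
})

test_that("with uniform weights the two path feature classes rank pairs identically", {
  net <- randomGraph(10, p = 0.4, seed = 3)
  e <- edgeTable(net); e$weight <- 2
  net <- GeneNetwork(genes(net), e)
  cgc <- genes(net)[1:3]
  sets <- GeneSetCollection(setNames(rep(list(cgc[1]), 10),
                                     paste0("h", 1:10)), cgcGenes = cgc)
  hop <- as.matrix(shortestPathFeatures(net, sets))
  ww <- as.matrix(smallestWeightPathFeatures(net, sets, "raw"))
  reach <- hop < numNodes(net)
  expect_equal(ww[reach], 2 * hop[reach])
})

test_that("assembled feature tables preserve class tags and column arithmetic", {
  cfg <- tinyConfig(nCgc = 20L, seed = 2)
  net <- generateNetwork(cfg)
  sets <- generateGeneSets(net, cfg)
  ft <- networkFeatures(net, sets)
  expect_equal(ncol(ft), 5 + 10 + 20 * 2)
  expect_equal(as.vector(table(featureClasses(ft))[
    c("traditional", "hallmark", "shortest_path", "smallest_path")]),
    c(5L, 10L, 20L, 20L))
  expect_equal(sort(colnames(as.matrix(selectClass(ft, "traditional")))),
               sort(c("degree", "avg_neighbor_degree",
                      "sum_adjacent_weights", "betweenness", "closeness")))
  expect_error(assembleFeatures(list()), "no feature tables")
  expect_error(assembleFeatures(list(traditionalFeatures(net),
                                     traditionalFeatures(net))),
               "duplicate")
  expect_error(dropClasses(ft, "nonexistent"), "unknown feature class")
})

test_that("feature computation is invariant to node ordering", {
  net <- randomGraph(9, p = 0.45, seed = 5)
  sets <- randomSets(net, seed = 6)
  perm <- sample(genes(net))
  netP <- GeneNetwork(perm, edgeTable(net))
  f1 <- as.matrix(networkFeatures(net, sets))
  f2 <- as.matrix(networkFeatures(netP, sets))
  expect_equal(f2[rownames(f1), colnames(f1)], f1)
})
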