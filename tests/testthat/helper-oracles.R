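# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (loops, exhaustive enumeration) so they share no code
# path with the implementation they check.

randomGraph <- function(n, p = 0.4, seed = 1, wlow = 0.5, whigh = 5) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < p
  edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                      weight = runif(sum(keep), wlow, whigh))
  GeneNetwork(ids, edges)
}

# adjacency helpers on the raw edge table
.oracleAdj <- function(net) {
  ids <- genes(net)
  e <- edgeTable(net)
  adj <- setNames(lapply(ids, function(i) character(0)), ids)
  for (k in seq_len(nrow(e))) {
    adj[[e$from[k]]] <- c(adj[[e$from[k]]], e$to[k])
    adj[[e$to[k]]] <- c(adj[[e$to[k]]], e$from[k])
  }
  adj
}

.oracleW <- function(net) {
  e <- edgeTable(net)
  w <- new.env()
  for (k in seq_len(nrow(e)))
    assign(paste(e$from[k], e$to[k]), e$weight[k], envir = w)
  function(a, b) {
    key <- paste(min(a, b), max(a, b))
    if (exists(key, envir = w)) get(key, envir = w) else NA_real_
  }
}

# DPI by explicit triangle enumeration: flag the strictly weakest edge of
# every triangle when below min(other two) - tol; remove all flags at once.
bruteDPI <- function(net, tol = 0) {
  ids <- genes(net)
  e <- edgeTable(net)
  wt <- .oracleW(net)
  flagged <- rep(FALSE, nrow(e))
  if (length(ids) >= 3) {
    for (trip in combn(ids, 3, simplify = FALSE)) {
      w12 <- wt(trip[1], trip[2]); w13 <- wt(trip[1], trip[3])
      w23 <- wt(trip[2], trip[3])
      if (any(is.na(c(w12, w13, w23)))) next
      for (k in seq_len(nrow(e))) {
        pair <- sort(c(e$from[k], e$to[k]))
        others <- c(w12, w13, w23)[!vapply(
          list(sort(trip[c(1, 2)]), sort(trip[c(1, 3)]),
               sort(trip[c(2, 3)])),
          identical, logical(1), pair)]
        if (length(others) == 2 && all(pair %in% trip) &&
            e$weight[k] < min(others) - tol)
          flagged[k] <- TRUE
      }
    }
  }
  GeneNetwork(ids, e[!flagged, , drop = FALSE])
}

# unweighted BFS hop distances from one source
bruteBFS <- function(net, from) {
  adj <- .oracleAdj(net)
  dist <- setNames(rep(Inf, length(adj)), names(adj))
  dist[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (u in adj[[v]]) {
      if (is.infinite(dist[u])) {
        dist[u] <- dist[v] + 1
        queue <- c(queue, u)
      }
    }
  }
  dist
}

# minimum summed edge cost over all simple paths (exhaustive DFS)
bruteMinPath <- function(net, from, to, invert = FALSE) {
  if (from == to) return(0)
  adj <- .oracleAdj(net)
  wt <- .oracleW(net)
  best <- Inf
  walk <- function(v, visited, acc) {
    if (acc >= best) return()
    for (u in adj[[v]]) {
      if (u %in% visited) next
      w <- wt(v, u)
      cost <- if (invert) 1 / w else w
      if (u == to) best <<- min(best, acc + cost)
      else walk(u, c(visited, u), acc + cost)
    }
  }
  walk(from, from, 0)
  best
}

# F1 from scratch off a confusion table, never via f1Score
bruteF1 <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  if (tp == 0) return(0)
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}

randomSets <- function(net, seed = 1, nCgc = 3, setSize = 3) {
  set.seed(seed)
  ids <- genes(net)
  hall <- setNames(lapply(1:10, function(i)
    sample(ids, min(setSize, length(ids)))),
    sprintf("hallmark_%02d", 1:10))
  GeneSetCollection(hall, sample(ids, min(nCgc, length(ids))))
}

# small fast synthetic config for structural tests; any argument of
# syntheticConfig() can be overridden
tinyConfig <- function(...) {
  args <- utils::modifyList(
    list(nGenes = 60L, nSamplesPerLineage = 12L, nCgc = 6L,
         hallmarkSizes = rep(3L, 10)),
    list(...))
  do.call(syntheticConfig, args)
}
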