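# The four engineered feature classes computed per gene on a pruned
# lineage network: classical topology, hallmark neighbour counts, and
# hop-count / smallest-weight paths to Cancer Gene Census genes.

.adjacencyList <- function(net) {
  nodes <- genes(net)
  e <- edgeTable(net)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (k in seq_along(adj)) adj[[k]] <- character(0)
  if (nrow(e)) {
    sp <- split(c(e$to, e$from), c(e$from, e$to))
    adj[names(sp)] <- sp
  }
  adj
}

#' Classical network topology features
#'
#' Computes the five traditional per-gene topology measures: degree,
#' average degree of first neighbours, sum of adjacent edge weights,
#' betweenness centrality and closeness centrality. Centralities are
#' computed on the unweighted graph in normalized form: betweenness is
#' divided by (n-1)(n-2)/2 and closeness is normalized within each
#' connected component (number reachable / total hop distance). Isolated
#' nodes get 0 for every measure.
#'
#' @param net a \linkS4class{GeneNetwork}
#' @return a \linkS4class{FeatureTable} with the 5 \code{traditional}
#'   columns
#' @export
traditionalFeatures <- function(net) {
  stopIfNot(numNodes(net) > 0, "network must be nonempty")
  g <- asIgraph(net)
  nodes <- genes(net)
  n <- length(nodes)
  deg <- igraph::degree(g)
  adj <- .adjacencyList(net)
  avgNbr <- vapply(nodes, function(v) {
    nb <- adj[[v]]
    if (length(nb) == 0) 0 else mean(deg[nb])
  }, numeric(1))
  sumW <- igraph::strength(g, weights = igraph::E(g)$weight)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  btw <- if (n > 2) btw / ((n - 1) * (n - 2) / 2) else rep(0, n)
  D <- igraph::distances(g, weights = NA)
  clo <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (length(d) == 0 || sum(d) == 0) 0 else length(d) / sum(d)
  }, numeric(1))
  v <- cbind(degree = as.numeric(deg)[match(nodes, names(deg))],
             avg_neighbor_degree = avgNbr,
             sum_adjacent_weights = as.numeric(sumW)[match(nodes, names(sumW))],
             betweenness = as.numeric(btw)[match(nodes, names(btw))],
             closeness = clo)
  rownames(v) <- nodes
  FeatureTable(v, "traditional")
}

#' Hallmark neighbour counts
#'
#' For every gene, counts its first-degree neighbours that belong to each
#' of the 10 cancer-hallmark gene sets, quantifying which cancer
#' capabilities lie in the gene's local network. A gene's own membership is
#' never counted and each count is bounded by the gene's degree.
#'
#' @param net a \linkS4class{GeneNetwork}
#' @param geneSets a \linkS4class{GeneSetCollection}
#' @return a \linkS4class{FeatureTable} with 10 \code{hallmark} columns
#' @export
hallmarkNeighborCounts <- function(net, geneSets) {
  adj <- .adjacencyList(net)
  sets <- hallmarkSets(geneSets)
  v <- vapply(sets, function(s)
    vapply(adj, function(nb) sum(nb %in% s), numeric(1)),
    numeric(length(adj)))
  v <- matrix(v, nrow = length(adj),
              dimnames = list(genes(net), names(sets)))
  FeatureTable(v, "hallmark")
}

.pathFeatureMatrix <- function(net, targets, weights, sentinel, prefix) {
  g <- asIgraph(net)
  nodes <- genes(net)
  present <- intersect(targets, nodes)
  v <- matrix(sentinel, nrow = length(nodes), ncol = length(targets),
              dimnames = list(nodes, paste0(prefix, targets)))
  if (length(present)) {
    D <- igraph::distances(g, to = present, weights = weights)
    D[!is.finite(D)] <- sentinel
    v[, paste0(prefix, present)] <- D[nodes, , drop = FALSE]
  }
  v
}

#' Hop-count shortest paths to CGC genes
#'
#' Records, per gene, the unweighted shortest-path length (hop count) to
#' every Cancer Gene Census gene. Distance to self is 0. Unreachable pairs
#' (and CGC genes absent from the network) are encoded with the sentinel
#' |nodes|, a finite value larger than any achievable hop count.
#'
#' @param net a \linkS4class{GeneNetwork}
#' @param geneSets a \linkS4class{GeneSetCollection}
#' @return a \linkS4class{FeatureTable} with one \code{shortest_path}
#'   column per CGC gene
#' @export
shortestPathFeatures <- function(net, geneSets) {
  sentinel <- numNodes(net)
  v <- .pathFeatureMatrix(net, cgcGenes(geneSets), NA, sentinel, "sp_")
  FeatureTable(v, "shortest_path",
               sentinelPolicy = list(shortest_path = sentinel))
}

#' Smallest-weight paths to CGC genes
#'
#' Records, per gene, the minimum over paths of the summed edge cost to
#' every Cancer Gene Census gene. In \code{"raw"} mode (the default) the
#' cost of an edge is its MI weight, i.e. the path minimizing the sum of
#' edge weights; in \code{"inverse"} mode the cost is 1/weight, the
#' conventional "strong edge = short distance" semantics. Unreachable
#' pairs are encoded with the sentinel (sum of all edge costs) + 1.
#'
#' @param net a \linkS4class{GeneNetwork}; all edge weights must be > 0
#' @param geneSets a \linkS4class{GeneSetCollection}
#' @param mode \code{"raw"} or \code{"inverse"}
#' @return a \linkS4class{FeatureTable} with one \code{smallest_path}
#'   column per CGC gene
#' @export
smallestWeightPathFeatures <- function(net, geneSets,
                                       mode = c("raw", "inverse")) {
  mode <- match.arg(mode)
  e <- edgeTable(net)
  stopIfNot(nrow(e) == 0 || all(e$weight > 0),
            "smallest-weight paths require strictly positive edge weights")
  cost <- if (mode == "raw") e$weight else 1 / e$weight
  sentinel <- sum(cost) + 1
  v <- .pathFeatureMatrix(net, cgcGenes(geneSets),
                          if (nrow(e)) cost else NA, sentinel, "wp_")
  FeatureTable(v, "smallest_path",
               sentinelPolicy = list(smallest_path = sentinel,
                                     smallest_path_mode = mode))
}

#' Per-gene expression summary features
#'
#' Mean and standard deviation of each gene's expression across the
#' samples of one lineage (or all samples), tagged as the
#' \code{expression} feature class.
#'
#' @param expr an \linkS4class{ExpressionMatrix}
#' @param lineage optional lineage name restricting the samples
#' @return a \linkS4class{FeatureTable} with columns \code{expr_mean},
#'   \code{expr_sd}
#' @export
expressionSummaryFeatures <- function(expr, lineage = NULL) {
  m <- assay(expr, "exprs")
  if (!is.null(lineage)) {
    lin <- sampleLineages(expr)
    stopIfNot(lineage %in% lin, "unknown lineage: ", lineage)
    m <- m[, names(lin)[lin == lineage], drop = FALSE]
  }
  v <- cbind(expr_mean = rowMeans(m), expr_sd = apply(m, 1, stats::sd))
  FeatureTable(v, "expression")
}

#' Assemble feature tables column-wise
#'
#' Concatenates feature tables (aligning on the intersection of their gene
#' universes; genes dropped by the alignment are reported) while
#' preserving class tags and sentinel policies. Duplicate column names are
#' an error.
#'
#' @param parts nonempty list of \linkS4class{FeatureTable}s
#' @param expressionSummary optional \code{expression}-class
#'   \linkS4class{FeatureTable} appended to the network features
#' @return the combined \linkS4class{FeatureTable}
#' @export
assembleFeatures <- function(parts, expressionSummary = NULL) {
  if (!is.null(expressionSummary)) parts <- c(parts, list(expressionSummary))
  stopIfNot(length(parts) > 0, "no feature tables to assemble")
  universes <- lapply(parts, genes)
  common <- Reduce(intersect, universes)
  dropped <- length(unique(unlist(universes))) - length(common)
  if (dropped > 0)
    msg("dropped ", dropped, " gene(s) absent from some feature table")
  stopIfNot(length(common) > 0, "empty gene universe after alignment")
  mats <- lapply(parts, function(p) as.matrix(p)[common, , drop = FALSE])
  v <- do.call(cbind, mats)
  stopIfNot(!anyDuplicated(colnames(v)), "duplicate feature column names")
  cls <- unlist(lapply(parts, function(p) p@featureClass))
  pol <- do.call(c, lapply(parts, function(p) p@sentinelPolicy))
  FeatureTable(v, cls, sentinelPolicy = as.list(pol))
}

#' All four network feature classes for a pruned lineage network
#'
#' Convenience wrapper computing and assembling the traditional, hallmark,
#' shortest-path and smallest-weight-path features.
#'
#' @param net a pruned \linkS4class{GeneNetwork}
#' @param geneSets a \linkS4class{GeneSetCollection}
#' @param pathMode \code{"raw"} or \code{"inverse"}, passed to
#'   \code{\link{smallestWeightPathFeatures}}
#' @return a \linkS4class{FeatureTable} with 5 + 10 + 2|CGC| columns
#' @examples
#' net <- GeneNetwork(c("a", "b", "c"),
#'                    data.frame(from = c("a", "b"), to = c("b", "c"),
#'                               weight = c(2, 1.5)))
#' sets <- GeneSetCollection(
#'   setNames(rep(list("c"), 10), paste0("hallmark_", 1:10)),
#'   cgcGenes = "c")
#' dim(networkFeatures(net, sets))
#' @export
networkFeatures <- function(net, geneSets, pathMode = "raw") {
  assembleFeatures(list(
    traditionalFeatures(net),
    hallmarkNeighborCounts(net, geneSets),
    shortestPathFeatures(net, geneSets),
    smallestWeightPathFeatures(net, geneSets, mode = pathMode)))
}
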