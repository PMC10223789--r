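#' @include AllGenerics.R
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
NULL

.FEATURE_CLASSES <- c("traditional", "hallmark", "shortest_path",
                      "smallest_path", "expression")

# ---------------------------------------------------------------------------
# GeneNetwork

#' Undirected weighted gene network
#'
#' Nodes are gene identifiers; edges carry a nonnegative weight, by
#' convention a mutual-information score between the two genes' expression
#' profiles. Edges are stored canonically (\code{from < to}), without
#' self-loops or duplicates. Isolated nodes are first-class members, so
#' pruning preserves network membership.
#'
#' @slot nodes character vector of unique gene ids
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{weight}
#' @export
setClass("GeneNetwork",
         slots = c(nodes = "character", edges = "data.frame"))

setValidity("GeneNetwork", function(object) {
  e <- object@edges
  n <- object@nodes
  if (anyDuplicated(n)) return("duplicate node ids")
  if (!identical(colnames(e), c("from", "to", "weight")))
    return("edges must have columns from, to, weight")
  if (nrow(e) == 0) return(TRUE)
  if (!all(e$from %in% n) || !all(e$to %in% n))
    return("edge endpoints must be network nodes")
  if (any(e$from == e$to)) return("self-loops are not allowed")
  if (!is.numeric(e$weight) || any(!is.finite(e$weight)) || any(e$weight < 0))
    return("edge weights must be finite and >= 0")
  if (any(e$from > e$to)) return("edges must be stored with from < to")
  if (anyDuplicated(paste(e$from, e$to))) return("duplicate edges")
  TRUE
})

#' Construct a GeneNetwork
#'
#' @param nodes character vector of gene ids
#' @param edges data.frame with columns \code{from}, \code{to},
#'   \code{weight}; pair order is canonicalized and need not be sorted
#' @return a \linkS4class{GeneNetwork}
#' @examples
#' net <- GeneNetwork(c("a", "b", "c"),
#'                    data.frame(from = c("a", "b"), to = c("b", "c"),
#'                               weight = c(2, 1.5)))
#' numEdges(net)
#' @export
GeneNetwork <- function(nodes,
                        edges = data.frame(from = character(),
                                           to = character(),
                                           weight = numeric())) {
  nodes <- as.character(nodes)
  edges <- as.data.frame(edges)[, c("from", "to", "weight")]
  a <- pmin(as.character(edges$from), as.character(edges$to))
  b <- pmax(as.character(edges$from), as.character(edges$to))
  edges <- data.frame(from = a, to = b, weight = as.numeric(edges$weight),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  new("GeneNetwork", nodes = nodes, edges = edges)
}

#' @rdname genes
#' @export
setMethod("genes", "GeneNetwork", function(x) x@nodes)

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "GeneNetwork", function(x) x@edges)

#' @rdname numNodes
#' @export
setMethod("numNodes", "GeneNetwork", function(x) length(x@nodes))

#' @rdname numNodes
#' @export
setMethod("numEdges", "GeneNetwork", function(x) nrow(x@edges))

#' @rdname asIgraph
#' @export
setMethod("asIgraph", "GeneNetwork", function(x) {
  igraph::graph_from_data_frame(x@edges, directed = FALSE,
                                vertices = data.frame(name = x@nodes))
})

setMethod("show", "GeneNetwork", function(object) {
  cat("GeneNetwork with", numNodes(object), "nodes and",
      numEdges(object), "edges\n")
  if (numEdges(object) > 0)
    cat(sprintf("  weight range: [%.4g, %.4g]\n",
                min(object@edges$weight), max(object@edges$weight)))
})

# ---------------------------------------------------------------------------
# ExpressionMatrix / DependencyScores

#' Expression matrix with lineage annotation
#'
#' A \linkS4class{SummarizedExperiment} holding a genes x samples matrix of
#' continuous (log-scale) expression in assay \code{"exprs"}, with a
#' \code{lineage} column in \code{colData} assigning every sample (cell
#' line) to a cancer lineage. Values must be complete: samples with missing
#' transcript values are expected to be filtered out upstream.
#'
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

#' CRISPR gene-effect score matrix with lineage annotation
#'
#' Same shape as \linkS4class{ExpressionMatrix}, holding gene-effect scores
#' in assay \code{"score"}. Scores are scaled so that the median of
#' ubiquitously essential genes is -1 and the median of nonessential genes
#' is 0; more negative means stronger dependency.
#'
#' @export
setClass("DependencyScores", contains = "SummarizedExperiment")

.validAssayObject <- function(object, assayName) {
  if (!assayName %in% SummarizedExperiment::assayNames(object))
    return(paste0("assay '", assayName, "' is required"))
  m <- SummarizedExperiment::assay(object, assayName)
  if (any(!is.finite(m))) return("values must be finite (no missing values)")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    return("unique gene ids (rownames) are required")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    return("unique sample ids (colnames) are required")
  if (!"lineage" %in% colnames(SummarizedExperiment::colData(object)))
    return("colData must contain a 'lineage' column")
  TRUE
}

setValidity("ExpressionMatrix", function(object)
  .validAssayObject(object, "exprs"))
setValidity("DependencyScores", function(object)
  .validAssayObject(object, "score"))

.makeAssayObject <- function(class, assayName, values, lineage) {
  values <- as.matrix(values)
  if (!is.null(names(lineage))) lineage <- lineage[colnames(values)]
  stopIfNot(length(lineage) == ncol(values),
            "one lineage per sample is required")
  se <- SummarizedExperiment(
    assays = stats::setNames(list(values), assayName),
    colData = DataFrame(lineage = as.character(lineage),
                        row.names = colnames(values)))
  new(class, se)
}

#' Construct an ExpressionMatrix
#'
#' @param values numeric genes x samples matrix with gene ids as rownames
#'   and sample ids as colnames
#' @param lineage character vector of lineage assignments, either in sample
#'   order or named by sample id
#' @return an \linkS4class{ExpressionMatrix}
#' @export
ExpressionMatrix <- function(values, lineage)
  .makeAssayObject("ExpressionMatrix", "exprs", values, lineage)

#' Construct a DependencyScores object
#'
#' @inheritParams ExpressionMatrix
#' @param values numeric genes x samples matrix of gene-effect scores
#' @return a \linkS4class{DependencyScores}
#' @export
DependencyScores <- function(values, lineage)
  .makeAssayObject("DependencyScores", "score", values, lineage)

#' @rdname lineages
#' @export
setMethod("lineages", "SummarizedExperiment", function(x)
  unique(as.character(SummarizedExperiment::colData(x)$lineage)))

#' @rdname lineages
#' @export
setMethod("sampleLineages", "SummarizedExperiment", function(x)
  stats::setNames(as.character(SummarizedExperiment::colData(x)$lineage),
                  colnames(x)))

#' @rdname genes
#' @export
setMethod("genes", "SummarizedExperiment", function(x) rownames(x))

# ---------------------------------------------------------------------------
# GeneSetCollection

#' Hallmark gene sets and the Cancer Gene Census list
#'
#' Holds the 10 cancer-hallmark gene sets (COSMIC Cancer Gene Census
#' hallmark categories) used for neighbour-count features, and the CGC gene
#' list used as path targets, optionally with per-gene evidence tiers.
#'
#' @slot hallmarkSets named list of exactly 10 character vectors
#' @slot cgcGenes character vector of cancer-census gene ids
#' @slot tiers integer vector of evidence tiers, either empty or one per
#'   CGC gene
#' @export
setClass("GeneSetCollection",
         slots = c(hallmarkSets = "list", cgcGenes = "character",
                   tiers = "integer"))

setValidity("GeneSetCollection", function(object) {
  h <- object@hallmarkSets
  if (length(h) != 10) return(sprintf("exactly 10 hallmark sets required, got %d", length(h)))
  if (is.null(names(h)) || anyDuplicated(names(h)) || any(names(h) == ""))
    return("hallmark sets must have unique non-empty names")
  if (!all(vapply(h, is.character, logical(1))))
    return("hallmark sets must be character vectors of gene ids")
  if (length(object@cgcGenes) == 0) return("CGC gene list must be nonempty")
  if (anyDuplicated(object@cgcGenes)) return("duplicate CGC genes")
  if (length(object@tiers) > 0 &&
      length(object@tiers) != length(object@cgcGenes))
    return("tiers must be empty or one per CGC gene")
  TRUE
})

#' Construct a GeneSetCollection
#'
#' @param hallmarkSets named list of exactly 10 character vectors;
#'   duplicate members within a set are removed with a message
#' @param cgcGenes character vector of Cancer Gene Census gene ids
#' @param tiers optional integer evidence tier per CGC gene
#' @return a \linkS4class{GeneSetCollection}
#' @export
GeneSetCollection <- function(hallmarkSets, cgcGenes, tiers = integer()) {
  hallmarkSets <- lapply(hallmarkSets, function(s) {
    s <- as.character(s)
    if (anyDuplicated(s)) {
      msg("removed ", sum(duplicated(s)), " duplicate genes within a hallmark set")
      s <- unique(s)
    }
    s
  })
  new("GeneSetCollection", hallmarkSets = hallmarkSets,
      cgcGenes = as.character(cgcGenes), tiers = as.integer(tiers))
}

#' @rdname hallmarkSets
#' @export
setMethod("hallmarkSets", "GeneSetCollection", function(x) x@hallmarkSets)

#' @rdname hallmarkSets
#' @export
setMethod("cgcGenes", "GeneSetCollection", function(x) x@cgcGenes)

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection: 10 hallmark sets (sizes",
      paste(vapply(object@hallmarkSets, length, integer(1)), collapse = ", "),
      ") and", length(object@cgcGenes), "CGC genes\n")
})

# ---------------------------------------------------------------------------
# FeatureTable

#' Per-gene feature table with class tags
#'
#' A genes x features numeric matrix in which every column is tagged with
#' the feature class it belongs to: \code{traditional} (5 classical
#' topology measures), \code{hallmark} (10 hallmark neighbour counts),
#' \code{shortest_path} / \code{smallest_path} (one column per CGC gene),
#' or \code{expression} (per-gene expression summaries). The
#' \code{sentinelPolicy} records how unreachable path distances were
#' encoded.
#'
#' @slot values numeric matrix, genes as rows
#' @slot featureClass character vector, one class tag per column
#' @slot sentinelPolicy named list describing sentinel encodings
#' @export
setClass("FeatureTable",
         slots = c(values = "matrix", featureClass = "character",
                   sentinelPolicy = "list"))

setValidity("FeatureTable", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("feature values must be numeric")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    return("unique gene rownames required")
  if (ncol(v) > 0 && (is.null(colnames(v)) || anyDuplicated(colnames(v))))
    return("unique feature colnames required")
  if (length(object@featureClass) != ncol(v))
    return("one class tag per feature column required")
  if (!all(object@featureClass %in% .FEATURE_CLASSES))
    return(paste("class tags must be in:",
                 paste(.FEATURE_CLASSES, collapse = ", ")))
  if (any(!is.finite(v))) return("feature values must be finite")
  TRUE
})

#' Construct a FeatureTable
#'
#' @param values numeric matrix with gene rownames and feature colnames
#' @param featureClass character vector of class tags (recycled if length 1)
#' @param sentinelPolicy named list describing sentinel encodings for
#'   unreachable paths
#' @return a \linkS4class{FeatureTable}
#' @export
FeatureTable <- function(values, featureClass, sentinelPolicy = list()) {
  values <- as.matrix(values)
  if (length(featureClass) == 1)
    featureClass <- rep(featureClass, ncol(values))
  new("FeatureTable", values = values,
      featureClass = as.character(featureClass),
      sentinelPolicy = sentinelPolicy)
}

#' @rdname featureClasses
#' @export
setMethod("featureClasses", "FeatureTable", function(x)
  stats::setNames(x@featureClass, colnames(x@values)))

#' @rdname genes
#' @export
setMethod("genes", "FeatureTable", function(x) rownames(x@values))

#' @export
setMethod("dim", "FeatureTable", function(x) dim(x@values))

#' Feature matrix of a FeatureTable
#'
#' @param x a \linkS4class{FeatureTable}
#' @param ... ignored
#' @return the underlying numeric matrix
#' @export
setMethod("as.matrix", "FeatureTable", function(x, ...) x@values)

#' @rdname selectClass
#' @export
setMethod("selectClass", "FeatureTable", function(x, classes) {
  keep <- x@featureClass %in% classes
  FeatureTable(x@values[, keep, drop = FALSE], x@featureClass[keep],
               x@sentinelPolicy)
})

#' @rdname selectClass
#' @export
setMethod("dropClasses", "FeatureTable", function(x, classes) {
  bad <- setdiff(classes, x@featureClass)
  stopIfNot(length(bad) == 0,
            "unknown feature class: ", paste(bad, collapse = ", "))
  selectClass(x, setdiff(unique(x@featureClass), classes))
})

#' @rdname dropFeatures
#' @export
setMethod("dropFeatures", "FeatureTable", function(x, features) {
  bad <- setdiff(features, colnames(x@values))
  stopIfNot(length(bad) == 0,
            "unknown feature: ", paste(bad, collapse = ", "))
  keep <- !colnames(x@values) %in% features
  FeatureTable(x@values[, keep, drop = FALSE], x@featureClass[keep],
               x@sentinelPolicy)
})

setMethod("show", "FeatureTable", function(object) {
  cat("FeatureTable:", nrow(object@values), "genes x",
      ncol(object@values), "features\n")
  tab <- table(factor(object@featureClass, levels = .FEATURE_CLASSES))
  tab <- tab[tab > 0]
  if (length(tab))
    cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# DependencyLabels

#' Binary dependency labels per (gene, lineage)
#'
#' Lineage-mean gene-effect scores with their binarized dependent /
#' non-dependent call. A gene is dependent in a lineage when its mean score
#' is less than or equal to the cutoff (default -1, the median score of
#' ubiquitously essential genes).
#'
#' @slot table data.frame with columns \code{gene}, \code{lineage},
#'   \code{mean_score}, \code{label}
#' @slot cutoff numeric binarization cutoff used
#' @export
setClass("DependencyLabels",
         slots = c(table = "data.frame", cutoff = "numeric"))

setValidity("DependencyLabels", function(object) {
  t <- object@table
  need <- c("gene", "lineage", "mean_score", "label")
  if (!all(need %in% colnames(t)))
    return(paste("label table needs columns:", paste(need, collapse = ", ")))
  if (!all(t$label %in% c("dependent", "non_dependent")))
    return("labels must be 'dependent' or 'non_dependent'")
  ok <- (t$mean_score <= object@cutoff) == (t$label == "dependent")
  if (!all(ok)) return("label must equal (mean_score <= cutoff)")
  TRUE
})

#' @rdname labelTable
#' @export
setMethod("labelTable", "DependencyLabels", function(x) x@table)

#' @rdname dependencyCutoff
#' @export
setMethod("dependencyCutoff", "DependencyLabels", function(x) x@cutoff)

setMethod("show", "DependencyLabels", function(object) {
  t <- object@table
  cat("DependencyLabels:", nrow(t), "(gene, lineage) calls at cutoff",
      object@cutoff, "\n")
  cat("  dependent:", sum(t$label == "dependent"), "of", nrow(t), "\n")
})

# ---------------------------------------------------------------------------
# ModelSpec

.MODEL_ZOO <- c("adaboost", "decision_tree", "gaussian_process", "knn",
                "linear_svc", "logistic_regression", "random_forest",
                "ridge", "sgd_linear_svc", "rbf_svc")

#' Names of the ten classifiers in the model zoo
#'
#' @return character vector of model names accepted by
#'   \code{\link{modelSpec}}
#' @export
modelZooNames <- function() .MODEL_ZOO

#' Classifier specification
#'
#' Identifies one of the ten classifiers in the model zoo together with
#' optional hyperparameter overrides (library defaults are used otherwise)
#' and the seed controlling any stochastic element of training.
#'
#' @slot name one of \code{modelZooNames()}
#' @slot hyperparameters named list of overrides
#' @slot seed integer RNG seed
#' @export
setClass("ModelSpec",
         slots = c(name = "character", hyperparameters = "list",
                   seed = "integer"))

setValidity("ModelSpec", function(object) {
  if (length(object@name) != 1 || !object@name %in% .MODEL_ZOO)
    return(paste("model name must be one of:",
                 paste(.MODEL_ZOO, collapse = ", ")))
  TRUE
})

#' Construct a ModelSpec
#'
#' @param name one of \code{modelZooNames()}
#' @param hyperparameters named list of hyperparameter overrides
#' @param seed integer seed for stochastic training steps
#' @return a \linkS4class{ModelSpec}
#' @examples
#' modelSpec("logistic_regression")
#' @export
modelSpec <- function(name, hyperparameters = list(), seed = 1L) {
  new("ModelSpec", name = name, hyperparameters = hyperparameters,
      seed = as.integer(seed))
}

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec:", object@name, "(seed", paste0(object@seed, ")"), "\n")
})

# ---------------------------------------------------------------------------
# InferenceConfig

#' Network inference configuration
#'
#' @slot miEstimator \code{"binned"} (equal-frequency binning with
#'   Miller-Madow correction) or \code{"spearman_gaussian"}
#'   (Spearman-to-Gaussian-copula closed form)
#' @slot nBins number of bins for the binned estimator; 0 means automatic
#'   (cube-root rule, ceiling of n^(1/3))
#' @slot dpiTolerance additive data-processing-inequality tolerance;
#'   \code{NA} disables DPI pruning
#' @slot miCutoff mutual-information edge cutoff: edges with weight below
#'   the cutoff are removed. Note the cutoff lives on the scale of the
#'   chosen estimator and is not transferable across estimators.
#' @slot perLineageCutoff named numeric vector of per-lineage cutoff
#'   overrides (e.g. a larger cutoff for a lineage with an unusually large
#'   network)
#' @export
setClass("InferenceConfig",
         slots = c(miEstimator = "character", nBins = "integer",
                   dpiTolerance = "numeric", miCutoff = "numeric",
                   perLineageCutoff = "numeric"))

setValidity("InferenceConfig", function(object) {
  if (!object@miEstimator %in% c("binned", "spearman_gaussian"))
    return("miEstimator must be 'binned' or 'spearman_gaussian'")
  if (!is.na(object@dpiTolerance) && object@dpiTolerance < 0)
    return("dpiTolerance must be >= 0 (or NA to disable)")
  if (object@miCutoff < 0) return("miCutoff must be >= 0")
  TRUE
})

#' Construct an InferenceConfig
#'
#' @param miEstimator mutual-information estimator (see
#'   \linkS4class{InferenceConfig})
#' @param nBins bins for the binned estimator (0 = automatic)
#' @param dpiTolerance DPI tolerance; \code{NA} disables DPI
#' @param miCutoff edge-weight pruning cutoff (default 1.5)
#' @param perLineageCutoff named numeric per-lineage cutoff overrides
#' @return an \linkS4class{InferenceConfig}
#' @export
inferenceConfig <- function(miEstimator = "binned", nBins = 0L,
                            dpiTolerance = 0, miCutoff = 1.5,
                            perLineageCutoff = numeric()) {
  new("InferenceConfig", miEstimator = miEstimator, nBins = as.integer(nBins),
      dpiTolerance = as.numeric(dpiTolerance),
      miCutoff = as.numeric(miCutoff),
      perLineageCutoff = perLineageCutoff)
}

.lineageCutoff <- function(config, lineage) {
  if (length(config@perLineageCutoff) &&
      lineage %in% names(config@perLineageCutoff))
    unname(config@perLineageCutoff[lineage])
  else config@miCutoff
}
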