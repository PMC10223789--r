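#' @import methods
NULL

#' Gene identifiers of an object
#'
#' @param x an object carrying gene identifiers
#' @return character vector of gene ids
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' Edge table of a gene network
#'
#' @param x a \linkS4class{GeneNetwork}
#' @return data.frame with columns \code{from}, \code{to}, \code{weight}
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' Number of nodes / edges
#'
#' @param x a \linkS4class{GeneNetwork}
#' @return integer count
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname numNodes
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' Convert to an igraph graph
#'
#' @param x a \linkS4class{GeneNetwork}
#' @return an \code{igraph} undirected weighted graph
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' Feature class tags of a feature table
#'
#' @param x a \linkS4class{FeatureTable}
#' @return named character vector, one class tag per feature column
#' @export
setGeneric("featureClasses", function(x) standardGeneric("featureClasses"))

#' Subset a feature table by feature class
#'
#' @param x a \linkS4class{FeatureTable}
#' @param classes class tags to keep (\code{selectClass}) or drop
#'   (\code{dropClasses})
#' @return a \linkS4class{FeatureTable}
#' @export
setGeneric("selectClass", function(x, classes) standardGeneric("selectClass"))

#' @rdname selectClass
#' @export
setGeneric("dropClasses", function(x, classes) standardGeneric("dropClasses"))

#' Drop named feature columns
#'
#' @param x a \linkS4class{FeatureTable}
#' @param features column names to drop
#' @return a \linkS4class{FeatureTable}
#' @export
setGeneric("dropFeatures", function(x, features) standardGeneric("dropFeatures"))

#' Label table of dependency calls
#'
#' @param x a \linkS4class{DependencyLabels}
#' @return data.frame with columns \code{gene}, \code{lineage},
#'   \code{mean_score}, \code{label}
#' @export
setGeneric("labelTable", function(x) standardGeneric("labelTable"))

#' Dependency cutoff used for binarization
#'
#' @param x a \linkS4class{DependencyLabels}
#' @return numeric cutoff
#' @export
setGeneric("dependencyCutoff", function(x) standardGeneric("dependencyCutoff"))

#' Lineages represented in an assay object
#'
#' @param x an \linkS4class{ExpressionMatrix} or
#'   \linkS4class{DependencyScores}
#' @return character vector of lineage names (\code{lineages}) or a named
#'   vector mapping sample id to lineage (\code{sampleLineages})
#' @export
setGeneric("lineages", function(x) standardGeneric("lineages"))

#' @rdname lineages
#' @export
setGeneric("sampleLineages", function(x) standardGeneric("sampleLineages"))

#' Hallmark gene sets and Cancer Gene Census accessors
#'
#' @param x a \linkS4class{GeneSetCollection}
#' @return \code{hallmarkSets}: named list of 10 character vectors;
#'   \code{cgcGenes}: character vector
#' @export
setGeneric("hallmarkSets", function(x) standardGeneric("hallmarkSets"))

#' @rdname hallmarkSets
#' @export
setGeneric("cgcGenes", function(x) standardGeneric("cgcGenes"))
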