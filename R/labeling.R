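# Lineage-level aggregation of CRISPR gene-effect scores and binarization
# into dependent / non-dependent labels.

#' Lineage-mean gene-effect scores
#'
#' Arithmetic mean of each gene's CRISPR gene-effect score across the cell
#' lines of one lineage. Lineages with fewer than 3 cell lines are
#' rejected, mirroring the cohort exclusion rule.
#'
#' @param scores a \linkS4class{DependencyScores}
#' @param lineage lineage name
#' @return named numeric vector of per-gene mean scores
#' @export
aggregateScores <- function(scores, lineage) {
  lin <- sampleLineages(scores)
  stopIfNot(lineage %in% lin, "unknown lineage: ", lineage)
  smp <- names(lin)[lin == lineage]
  stopIfNot(length(smp) >= 3,
            "lineage '", lineage, "' has fewer than 3 cell lines")
  rowMeans(assay(scores, "score")[, smp, drop = FALSE])
}

#' Binarize mean dependency scores
#'
#' A gene is labeled \code{dependent} when its lineage-mean score is below
#' or equal to the cutoff (default -1, the median score of ubiquitously
#' essential genes), and \code{non_dependent} otherwise. The tie at the
#' cutoff is labeled dependent. Raising the cutoff never shrinks the
#' dependent set.
#'
#' @param means named numeric vector of per-gene mean scores (from
#'   \code{\link{aggregateScores}})
#' @param cutoff binarization cutoff (default -1)
#' @param lineage lineage name recorded in the result
#' @return a \linkS4class{DependencyLabels}
#' @examples
#' binarizeDependency(c(g1 = -1.0, g2 = -0.99), cutoff = -1)
#' @export
binarizeDependency <- function(means, cutoff = -1, lineage = "all") {
  stopIfNot(!is.null(names(means)), "means must be named by gene")
  tab <- data.frame(
    gene = names(means), lineage = lineage,
    mean_score = as.numeric(means),
    label = ifelse(means <= cutoff, "dependent", "non_dependent"),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  new("DependencyLabels", table = tab, cutoff = as.numeric(cutoff))
}

#' Dependency labels for every lineage of a score matrix
#'
#' Applies \code{\link{aggregateScores}} and
#' \code{\link{binarizeDependency}} to each lineage with at least
#' \code{minLines} cell lines and concatenates the per-lineage calls.
#'
#' @param scores a \linkS4class{DependencyScores}
#' @param cutoff binarization cutoff (default -1)
#' @param minLines minimum cell lines per lineage (default 3)
#' @return a \linkS4class{DependencyLabels} spanning all retained lineages
#' @export
dependencyLabels <- function(scores, cutoff = -1, minLines = 3) {
  lin <- sampleLineages(scores)
  counts <- table(lin)
  keep <- names(counts)[counts >= minLines]
  stopIfNot(length(keep) > 0, "no lineage with >= ", minLines, " cell lines")
  if (length(keep) < length(counts))
    msg("excluding ", length(counts) - length(keep),
        " lineage(s) with fewer than ", minLines, " cell lines")
  tabs <- lapply(keep, function(l)
    labelTable(binarizeDependency(aggregateScores(scores, l), cutoff, l)))
  new("DependencyLabels", table = do.call(rbind, tabs),
      cutoff = as.numeric(cutoff))
}
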