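# Cohort filtering and the end-to-end pipeline driver.

#' Restrict expression and scores to a common cohort
#'
#' Restricts both matrices to the samples present in expression, scores
#' and (if given) an external cohort index, then drops lineages with
#' fewer than \code{minLines} cell lines. All filter counts are reported.
#'
#' @param expr an \linkS4class{ExpressionMatrix}
#' @param scores a \linkS4class{DependencyScores}
#' @param cohortIndex optional character vector of sample ids to retain
#'   (e.g. a curated cell-line index)
#' @param minLines minimum cell lines per lineage (default 3)
#' @return list with the filtered \code{expression} and \code{scores}
#' @export
applyCohortFilters <- function(expr, scores, cohortIndex = NULL,
                               minLines = 3) {
  common <- intersect(colnames(expr), colnames(scores))
  if (!is.null(cohortIndex)) common <- intersect(common, cohortIndex)
  stopIfNot(length(common) > 0, "empty sample intersection")
  dropped <- length(union(colnames(expr), colnames(scores))) - length(common)
  if (dropped > 0) msg("cohort filter: dropped ", dropped, " sample(s)")
  lin <- sampleLineages(expr)[common]
  counts <- table(lin)
  keepLin <- names(counts)[counts >= minLines]
  if (length(keepLin) < length(counts))
    msg("cohort filter: excluded ", length(counts) - length(keepLin),
        " lineage(s) with fewer than ", minLines, " cell lines")
  keep <- common[lin %in% keepLin]
  stopIfNot(length(keep) > 0, "no samples left after lineage filter")
  list(expression = expr[, keep], scores = scores[, keep])
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes the expression TSV, lineage annotation TSV, scores TSV,
#' hallmark GMT, CGC list, ground-truth network TSV, and a truth JSON
#' holding the truth labels, planted feature weights and generating
#' configuration.
#'
#' @param ds a \linkS4class{SyntheticDataset}
#' @param outdir output directory (created if absent)
#' @return the output directory, invisibly
#' @export
writeSyntheticDataset <- function(ds, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  writeExpressionMatrix(ds@expression, p("expression.tsv"),
                        p("annotations.tsv"))
  writeDependencyScores(ds@scores, p("scores.tsv"))
  writeGeneSets(ds@geneSets, p("hallmarks.gmt"), p("cgc.txt"))
  writeNetwork(ds@network, p("network_truth.tsv"))
  cfg <- ds@config
  truth <- list(
    labels = labelTable(ds@truthLabels),
    cutoff = dependencyCutoff(ds@truthLabels),
    planted_feature_weights = as.list(ds@truthFeatureWeights),
    config = list(nGenes = cfg@nGenes,
                  nSamplesPerLineage = cfg@nSamplesPerLineage,
                  nLineages = cfg@nLineages, seed = cfg@seed,
                  noiseSd = cfg@noiseSd,
                  dependencyFraction = cfg@dependencyFraction))
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(outdir)
}

.defaultPipelineConfig <- function() {
  list(miEstimator = "binned", nBins = 0, dpiTolerance = 0, miCutoff = 1.5,
       perLineageCutoff = list(), labelCutoff = -1, pathMode = "raw",
       models = "logistic_regression",
       featureSets = c("network", "expression", "combined"),
       lineages = NULL, minLines = 3, k = 5, seed = 1)
}

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or YAML file) with the input paths
#' \code{expression}, \code{annotations}, \code{scores},
#' \code{hallmarkGmt}, \code{cgc} plus optional analysis settings
#' (\code{miEstimator}, \code{nBins}, \code{dpiTolerance},
#' \code{miCutoff}, \code{perLineageCutoff}, \code{labelCutoff},
#' \code{pathMode}, \code{models}, \code{featureSets}, \code{lineages},
#' \code{minLines}, \code{k}, \code{seed}). Unknown model names and
#' missing paths are rejected before any computation.
#'
#' @param config named list or path to a YAML file
#' @return the validated configuration with defaults filled in
#' @export
pipelineConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopIfNot(is.list(config), "config must be a list or YAML path")
  cfg <- utils::modifyList(.defaultPipelineConfig(), config)
  need <- c("expression", "annotations", "scores", "hallmarkGmt", "cgc")
  missing <- setdiff(need, names(cfg))
  stopIfNot(length(missing) == 0,
            "config is missing required path(s): ",
            paste(missing, collapse = ", "))
  for (f in need)
    stopIfNot(file.exists(cfg[[f]]), "path does not exist: ", cfg[[f]])
  bad <- setdiff(cfg$models, modelZooNames())
  stopIfNot(length(bad) == 0,
            "unknown model name(s) in config: ", paste(bad, collapse = ", "))
  stopIfNot(all(cfg$featureSets %in% c("network", "expression", "combined")),
            "featureSets must be among network, expression, combined")
  cfg
}

#' Run the full pipeline
#'
#' Reads the inputs named in the configuration, applies cohort filters,
#' and for every retained lineage: infers the dense MI network, applies
#' DPI, prunes at the (possibly lineage-specific) cutoff, computes the
#' four network feature classes plus expression summaries, binarizes
#' dependency labels, and cross-validates the configured models on the
#' configured feature sets. Per-lineage networks, feature tables, label
#' tables, an evaluation table and a manifest JSON (package version,
#' seed, parameters, config hash, per-stage status) are written to
#' \code{outdir}. Stage failures are recorded in the manifest and do not
#' discard completed outputs.
#'
#' @param config configuration list or YAML path (see
#'   \code{\link{pipelineConfig}})
#' @param outdir output directory
#' @return the manifest, invisibly
#' @export
runPipeline <- function(config, outdir) {
  cfg <- pipelineConfig(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfgFile <- file.path(outdir, "config_used.yaml")
  yaml::write_yaml(cfg, cfgFile)
  manifest <- list(
    package = "depnet",
    version = as.character(utils::packageVersion("depnet")),
    seed = cfg$seed,
    config = cfg,
    config_hash = unname(tools::md5sum(cfgFile)),
    stages = list())
  stage <- function(name, fun) {
    out <- tryCatch(list(status = "ok", value = fun()),
                    error = function(e)
                      list(status = conditionMessage(e), value = NULL))
    manifest$stages[[name]] <<- out$status
    out$value
  }

  expr <- stage("read_expression", function()
    readExpressionMatrix(cfg$expression, cfg$annotations))
  scores <- stage("read_scores", function()
    readDependencyScores(cfg$scores, cfg$annotations))
  sets <- stage("read_gene_sets", function()
    readGeneSets(cfg$hallmarkGmt, cfg$cgc))
  filtered <- stage("cohort_filters", function()
    applyCohortFilters(expr, scores, minLines = cfg$minLines))

  evalRows <- list()
  if (!is.null(filtered)) {
    expr <- filtered$expression
    scores <- filtered$scores
    lins <- lineages(expr)
    if (!is.null(cfg$lineages)) lins <- intersect(lins, cfg$lineages)
    infCfg <- inferenceConfig(
      miEstimator = cfg$miEstimator, nBins = cfg$nBins,
      dpiTolerance = if (is.null(cfg$dpiTolerance)) NA_real_
                     else cfg$dpiTolerance,
      miCutoff = cfg$miCutoff,
      perLineageCutoff = unlist(cfg$perLineageCutoff) %||% numeric())
    for (lin in lins) {
      res <- stage(paste0("lineage_", lin), function() {
        net <- estimateMINetwork(expr, lin, infCfg)
        net <- applyDPI(net, infCfg@dpiTolerance)
        net <- pruneNetwork(net, .lineageCutoff(infCfg, lin))
        writeNetwork(net, file.path(outdir,
                                    paste0("network_", lin, ".tsv")))
        ft <- networkFeatures(net, sets, pathMode = cfg$pathMode)
        ft <- assembleFeatures(list(ft),
                               expressionSummaryFeatures(expr, lin))
        writeFeatureTable(ft, file.path(outdir,
                                        paste0("features_", lin, ".csv")))
        labels <- binarizeDependency(aggregateScores(scores, lin),
                                     cutoff = cfg$labelCutoff, lin)
        writeLabels(labels, file.path(outdir,
                                      paste0("labels_", lin, ".csv")))
        zoo <- runModelZoo(ft, labels, models = cfg$models,
                           featureSets = cfg$featureSets, k = cfg$k,
                           seed = cfg$seed)
        zoo$lineage <- lin
        zoo
      })
      if (!is.null(res)) evalRows[[lin]] <- res
    }
  }
  if (length(evalRows)) {
    evaluation <- do.call(rbind, evalRows)
    utils::write.csv(evaluation, file.path(outdir, "evaluation.csv"),
                     row.names = FALSE)
    manifest$evaluation <- "evaluation.csv"
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
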