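# Readers and writers for the pipeline's plain-text formats: TSV/CSV
# matrices, lineage annotations, GMT gene sets, edge-list / GraphML
# networks, feature tables and label tables.

.detectDelim <- function(path) {
  first <- readLines(path, n = 1)
  stopIfNot(length(first) == 1 && nzchar(first), "empty file: ", path)
  if (grepl("\t", first)) "\t" else ","
}

.readMatrixFile <- function(path, delim = NULL) {
  if (is.null(delim)) delim <- .detectDelim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  stopIfNot(ncol(df) >= 2, "matrix file needs an id column plus samples: ",
            path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("malformed numeric fields in ", path,
                           call. = FALSE)
  rownames(m) <- ids
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    firsts <- m[!duplicated(ids), , drop = FALSE]
    for (d in dup) {
      rows <- m[ids == d, , drop = FALSE]
      if (!all(apply(rows, 2, function(col) length(unique(col)) == 1)))
        stop("conflicting duplicate rows for id '", d, "' in ", path,
             call. = FALSE)
    }
    msg("deduplicated ", length(dup), " repeated id(s) in ", path)
    m <- firsts
  }
  incomplete <- apply(m, 1, function(r) any(is.na(r)))
  if (any(incomplete)) {
    msg("dropping ", sum(incomplete),
        " row(s) with missing values from ", path)
    m <- m[!incomplete, , drop = FALSE]
  }
  stopIfNot(nrow(m) > 0, "no complete rows in ", path)
  m
}

.readAnnotation <- function(path, delim = NULL) {
  if (is.null(delim)) delim <- .detectDelim(path)
  ann <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  stopIfNot(all(c("sample", "lineage") %in% colnames(ann)),
            "annotation file needs 'sample' and 'lineage' columns: ", path)
  stats::setNames(as.character(ann$lineage), as.character(ann$sample))
}

#' Read an expression matrix with lineage annotations
#'
#' Expects a genes x samples matrix (first column gene ids, header row of
#' sample ids) and an annotation table with \code{sample} and
#' \code{lineage} columns. Rows with any missing value are dropped with a
#' reported count (only cell lines/transcripts with complete values are
#' usable); duplicated gene rows are deduplicated, with an error on
#' conflicting duplicates. Samples without a lineage annotation are
#' dropped with a message.
#'
#' @param path matrix file (TSV or CSV; tab/comma auto-detected)
#' @param annotationPath sample-to-lineage table
#' @param delim optional explicit delimiter overriding auto-detection
#' @return an \linkS4class{ExpressionMatrix}
#' @export
readExpressionMatrix <- function(path, annotationPath, delim = NULL) {
  m <- .readMatrixFile(path, delim)
  lin <- .readAnnotation(annotationPath, delim)
  known <- colnames(m) %in% names(lin)
  if (any(!known)) {
    msg("dropping ", sum(!known), " sample(s) without lineage annotation")
    m <- m[, known, drop = FALSE]
  }
  stopIfNot(ncol(m) > 0, "no annotated samples in ", path)
  ExpressionMatrix(m, lin[colnames(m)])
}

#' Read a dependency score matrix with lineage annotations
#'
#' @inheritParams readExpressionMatrix
#' @return a \linkS4class{DependencyScores}
#' @export
readDependencyScores <- function(path, annotationPath, delim = NULL) {
  m <- .readMatrixFile(path, delim)
  lin <- .readAnnotation(annotationPath, delim)
  known <- colnames(m) %in% names(lin)
  if (any(!known)) {
    msg("dropping ", sum(!known), " sample(s) without lineage annotation")
    m <- m[, known, drop = FALSE]
  }
  stopIfNot(ncol(m) > 0, "no annotated samples in ", path)
  DependencyScores(m, lin[colnames(m)])
}

.writeAssayObject <- function(x, assayName, path, annotationPath,
                              delim = "\t") {
  m <- assay(x, assayName)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = delim, quote = FALSE,
                     row.names = FALSE)
  if (!is.null(annotationPath)) {
    lin <- sampleLineages(x)
    utils::write.table(data.frame(sample = names(lin), lineage = lin),
                       annotationPath, sep = delim, quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Write expression / scores with lineage annotations
#'
#' @param x an \linkS4class{ExpressionMatrix} or
#'   \linkS4class{DependencyScores}
#' @param path output matrix file
#' @param annotationPath optional sample-to-lineage table output
#' @param delim field delimiter
#' @return the matrix path, invisibly
#' @export
writeExpressionMatrix <- function(x, path, annotationPath = NULL,
                                  delim = "\t")
  .writeAssayObject(x, "exprs", path, annotationPath, delim)

#' @rdname writeExpressionMatrix
#' @export
writeDependencyScores <- function(x, path, annotationPath = NULL,
                                  delim = "\t")
  .writeAssayObject(x, "score", path, annotationPath, delim)

#' Read hallmark and CGC gene sets
#'
#' The hallmark GMT must contain exactly 10 sets (one per cancer hallmark
#' category); any other count is an error naming the count. The CGC list
#' is read from a one-column text file, or from a GMT whose sets are
#' unioned. Duplicate genes within a set are removed with a message.
#'
#' @param hallmarkGmt GMT file of the 10 hallmark sets
#' @param cgcPath CGC gene list (one-column text or GMT)
#' @return a \linkS4class{GeneSetCollection}
#' @export
readGeneSets <- function(hallmarkGmt, cgcPath) {
  sets <- fgsea::gmtPathways(hallmarkGmt)
  if (length(sets) != 10)
    stop("hallmark GMT must contain exactly 10 sets, got ", length(sets),
         call. = FALSE)
  cgc <- if (grepl("\\.gmt$", cgcPath, ignore.case = TRUE)) {
    unique(unlist(fgsea::gmtPathways(cgcPath), use.names = FALSE))
  } else {
    unique(readLines(cgcPath))
  }
  cgc <- cgc[nzchar(cgc)]
  GeneSetCollection(sets, cgc)
}

#' Write gene sets to GMT / plain text
#'
#' @param geneSets a \linkS4class{GeneSetCollection}
#' @param hallmarkGmt output GMT path for the hallmark sets
#' @param cgcPath optional output path for the CGC list (one gene per
#'   line)
#' @return the GMT path, invisibly
#' @export
writeGeneSets <- function(geneSets, hallmarkGmt, cgcPath = NULL) {
  sets <- hallmarkSets(geneSets)
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, hallmarkGmt)
  if (!is.null(cgcPath)) writeLines(cgcGenes(geneSets), cgcPath)
  invisible(hallmarkGmt)
}

#' Read / write a gene network
#'
#' Networks are stored either as a 3-column edge-list TSV
#' (\code{gene_a}, \code{gene_b}, \code{mi}) -- which loses isolated
#' nodes -- or as GraphML, which preserves them.
#'
#' @param path input file; \code{.graphml} suffix selects GraphML
#' @return a \linkS4class{GeneNetwork}
#' @export
readNetwork <- function(path) {
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    g <- igraph::read_graph(path, format = "graphml")
    e <- igraph::as_data_frame(g, what = "edges")
    return(GeneNetwork(igraph::V(g)$name,
                       data.frame(from = e$from, to = e$to,
                                  weight = as.numeric(e$weight))))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopIfNot(ncol(df) >= 3, "edge list needs 3 columns: ", path)
  colnames(df)[1:3] <- c("from", "to", "weight")
  GeneNetwork(unique(c(df$from, df$to)), df[, 1:3])
}

#' @rdname readNetwork
#' @param net a \linkS4class{GeneNetwork}
#' @param format \code{"tsv"} or \code{"graphml"}
#' @export
writeNetwork <- function(net, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(asIgraph(net), path, format = "graphml")
  } else {
    e <- edgeTable(net)
    colnames(e) <- c("gene_a", "gene_b", "mi")
    utils::write.table(e, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read / write a feature table
#'
#' CSV with a two-row header: the first row carries the feature class tag
#' of every column, the second the feature name; rows are genes.
#'
#' @param path file path
#' @return a \linkS4class{FeatureTable}
#' @export
readFeatureTable <- function(path) {
  hdr <- utils::read.csv(path, header = FALSE, nrows = 2,
                         stringsAsFactors = FALSE)
  cls <- as.character(hdr[1, -1])
  nms <- as.character(hdr[2, -1])
  body <- utils::read.csv(path, header = FALSE, skip = 2,
                          stringsAsFactors = FALSE)
  m <- as.matrix(body[, -1, drop = FALSE])
  dimnames(m) <- list(as.character(body[[1]]), nms)
  FeatureTable(m, cls)
}

#' @rdname readFeatureTable
#' @param features a \linkS4class{FeatureTable}
#' @export
writeFeatureTable <- function(features, path) {
  m <- as.matrix(features)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("class", unname(featureClasses(features))),
                   collapse = ","), con)
  writeLines(paste(c("gene", colnames(m)), collapse = ","), con)
  utils::write.table(data.frame(gene = rownames(m), m,
                                check.names = FALSE),
                     con, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write dependency labels
#'
#' CSV with columns \code{gene}, \code{lineage}, \code{mean_score},
#' \code{label}, \code{cutoff_used}.
#'
#' @param path file path
#' @return a \linkS4class{DependencyLabels}
#' @export
readLabels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cutoff <- unique(df$cutoff_used)
  stopIfNot(length(cutoff) == 1, "mixed cutoffs in ", path)
  new("DependencyLabels",
      table = df[, c("gene", "lineage", "mean_score", "label")],
      cutoff = as.numeric(cutoff))
}

#' @rdname readLabels
#' @param labels a \linkS4class{DependencyLabels}
#' @export
writeLabels <- function(labels, path) {
  df <- labelTable(labels)
  df$cutoff_used <- dependencyCutoff(labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
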