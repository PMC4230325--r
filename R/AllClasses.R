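#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.EXPR_UNITS <- c("counts", "rpm", "log_rpm", "polished")

#' CTCExperiment: a gene-by-cell expression matrix with a declared unit
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a single
#' assay \code{"expr"} (genes in rows, cells in columns) together with the
#' unit of measurement. Units are \code{"counts"} (raw reads),
#' \code{"rpm"} (reads per million; every non-empty cell column sums to
#' 10^6), \code{"log_rpm"} (log10(rpm + pseudocount)) and
#' \code{"polished"} (median-polish residuals). Per-cell annotations
#' (class, animal of origin, QC status) live in \code{colData}.
#'
#' Validity rules: gene and cell identifiers are unique and non-empty;
#' values are finite, with no missing entries (absence of detection is 0);
#' counts and rpm are non-negative; rpm columns with nonzero library size
#' sum to 10^6 within 1e-6 relative tolerance.
#'
#' @slot unit character scalar, one of \code{"counts"}, \code{"rpm"},
#'   \code{"log_rpm"}, \code{"polished"}.
#' @export
setClass("CTCExperiment",
         contains = "SummarizedExperiment",
         slots = c(unit = "character"))

setValidity("CTCExperiment", function(object) {
  msgs <- character()
  if (length(object@unit) != 1L || !object@unit %in% .EXPR_UNITS)
    msgs <- c(msgs, sprintf("unit must be one of %s",
                            paste(.EXPR_UNITS, collapse = ", ")))
  v <- SummarizedExperiment::assay(object, withDimnames = FALSE)
  g <- rownames(object); cc <- colnames(object)
  if (is.null(g) || anyDuplicated(g) || any(!nzchar(g)))
    msgs <- c(msgs, "gene ids must be unique non-empty strings")
  if (is.null(cc) && ncol(object) > 0L || anyDuplicated(cc) || any(!nzchar(cc)))
    msgs <- c(msgs, "cell ids must be unique non-empty strings")
  if (anyNA(v) || any(!is.finite(v)))
    msgs <- c(msgs, "values must be finite; missing values are not permitted")
  else {
    if (length(object@unit) == 1L && object@unit %in% c("counts", "rpm") &&
        length(v) && min(v) < 0)
      msgs <- c(msgs, sprintf("negative values not allowed for unit '%s'",
                              object@unit))
    if (identical(object@unit, "rpm") && ncol(v) > 0L) {
      cs <- colSums(v)
      bad <- cs > 0 & abs(cs - 1e6) > 1e-6 * 1e6
      if (any(bad))
        msgs <- c(msgs, sprintf(
          "rpm columns must sum to 1e6 (offending cell: %s)",
          colnames(v)[which(bad)[1L]]))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CTCExperiment
#'
#' @param values numeric matrix, genes in rows and cells in columns, with
#'   row and column names.
#' @param unit expression unit; see \linkS4class{CTCExperiment}.
#' @param cellMeta optional data.frame of per-cell annotations (one row per
#'   cell, in column order).
#' @param geneMeta optional data.frame of per-gene annotations.
#' @return a \linkS4class{CTCExperiment}.
#' @examples
#' m <- matrix(1:4, 2, dimnames = list(c("Gapdh", "Actb"), c("c1", "c2")))
#' CTCExperiment(m, unit = "counts")
#' @export
CTCExperiment <- function(values, unit = "counts", cellMeta = NULL,
                          geneMeta = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  cd <- if (is.null(cellMeta)) S4Vectors::DataFrame(row.names = colnames(values))
        else S4Vectors::DataFrame(cellMeta, row.names = colnames(values))
  rd <- if (is.null(geneMeta)) S4Vectors::DataFrame(row.names = rownames(values))
        else S4Vectors::DataFrame(geneMeta, row.names = rownames(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = values), colData = cd, rowData = rd)
  new("CTCExperiment", se, unit = unit)
}

#' GeneSetList: a named collection of gene sets
#'
#' Marker panels and candidate gene lists are stored as a named list of
#' character vectors plus free-text provenance per set. Gene identifiers
#' are case-sensitive symbols; no cross-species mapping is attempted.
#'
#' @slot sets named list of character vectors (each non-empty, no
#'   duplicates within a set).
#' @slot provenance named character vector of free-text descriptions.
#' @export
setClass("GeneSetList",
         slots = c(sets = "list", provenance = "character"))

setValidity("GeneSetList", function(object) {
  s <- object@sets
  if (length(s)) {
    if (is.null(names(s)) || anyDuplicated(names(s)) || any(!nzchar(names(s))))
      return("sets must have unique non-empty names")
    if (any(!vapply(s, is.character, TRUE)))
      return("each set must be a character vector")
    if (any(vapply(s, length, 1L) == 0L))
      return("every set must be non-empty")
    if (any(vapply(s, anyDuplicated, 1L) > 0L))
      return("gene ids within a set must be unique")
  }
  if (length(object@provenance) &&
      !identical(names(object@provenance), names(s)))
    return("provenance names must match set names")
  TRUE
})

#' Construct a GeneSetList
#'
#' @param sets named list of character vectors.
#' @param provenance optional named character vector (recycled description
#'   if a single unnamed string is given).
#' @return a \linkS4class{GeneSetList}.
#' @export
GeneSetList <- function(sets = list(), provenance = NULL) {
  if (is.null(provenance))
    provenance <- setNames(rep("", length(sets)), names(sets))
  else if (length(provenance) == 1L && is.null(names(provenance)))
    provenance <- setNames(rep(provenance, length(sets)), names(sets))
  new("GeneSetList", sets = sets, provenance = provenance)
}

#' ClusterAssignment: a cut hierarchical clustering of cells
#'
#' @slot labels named integer vector of cluster labels (a partition of the
#'   clustered cells).
#' @slot tree the \code{hclust} merge tree (n - 1 merges for n cells).
#' @slot distance character, distance used.
#' @slot linkage character, linkage used.
#' @slot k integer, number of clusters the tree was cut at.
#' @export
setClass("ClusterAssignment",
         slots = c(labels = "integer", tree = "ANY",
                   distance = "character", linkage = "character",
                   k = "integer"))

setValidity("ClusterAssignment", function(object) {
  if (is.null(names(object@labels)))
    return("labels must be named by cell id")
  if (inherits(object@tree, "hclust") &&
      nrow(object@tree$merge) != length(object@labels) - 1L)
    return("tree must contain n - 1 merges for n cells")
  if (object@k < 1L || object@k > length(object@labels))
    return("k must lie between 1 and the number of cells")
  TRUE
})

setMethod("show", "CTCExperiment", function(object) {
  cat(sprintf("CTCExperiment: %d genes x %d cells [unit: %s]\n",
              nrow(object), ncol(object), object@unit))
  if (ncol(SummarizedExperiment::colData(object)))
    cat("cell annotations:",
        paste(colnames(SummarizedExperiment::colData(object)), collapse = ", "),
        "\n")
})

setMethod("show", "GeneSetList", function(object) {
  cat(sprintf("GeneSetList with %d set(s)\n", length(object@sets)))
  for (nm in head(names(object@sets), 10L))
    cat(sprintf("  %s (%d genes)\n", nm, length(object@sets[[nm]])))
  if (length(object@sets) > 10L) cat("  ...\n")
})

setMethod("show", "ClusterAssignment", function(object) {
  cat(sprintf("ClusterAssignment: %d cells in %d clusters (%s distance, %s linkage)\n",
              length(object@labels), object@k, object@distance, object@linkage))
  print(table(cluster = object@labels))
})
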