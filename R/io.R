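#' Read a gene-by-cell expression matrix
#'
#' Two on-disk layouts are supported. \code{format = "tsv"}: a UTF-8
#' tab-delimited table whose first column is \code{gene_id} and whose
#' remaining columns are one per cell. \code{format = "mtx"}: MatrixMarket
#' coordinate format (1-based indices) with sidecar files \code{genes.tsv}
#' and \code{cells.tsv} (one id per line) in the same directory, unless
#' explicit paths are given. Row and column order is preserved from file.
#'
#' @param path path to the matrix file.
#' @param format \code{"tsv"} or \code{"mtx"}.
#' @param unit declared unit of the stored values (default \code{"counts"}).
#' @param genesPath,cellsPath optional sidecar paths for \code{"mtx"}.
#' @return a \linkS4class{CTCExperiment}.
#' @export
readExprMatrix <- function(path, format = c("tsv", "mtx"), unit = "counts",
                           genesPath = NULL, cellsPath = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    tab <- tryCatch(
      read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
      error = function(e) stop("parse error in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    if (!identical(colnames(tab)[1L], "gene_id"))
      stop("parse error in ", path, " line 1: first column must be 'gene_id'",
           call. = FALSE)
    bad <- which(!vapply(tab[-1L], is.numeric, TRUE))
    if (length(bad))
      stop("parse error in ", path, ": non-numeric values in column '",
           colnames(tab)[-1L][bad[1L]], "'", call. = FALSE)
    if (anyDuplicated(tab$gene_id))
      stop("validation error: duplicate gene ids in ", path, call. = FALSE)
    if (anyDuplicated(colnames(tab)[-1L]))
      stop("validation error: duplicate cell ids in ", path, call. = FALSE)
    m <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(m) <- tab$gene_id
  } else {
    dirn <- dirname(path)
    if (is.null(genesPath)) genesPath <- file.path(dirn, "genes.tsv")
    if (is.null(cellsPath)) cellsPath <- file.path(dirn, "cells.tsv")
    for (p in c(genesPath, cellsPath))
      if (!file.exists(p)) stop("sidecar file not found: ", p, call. = FALSE)
    mm <- tryCatch(Matrix::readMM(path),
                   error = function(e) stop("parse error in ", path, ": ",
                                            conditionMessage(e), call. = FALSE))
    g <- readLines(genesPath)
    cc <- readLines(cellsPath)
    if (nrow(mm) != length(g) || ncol(mm) != length(cc))
      stop("validation error: sidecar id counts (", length(g), " genes, ",
           length(cc), " cells) do not match matrix dimensions", call. = FALSE)
    if (anyDuplicated(g) || anyDuplicated(cc))
      stop("validation error: duplicate ids in sidecar files", call. = FALSE)
    m <- as.matrix(mm)
    dimnames(m) <- list(g, cc)
  }
  CTCExperiment(m, unit = unit)
}

#' Write a gene-by-cell expression matrix
#'
#' Inverse of \code{\link{readExprMatrix}}; \code{read(write(x))}
#' round-trips counts matrices bit-exactly in both formats.
#'
#' @param x a \linkS4class{CTCExperiment}.
#' @param path output path (for \code{"mtx"}, sidecars \code{genes.tsv} and
#'   \code{cells.tsv} are written next to it).
#' @param format \code{"tsv"} or \code{"mtx"}.
#' @return invisibly, \code{path}.
#' @export
writeExprMatrix <- function(x, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  v <- exprValues(x)
  if (format == "tsv") {
    tab <- data.frame(gene_id = rownames(v), v, check.names = FALSE,
                      stringsAsFactors = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
  } else {
    Matrix::writeMM(Matrix::Matrix(v, sparse = TRUE), path)
    dirn <- dirname(path)
    writeLines(rownames(v), file.path(dirn, "genes.tsv"))
    writeLines(colnames(v), file.path(dirn, "cells.tsv"))
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: set name, description, then tab-separated gene ids.
#' Gene order within a set is preserved.
#'
#' @param path path to a GMT file.
#' @return a \linkS4class{GeneSetList} (empty file gives an empty
#'   collection).
#' @export
readGeneSets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(GeneSetList())
  sets <- list(); prov <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("parse error in ", path, " line ", i,
           ": expected at least 3 tab-separated fields", call. = FALSE)
    sets[[f[1L]]] <- f[-(1:2)]
    prov[f[1L]] <- f[2L]
  }
  GeneSetList(sets, prov)
}

#' Write gene sets to a GMT file
#'
#' @param x a \linkS4class{GeneSetList}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeGeneSets <- function(x, path) {
  lines <- vapply(names(x), function(nm) {
    paste(c(nm, if (nzchar(x@provenance[[nm]])) x@provenance[[nm]] else "na",
            x[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
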