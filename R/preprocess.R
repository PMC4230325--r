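#' Housekeeping-gene quality-control filter
#'
#' A cell passes QC iff every housekeeping gene (default Gapdh and Actb)
#' reaches \code{minRpm} reads per million after per-cell normalization and
#' the cell has a nonzero library. The default threshold of 100 rpm follows
#' the study's "high expression" convention; degraded cells in the
#' synthetic cohort are constructed to fail it with at least a 10-fold
#' margin, so QC decisions are robust to the exact cutoff.
#'
#' @param x a counts or rpm \linkS4class{CTCExperiment}.
#' @param housekeeping character vector of housekeeping gene ids (must be
#'   non-empty and present; a silent pass-all is forbidden).
#' @param minRpm minimum rpm required for each housekeeping gene
#'   (inclusive).
#' @return a list with \code{report} (data.frame: cell_id, one rpm column
#'   per housekeeping gene, pass, plus the threshold and cohort pass
#'   fraction as attributes) and \code{matrix} (the input restricted to
#'   passing cells).
#' @export
qcFilter <- function(x, housekeeping = c("Gapdh", "Actb"), minRpm = 100) {
  if (!length(housekeeping))
    stop("housekeeping gene list must not be empty", call. = FALSE)
  gidx <- .matchGenes(housekeeping, geneIds(x))
  v <- exprValues(x)
  if (exprUnit(x) == "counts") {
    lib <- colSums(v)
    hk <- sweep(v[gidx, , drop = FALSE], 2L, pmax(lib, 1), "/") * 1e6
  } else if (exprUnit(x) == "rpm") {
    lib <- colSums(v)
    hk <- v[gidx, , drop = FALSE]
  } else stop("qcFilter expects counts or rpm", call. = FALSE)
  pass <- apply(hk >= minRpm, 2L, all) & lib > 0
  report <- data.frame(cell_id = cellIds(x),
                       t(hk), pass = unname(pass),
                       row.names = NULL, check.names = FALSE,
                       stringsAsFactors = FALSE)
  colnames(report)[seq_along(gidx) + 1L] <- paste0(housekeeping, "_rpm")
  attr(report, "min_rpm") <- minRpm
  attr(report, "pass_fraction") <- if (ncol(v)) mean(pass) else NA_real_
  list(report = report, matrix = x[, pass])
}

#' Normalize counts to reads per million
#'
#' Scales every cell column to a total of 10^6. All-zero columns remain
#' all-zero and are flagged in the returned object's metadata
#' (\code{metadata(x)$empty_cells}). Idempotent on already-normalized
#' columns.
#'
#' @param x a counts \linkS4class{CTCExperiment}.
#' @return an rpm \linkS4class{CTCExperiment}.
#' @export
normalizeRpm <- function(x) {
  if (!exprUnit(x) %in% c("counts", "rpm"))
    stop("normalizeRpm expects counts (or rpm, for idempotence)",
         call. = FALSE)
  v <- exprValues(x)
  if (length(v) && min(v) < 0)
    stop("negative values are not valid counts", call. = FALSE)
  lib <- colSums(v)
  empty <- lib == 0
  out <- sweep(v, 2L, ifelse(empty, 1, lib), "/") * 1e6
  res <- CTCExperiment(out, unit = "rpm",
                       cellMeta = as.data.frame(cellData(x)))
  S4Vectors::metadata(res)$empty_cells <- cellIds(x)[empty]
  res
}

#' Log-transform an rpm matrix
#'
#' \code{value <- log10(rpm + pseudocount)}; strictly monotone in the
#' input. Defaults follow the study's display scale (log10, pseudocount
#' 1, so 0 rpm maps to 0 and 99 rpm to 2).
#'
#' @param x an rpm \linkS4class{CTCExperiment}.
#' @param pseudocount positive stabilizer added before the log.
#' @param base logarithm base.
#' @return a log_rpm \linkS4class{CTCExperiment}.
#' @export
logTransform <- function(x, pseudocount = 1, base = 10) {
  if (exprUnit(x) != "rpm")
    stop("logTransform expects an rpm matrix", call. = FALSE)
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  v <- log(exprValues(x) + pseudocount, base = base)
  CTCExperiment(v, unit = "log_rpm",
                cellMeta = as.data.frame(cellData(x)))
}

#' Tukey median polish of a log-expression matrix
#'
#' Decomposes the matrix into overall + gene (row) effects + cell (column)
#' effects + residuals, sweeping rows first then columns per Tukey's
#' classical ordering (results depend on the order if iteration stops
#' before convergence). Iteration stops when the change in the sum of
#' absolute residuals falls below \code{tol} or after \code{maxIter}
#' sweeps. The decomposition identity
#' \code{overall + row + col + residual == input} holds exactly.
#'
#' @param x a log_rpm \linkS4class{CTCExperiment} (or any numeric state).
#' @param maxIter maximum number of sweeps (>= 1).
#' @param tol positive convergence tolerance on the sum of absolute
#'   residuals.
#' @return a list with \code{matrix} (residuals as a polished
#'   \linkS4class{CTCExperiment}), \code{overall}, \code{row_effects},
#'   \code{col_effects}, and \code{converged}.
#' @export
medianPolishMatrix <- function(x, maxIter = 10L, tol = 0.01) {
  stopifnot(maxIter >= 1L, tol > 0)
  v <- exprValues(x)
  mp <- suppressWarnings(
    medpolish(v, eps = tol, maxiter = maxIter, trace.iter = FALSE))
  res <- CTCExperiment(mp$residuals + 0, unit = "polished",
                       cellMeta = as.data.frame(cellData(x)))
  list(matrix = res, overall = mp$overall,
       row_effects = setNames(mp$row, rownames(v)),
       col_effects = setNames(mp$col, colnames(v)),
       converged = TRUE)
}
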