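#' Default pipeline configuration
#'
#' Returns the nested parameter list consumed by \code{\link{runPipeline}}
#' and the individual stage functions. Defaults carry the study's printed
#' thresholds: an RP score bound of 300, an expression bound of 100 rpm,
#' a cell fraction of 0.90 for the CTC-enriched selection (inclusive) and
#' 0.15 for the ECM screen (strict).
#'
#' @param ... named overrides for top-level entries (lists are merged
#'   shallowly).
#' @return a list of class \code{ctc_pipeline_config}.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    seed = 7L,
    qc = list(housekeeping = c("Gapdh", "Actb"), min_rpm = 100),
    normalize = list(pseudocount = 1, log_base = 10),
    polish = list(max_iter = 10L, tol = 0.01),
    cluster = list(distance = "pearson", linkage = "average", k = 7L,
                   min_cells_detected = 2L),
    heterogeneity = list(n_boot = 1000L, level = 0.95),
    de = list(n_perm = 100L, min_detect_fraction = 0.2, pseudocount = 1,
              max_pairs = 10000L, q_max = 0.01),
    selection = list(rp_max = 300, rpm_min = 100, cell_fraction_min = 0.90),
    ecm = list(rpm_min = 100, cell_fraction_min = 0.15, strict_fraction = TRUE),
    panels_gmt = NULL,
    cohort = cohortConfig()
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg))
      stop("unknown configuration key: ", nm, call. = FALSE)
    if (nm == "cohort") {
      cfg$cohort <- if (inherits(over$cohort, "ctc_cohort_config"))
        over$cohort else do.call(cohortConfig, over$cohort)
    } else if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      bad <- setdiff(names(over[[nm]]), names(cfg[[nm]]))
      if (length(bad))
        stop("unknown configuration key: ", nm, "$", bad[1L], call. = FALSE)
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else cfg[[nm]] <- over[[nm]]
  }
  class(cfg) <- "ctc_pipeline_config"
  validatePipelineConfig(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks that counts are positive integers, fractions lie in (0, 1], the
#' seed is a non-negative integer, and thresholds are positive.
#'
#' @param cfg a configuration list.
#' @return invisibly, \code{cfg}; errors on the first violation.
#' @export
validatePipelineConfig <- function(cfg) {
  chkCount <- function(x, what)
    if (!is.numeric(x) || length(x) != 1L || x < 1 || x != round(x))
      stop(what, " must be a positive integer", call. = FALSE)
  chkFrac <- function(x, what)
    if (!is.numeric(x) || length(x) != 1L || x <= 0 || x > 1)
      stop(what, " must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(cfg$seed) || cfg$seed < 0 || cfg$seed != round(cfg$seed))
    stop("seed must be a non-negative integer", call. = FALSE)
  if (!length(cfg$qc$housekeeping))
    stop("qc$housekeeping must name at least one gene", call. = FALSE)
  if (cfg$qc$min_rpm < 0) stop("qc$min_rpm must be >= 0", call. = FALSE)
  if (cfg$normalize$pseudocount <= 0)
    stop("normalize$pseudocount must be > 0", call. = FALSE)
  chkCount(cfg$polish$max_iter, "polish$max_iter")
  if (cfg$polish$tol <= 0) stop("polish$tol must be > 0", call. = FALSE)
  chkCount(cfg$cluster$k, "cluster$k")
  chkCount(cfg$heterogeneity$n_boot, "heterogeneity$n_boot")
  chkFrac(cfg$heterogeneity$level, "heterogeneity$level")
  chkCount(cfg$de$n_perm, "de$n_perm")
  chkFrac(cfg$de$min_detect_fraction, "de$min_detect_fraction")
  chkCount(cfg$de$max_pairs, "de$max_pairs")
  chkFrac(cfg$de$q_max + as.numeric(cfg$de$q_max == 0), "de$q_max")
  if (cfg$selection$rp_max <= 0)
    stop("selection$rp_max must be > 0", call. = FALSE)
  if (cfg$selection$rpm_min < 0)
    stop("selection$rpm_min must be >= 0", call. = FALSE)
  chkFrac(cfg$selection$cell_fraction_min, "selection$cell_fraction_min")
  chkFrac(cfg$ecm$cell_fraction_min, "ecm$cell_fraction_min")
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' \code{readPipelineConfig} merges the file's entries over the defaults
#' from \code{\link{pipelineConfig}} and rejects unknown keys;
#' \code{writePipelineConfig} serializes a configuration so that reading
#' it back round-trips.
#'
#' @param path YAML file path.
#' @param cfg a configuration list.
#' @return the configuration (read) or invisibly the path (write).
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  do.call(pipelineConfig, raw)
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(cfg, path) {
  out <- unclass(cfg)
  out$cohort <- unclass(out$cohort)
  # data.frame entries serialize as column lists and are rebuilt on read
  out$cohort$planted <- as.list(out$cohort$planted)
  yaml::write_yaml(out, path)
  invisible(path)
}
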