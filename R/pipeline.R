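#' Run the full CTC classification pipeline
#'
#' Orchestrates simulate/read -> QC -> rpm normalization -> log +
#' median polish -> hierarchical clustering + PCA -> heterogeneity ->
#' marker annotation -> rank-product DE (classical CTCs vs bulk tumor) ->
#' CTC-enriched signature selection, writing every stage artifact as
#' plain TSV into \code{outDir} together with a JSON run manifest
#' (resolved configuration, root seed, file hashes, stage timings,
#' package version). Stages run in fixed order; a failing stage aborts
#' with its name, leaving partial outputs plus a \code{FAILED} marker
#' file. Re-running with the same configuration and seed reproduces all
#' outputs bit-exactly.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param input \code{"simulate"} (default) to generate the synthetic
#'   cohort from \code{config$cohort}, or a path to a counts TSV matrix.
#' @param outDir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config = pipelineConfig(), input = "simulate",
                        outDir) {
  validatePipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("CTCscope")),
                   seed = config$seed, input = input,
                   config = unclass(config), stages = list())
  manifest$config$cohort <- unclass(manifest$config$cohort)
  manifest$config$cohort$planted <- as.list(manifest$config$cohort$planted)
  artifacts <- character()
  failed <- function(stage, e) {
    writeLines(c(stage, conditionMessage(e)), file.path(outDir, "FAILED"))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    ctcLog("stage %s", name)
    out <- tryCatch(expr, error = function(e) failed(name, e))
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    out
  }
  wtsv <- function(df, file) {
    p <- file.path(outDir, file)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts <<- c(artifacts, p)
    p
  }

  truth <- NULL
  raw <- stage("input", {
    if (identical(input, "simulate")) {
      cohort <- config$cohort
      cohort$seed <- substreamSeed(config$seed, "cohort")
      sim <- simulateCohort(cohort)
      truth <- sim$truth
      wtsv(sim$truth$cells, "truth_cells.tsv")
      wtsv(sim$truth$genes, "truth_genes.tsv")
      writeExprMatrix(sim$matrix, file.path(outDir, "matrix_counts.tsv"), "tsv")
      artifacts <- c(artifacts, file.path(outDir, "matrix_counts.tsv"))
      sim$matrix
    } else readExprMatrix(input, "tsv")
  })

  qc <- stage("qc", qcFilter(raw, config$qc$housekeeping, config$qc$min_rpm))
  wtsv(qc$report, "qc_report.tsv")

  rpm <- stage("normalize", normalizeRpm(qc$matrix))
  lg <- logTransform(rpm, config$normalize$pseudocount,
                     config$normalize$log_base)
  pol <- stage("polish",
               medianPolishMatrix(lg, config$polish$max_iter,
                                  config$polish$tol))

  assign <- stage("cluster", {
    cl <- hierarchicalCluster(pol$matrix, config$cluster$distance,
                              config$cluster$linkage, config$cluster$k,
                              config$cluster$min_cells_detected)
    wtsv(data.frame(cell_id = names(clusterLabels(cl)),
                    cluster = unname(clusterLabels(cl))), "clusters.tsv")
    m <- cl@tree$merge
    wtsv(data.frame(merge1 = m[, 1L], merge2 = m[, 2L],
                    height = cl@tree$height), "linkage.tsv")
    pc <- pcaCells(pol$matrix, 2L)
    wtsv(data.frame(cell_id = rownames(pc$coords), pc$coords),
         "pca_coordinates.tsv")
    cl
  })

  het <- stage("heterogeneity", {
    labs <- clusterLabels(assign)
    hs <- do.call(rbind, lapply(sort(unique(labs)), function(cl) {
      cells <- names(labs)[labs == cl]
      if (length(cells) < 2L) return(NULL)
      intraclusterCorrelation(lg, cells, config$heterogeneity$n_boot,
                              config$heterogeneity$level,
                              seed = substreamSeed(config$seed,
                                                   paste0("het_", cl)),
                              cluster = cl)
    }))
    wtsv(hs, "heterogeneity.tsv")
    hs
  })

  classes <- stage("annotate", {
    panels <- if (is.null(config$panels_gmt)) markerPanels()
              else readGeneSets(config$panels_gmt)
    sc <- scorePanels(rpm, assign, panels)
    mk <- proliferationLevel(rpm, assign)
    calls <- callClasses(sc, mk)
    labs <- clusterLabels(assign)
    perCell <- data.frame(
      cell_id = names(labs), cluster = unname(labs),
      class = calls$class[match(labs, calls$cluster)],
      stringsAsFactors = FALSE)
    wtsv(calls, "class_calls.tsv")
    wtsv(perCell, "cell_classes.tsv")
    perCell
  })

  de <- stage("de", {
    groupA <- classes$cell_id[classes$class == "CTC-classical"]
    groupB <- if (identical(input, "simulate"))
      cellIds(rpm)[cellData(rpm)$class == "bulk_tumor"]
    else classes$cell_id[classes$class == "tumor"]
    if (length(groupA) < 2L || length(groupB) < 2L)
      stop("need >= 2 classical CTCs and >= 2 tumor cells for DE")
    rp <- rankProduct(rpm, groupA, groupB, config$de$min_detect_fraction,
                      config$de$pseudocount, config$de$max_pairs,
                      seed = substreamSeed(config$seed, "de_pairs"))
    rp <- rpSignificance(rp, rpm, config$de$n_perm,
                         seed = substreamSeed(config$seed, "de_perm"))
    wtsv(as.data.frame(rp), "de_results.tsv")
    sm <- deSummary(rp, config$de$q_max)
    wtsv(data.frame(direction = c("up_in_ctc", "up_in_tumor"),
                    n = c(sm$n_up_A, sm$n_up_B)), "de_summary.tsv")
    rp
  })

  sig <- stage("select", {
    groupA <- classes$cell_id[classes$class == "CTC-classical"]
    genes <- selectEnrichedGenes(de, rpm, groupA,
                                 config$selection$rp_max,
                                 config$selection$rpm_min,
                                 config$selection$cell_fraction_min)
    wtsv(data.frame(gene_id = genes), "signature_genes.tsv")
    genes
  })

  manifest$artifacts <- lapply(
    setNames(nm = basename(list.files(outDir, full.names = FALSE))),
    function(f) unname(tools::md5sum(file.path(outDir, f))))
  manifest$artifacts$manifest.json <- NULL
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  ctcLog("pipeline complete: %s", outDir)
  invisible(c(manifest, list(signature = sig, classes = classes,
                             heterogeneity = het)))
}
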