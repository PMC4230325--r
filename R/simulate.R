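#' Default synthetic-cohort configuration
#'
#' The generator emulates the cell-population structure of the mouse
#' pancreatic CTC study: 168 candidate single CTCs per run (41 classical,
#' 24 platelet-adhered, 10 proliferative, 93 RNA-degraded), 12 leukocytes,
#' 16 cancer cell-line cells, 12 embryonic fibroblasts, 34 diluted
#' bulk-tumor replicates and 20 purified single primary-tumor cells.
#' Expression follows log-normal gene abundances with Poisson sampling,
#' Bernoulli dropout on weakly expressed genes, bounded class-specific
#' abundance offsets, and per-cell log-normal noise whose scale is
#' calibrated numerically so each class attains its configured mean
#' intracluster pairwise correlation in expectation (cell line 0.86,
#' CTC classes 0.42, purified tumor single cells 0.38).
#'
#' @param ... named overrides of the defaults (unknown keys rejected).
#' @return a list of class \code{ctc_cohort_config}.
#' @export
cohortConfig <- function(...) {
  cfg <- list(
    class_counts = c(ctc_classical = 41L, ctc_plt = 24L, ctc_pro = 10L,
                     degraded = 93L, wbc = 12L, cell_line = 16L, mef = 12L,
                     bulk_tumor = 34L, primary_single = 20L),
    n_genes = 2000L,
    depth_mean = 2e5,
    depth_sdlog = 0.15,
    filler_mean_log10 = 2.35,
    filler_sd_log10 = 0.55,
    class_distinctness = 0.65,
    tumor_distinctness = 1.2,
    distinctness_max_log10 = 2.3,
    dropout_rate = 0.3,
    dropout_floor_rpm = 10,
    degradation = list(housekeeping_log10 = -3, noise_sd_log10 = 1),
    correlation_targets = c(ctc_classical = 0.42, ctc_plt = 0.42,
                            ctc_pro = 0.42, wbc = 0.80, cell_line = 0.86,
                            mef = 0.80, bulk_tumor = 0.90,
                            primary_single = 0.38),
    planted = data.frame(
      gene = c("Klf4", "Igfbp5", "Dcn"),
      level_rpm = c(4000, 3500, 4000),
      cell_fraction = c(1, 1, 1),
      stringsAsFactors = FALSE),
    seed = 7L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown cohort key: ", bad[1L], call. = FALSE)
  for (nm in names(over)) {
    if (nm == "class_counts") {
      badc <- setdiff(names(over$class_counts), names(cfg$class_counts))
      if (length(badc)) stop("unknown class: ", badc[1L], call. = FALSE)
      cfg$class_counts[names(over$class_counts)] <-
        unlist(over$class_counts)
    } else if (nm == "correlation_targets") {
      cfg$correlation_targets[names(over[[nm]])] <- unlist(over[[nm]])
    } else if (nm == "planted" && is.list(over[[nm]]) &&
               !is.data.frame(over[[nm]])) {
      cfg$planted <- as.data.frame(over[[nm]], stringsAsFactors = FALSE)
    } else cfg[[nm]] <- over[[nm]]
  }
  class(cfg) <- "ctc_cohort_config"
  validateCohortConfig(cfg)
  cfg
}

#' @rdname cohortConfig
#' @param cfg a cohort configuration.
#' @export
validateCohortConfig <- function(cfg) {
  if (any(cfg$class_counts < 0) || any(cfg$class_counts != round(cfg$class_counts)))
    stop("class_counts must be non-negative integers", call. = FALSE)
  if (cfg$dropout_rate < 0 || cfg$dropout_rate > 1)
    stop("dropout_rate must lie in [0, 1]", call. = FALSE)
  if (any(cfg$correlation_targets <= -1) || any(cfg$correlation_targets > 1))
    stop("correlation targets must lie in (-1, 1]", call. = FALSE)
  if (!is.numeric(cfg$seed) || cfg$seed < 0 || cfg$seed != round(cfg$seed))
    stop("seed must be a non-negative integer", call. = FALSE)
  if (nrow(cfg$planted) > cfg$n_genes)
    stop("more planted genes than n_genes", call. = FALSE)
  if (cfg$n_genes < 300L)
    stop("n_genes must be at least 300 to hold the marker modules",
         call. = FALSE)
  invisible(cfg)
}

# ---- gene universe -------------------------------------------------------

# Named marker genes with baseline log10 abundance of the epithelial
# primary-tumor reference cell; all class effects are offsets from this.
.NAMED_BASELINE <- c(
  Gapdh = 4.00, Actb = 4.00,
  Krt7 = 3.18, Krt8 = 3.40, Krt18 = 3.40, Krt19 = 3.48, Epcam = 3.08,
  Egfr = 2.60, Cdh1 = 2.90, Muc1 = 2.78,
  Ptprc = 0.70, Csf3r = 0.50, Cd14 = 0.70, Fcgr3 = 0.70,
  Itga2b = 0.50, Itgb3 = 0.50, Pf4 = 0.50, Ppbp = 0.50,
  Cdh5 = 0.70, Vwf = 0.70, Thbd = 0.70, Pecam1 = 0.70, Mcam = 0.70,
  Sele = 0.70, Cd34 = 1.00,
  Aldh1a1 = 1.70, Aldh1a2 = 0.70, Prom1 = 1.78, Cd44 = 2.48, Met = 2.30,
  Cdh11 = 1.48, Vim = 2.48, S100a4 = 2.30, Itga5 = 2.18, Sdc1 = 2.60,
  Dcn = 1.48, Sparc = 1.60, Ccdc80 = 1.30, Col1a2 = 1.48, Col3a1 = 1.48,
  Timp2 = 1.78,
  Klf4 = 1.60, Igfbp5 = 1.30, Mki67 = 1.78
)

.MODULES <- list(
  prolif = list(n = 24L, base = 1.70),
  plt    = list(n = 21L, base = 0.50),
  pltres = list(n = 12L, base = 1.60),
  stroma = list(n = 25L, base = 1.40),
  ctcprog = list(n = 30L, base = 1.48),
  hema   = list(n = 30L, base = 0.90),
  mes    = list(n = 30L, base = 1.40)
)

.geneTable <- function(cfg) {
  ids <- names(.NAMED_BASELINE)
  base <- unname(.NAMED_BASELINE)
  module <- rep("marker", length(ids))
  for (m in names(.MODULES)) {
    ids <- c(ids, sprintf("%s_%02d", m, seq_len(.MODULES[[m]]$n)))
    base <- c(base, rep(.MODULES[[m]]$base, .MODULES[[m]]$n))
    module <- c(module, rep(m, .MODULES[[m]]$n))
  }
  nFill <- cfg$n_genes - length(ids)
  set.seed(substreamSeed(cfg$seed, "gene_baseline"))
  ids <- c(ids, sprintf("g%04d", seq_len(nFill)))
  base <- c(base, rnorm(nFill, cfg$filler_mean_log10, cfg$filler_sd_log10))
  module <- c(module, rep("filler", nFill))
  data.frame(gene_id = ids, baseline_log10 = base, module = module,
             stringsAsFactors = FALSE)
}

.moduleIdx <- function(gt, m) which(gt$module == m)
.geneIdx <- function(gt, g) match(g, gt$gene_id)

# class effect matrix (log10 offsets relative to the tumor-epithelial
# reference), deterministic by design
.classEffects <- function(gt, cfg) {
  G <- nrow(gt)
  classes <- names(cfg$class_counts)
  E <- matrix(0, length(classes), G, dimnames = list(classes, gt$gene_id))
  gi <- function(g) .geneIdx(gt, g)
  epi <- c("Krt7", "Krt8", "Krt18", "Krt19", "Epcam", "Egfr", "Cdh1", "Muc1")

  # classical CTC: planted trio very high, partial ECM, biphenotypic EMT,
  # Aldh1a2 stem isoform up, low proliferation, CTC expression program
  cl <- numeric(G)
  pl <- cfg$planted
  pidx <- gi(pl$gene)
  if (anyNA(pidx)) stop("planted gene absent from gene table", call. = FALSE)
  cl[pidx] <- log10(pl$level_rpm) - gt$baseline_log10[pidx]
  cl[gi(c("Sparc", "Ccdc80", "Col1a2", "Col3a1", "Timp2"))] <-
    c(0.70, 1.00, 0.82, 0.82, 0.52)
  cl[gi("Cdh1")] <- -1.2; cl[gi("Muc1")] <- -1.0
  cl[gi(c("Cdh11", "Vim", "S100a4", "Itga5", "Sdc1"))] <-
    c(0.9, 0.5, -0.8, -0.6, -0.6)
  cl[gi("Aldh1a2")] <- 1.48
  cl[gi("Mki67")] <- -0.8
  cl[.moduleIdx(gt, "ctcprog")] <- 0.8
  E["ctc_classical", ] <- cl

  # platelet-adhered: classical plus an additive platelet-transcript
  # component plus a residual platelet-induced expression module that
  # survives digital removal of annotated platelet transcripts
  plt <- cl
  plt[gi(c("Itga2b", "Itgb3", "Pf4", "Ppbp"))] <- 2.7
  plt[.moduleIdx(gt, "plt")] <- 1.8
  plt[.moduleIdx(gt, "pltres")] <- 0.8
  E["ctc_plt", ] <- plt

  # proliferative: classical plus a cell-cycle module
  pro <- cl
  pro[gi("Mki67")] <- 1.6
  pro[.moduleIdx(gt, "prolif")] <- 1.2
  E["ctc_pro", ] <- pro

  # degraded: a dying classical CTC whose housekeeping transcripts have
  # collapsed (margin >= 10x below the default QC threshold)
  dg <- cl
  dg[gi(c("Gapdh", "Actb"))] <- dg[gi(c("Gapdh", "Actb"))] +
    cfg$degradation$housekeeping_log10
  E["degraded", ] <- dg

  # leukocytes
  w <- numeric(G)
  w[gi(epi)] <- -2.0
  w[gi(c("Ptprc", "Csf3r", "Cd14", "Fcgr3"))] <- c(2.7, 2.3, 2.5, 2.5)
  w[gi(c("Itga2b", "Itgb3"))] <- 0.7
  w[.moduleIdx(gt, "hema")] <- 2.3
  w[gi(c("Cdh11", "Vim", "S100a4", "Itga5", "Sdc1"))] <- -0.8
  w[.moduleIdx(gt, "mes")] <- -0.5
  w[.moduleIdx(gt, "prolif")] <- -0.5
  w[gi("Aldh1a1")] <- 0.5
  E["wbc", ] <- w

  # embryonic fibroblasts: mesenchymal, Cd34-positive, ECM-producing
  mf <- numeric(G)
  mf[gi(epi)] <- -2.0
  mf[gi(c("Vim", "Cdh11", "S100a4", "Itga5"))] <- c(0.8, 1.3, 0.8, 0.7)
  mf[.moduleIdx(gt, "mes")] <- 1.6
  mf[.moduleIdx(gt, "hema")] <- -0.5
  mf[.moduleIdx(gt, "prolif")] <- -0.5
  mf[gi("Cd34")] <- 1.3
  mf[gi(c("Sparc", "Col1a2", "Col3a1", "Dcn"))] <- c(1.2, 1.2, 1.2, 0.8)
  mf[gi("Aldh1a1")] <- 0.5
  E["mef", ] <- mf

  # cultured cancer cell line: epithelial, proliferative, no CTC program
  clne <- numeric(G)
  clne[gi("Mki67")] <- 1.3
  clne[.moduleIdx(gt, "prolif")] <- 0.5
  clne[.moduleIdx(gt, "mes")] <- -0.5
  clne[.moduleIdx(gt, "stroma")] <- -0.5
  clne[.moduleIdx(gt, "hema")] <- -0.5
  E["cell_line", ] <- clne

  # diluted bulk tumor: epithelial reference plus stromal and leukocytic
  # admixture
  bt <- numeric(G)
  bt[.moduleIdx(gt, "stroma")] <- 1.0
  bt[gi(c("Dcn", "Sparc", "Ccdc80", "Col1a2", "Col3a1", "Timp2"))] <- 0.6
  bt[gi(c("Ptprc", "Csf3r", "Cd14", "Fcgr3", "Itga2b", "Itgb3"))] <- 0.5
  bt[.moduleIdx(gt, "hema")] <- 0.3
  bt[gi("Aldh1a2")] <- 0.8
  bt[gi("Vim")] <- 0.3
  E["bulk_tumor", ] <- bt

  # purified single primary tumor cells: the epithelial reference itself
  E["primary_single", ] <- 0
  E
}

# ---- noise calibration ---------------------------------------------------

# exact/delta moments of y = log10(N * cfac + 1), N ~ Poisson(lam)
.poisLog10Moments <- function(lam, cfac) {
  m1 <- m2 <- numeric(length(lam))
  big <- lam > 15
  if (any(big)) {
    lb <- lam[big]
    mu <- log10(lb * cfac + 1)
    v <- lb * (cfac / ((lb * cfac + 1) * log(10)))^2
    m1[big] <- mu
    m2[big] <- v + mu^2
  }
  if (any(!big)) {
    ls <- lam[!big]
    n <- 0:60
    P <- outer(ls, n, function(l, k) dpois(k, l))
    y <- log10(n * cfac + 1)
    m1[!big] <- as.vector(P %*% y)
    m2[!big] <- as.vector(P %*% y^2)
  }
  list(m1 = m1, m2 = m2)
}

# Per-gene mean and variance of y = log10(rpm + 1) under per-cell
# log-normal abundance noise (per-gene sd sigma[g] on the log10 scale),
# Poisson sampling at the given depth and Bernoulli dropout, via
# Gauss-Hermite quadrature over the noise. Library-size renormalization
# is approximated by its expectation: the whole profile is deflated by
# the lognormal mass-inflation factor sum(rpm * 10^(sigma^2 ln10 / 2)) /
# sum(rpm), which is what the per-cell softmax converges to over many
# genes.
.logExprMoments <- function(rpm, sigma, dropP, depth, nNodes = 9L) {
  gh <- pracma::gaussHermite(nNodes)
  w <- gh$w / sqrt(pi)
  z <- sqrt(2) * gh$x
  cfac <- 1e6 / depth
  massFactor <- sum(rpm * 10^(sigma^2 * log(10) / 2)) / sum(rpm)
  m1 <- m2 <- numeric(length(rpm))
  for (k in seq_len(nNodes)) {
    lam <- depth * (rpm / 1e6) * 10^(sigma * z[k]) / massFactor
    mom <- .poisLog10Moments(lam, cfac)
    m1 <- m1 + w[k] * mom$m1
    m2 <- m2 + w[k] * mom$m2
  }
  m1d <- (1 - dropP) * m1
  m2d <- (1 - dropP) * m2
  list(mean = m1d, var = pmax(m2d - m1d^2, 0))
}

# expected pairwise Pearson correlation (across genes, on log10(rpm+1))
# between two cells sharing the given abundance profile, at class noise
# scale s (per-gene sd = s * susceptibility[g])
.predictPairCorrelation <- function(rpm, s, susceptibility, dropP, depth) {
  mom <- .logExprMoments(rpm, s * susceptibility, dropP, depth)
  S <- var(mom$mean)
  W <- mean(mom$var)
  S / (S + W)
}

# Solve for the class noise scale that attains the target correlation:
# r(s) is monotone decreasing, so it is evaluated on a coarse grid and
# the target inverted by monotone interpolation (refined once).
.calibrateNoise <- function(rpm, target, susceptibility, dropP, depth) {
  grid <- c(0.05, 0.15, 0.3, 0.5, 0.7, 0.9, 1.1, 1.4)
  r <- vapply(grid, .predictPairCorrelation, 1,
              rpm = rpm, susceptibility = susceptibility,
              dropP = dropP, depth = depth)
  if (target > r[1L]) {
    warning("correlation target ", target,
            " unattainable; using minimal noise")
    return(grid[1L])
  }
  if (target < r[length(r)]) return(grid[length(grid)])
  s0 <- stats::approx(rev(r), rev(grid), xout = target, ties = "ordered")$y
  # one secant refinement around the interpolated solution
  r0 <- .predictPairCorrelation(rpm, s0, susceptibility, dropP, depth)
  i <- findInterval(-target, -r)  # r is decreasing
  slope <- (grid[i + 1L] - grid[i]) / (r[i + 1L] - r[i])
  max(grid[1L], s0 + (target - r0) * slope)
}

# ---- cohort simulation ---------------------------------------------------

#' Simulate a synthetic single-cell cohort
#'
#' Generates a counts matrix plus ground truth for the configured cell
#' classes. Deterministic given the config seed: all randomness flows
#' through named substreams (gene baselines, per-class abundance offsets,
#' per-class cell noise), so identical configs give bit-identical output
#' and adding cells of one class never perturbs another.
#'
#' Construction guarantees, relied on downstream: degraded cells carry
#' housekeeping transcripts at least 10-fold below the default QC
#' threshold in expectation while viable cells sit at least 10-fold above
#' it; planted signature genes exceed their target level in the configured
#' fraction of tumor-derived CTC cells; each class's per-cell noise is
#' calibrated so its mean intracluster pairwise correlation matches its
#' configured target in expectation.
#'
#' @param cfg a \code{\link{cohortConfig}}.
#' @return a list with elements \code{matrix} (a counts
#'   \linkS4class{CTCExperiment} with per-cell \code{class}, \code{animal},
#'   \code{viable} and \code{candidate_ctc} annotations) and \code{truth}
#'   (list of \code{cells} and \code{genes} data frames).
#' @examples
#' sim <- simulateCohort(cohortConfig(
#'   class_counts = c(ctc_classical = 4, wbc = 3), n_genes = 400))
#' sim$matrix
#' @export
simulateCohort <- function(cfg = cohortConfig()) {
  validateCohortConfig(cfg)
  gt <- .geneTable(cfg)
  E <- .classEffects(gt, cfg)
  G <- nrow(gt)
  classes <- names(cfg$class_counts)

  # Bounded class-distinctness offsets, restricted to the lower-abundance
  # transcriptome: cell-type identity programs live among moderately
  # expressed genes, while the most abundant (housekeeping-like)
  # transcripts are shared across cell types. The bound keeps any single
  # gene's between-class shift well below the deterministic marker
  # effects, so no background gene can cross the selection cascade's
  # rank-product and ubiquity thresholds by offset alone. The tumor
  # lineage (bulk replicates and purified single cells) shares one
  # offset; degraded cells inherit the classical offset (they are dying
  # CTCs of the same origin).
  # the tumor lineage gets a wider offset so that the highly
  # heterogeneous purified single tumor cells still cohere with their
  # matched bulk replicates, as they do in the study
  uMask <- gt$baseline_log10 < cfg$distinctness_max_log10 &
    gt$module != "marker"
  offsetFor <- function(cls) {
    key <- switch(cls,
                  bulk_tumor = "tumor", primary_single = "tumor",
                  degraded = "ctc_classical", cls)
    a <- if (key == "tumor") cfg$tumor_distinctness
         else cfg$class_distinctness
    set.seed(substreamSeed(cfg$seed, paste0("offset_", key)))
    runif(G, -a, a) * uMask
  }
  U <- t(vapply(classes, offsetFor, numeric(G)))

  counts <- matrix(0, G, 0)
  meta <- data.frame(cell_id = character(), class = character(),
                     animal = character(), stringsAsFactors = FALSE)
  mice <- paste0("KPC", 1:5)
  tumors <- paste0("Tu", 1:4)

  # noise susceptibility: housekeeping transcripts are biologically
  # stable and planted signature genes are, by construction, uniformly
  # high across their carrier cells; both get damped per-cell noise so
  # the QC and ubiquity guarantees hold under the heavy-tailed cell noise
  # the heterogeneity targets require
  sus <- rep(1, G)
  sus[.geneIdx(gt, c("Gapdh", "Actb"))] <- 0.2
  sus[.geneIdx(gt, cfg$planted$gene)] <- 0.3

  for (cls in classes) {
    n <- cfg$class_counts[[cls]]
    if (n == 0L) next
    profLog <- gt$baseline_log10 + E[cls, ] + U[cls, ]

    # planted signature genes carried by only a fraction of cells are
    # handled per cell below
    plIdx <- .geneIdx(gt, cfg$planted$gene)
    plFrac <- cfg$planted$cell_fraction
    isCtc <- cls %in% c("ctc_classical", "ctc_plt", "ctc_pro", "degraded")

    w0 <- 10^profLog
    profRpm <- w0 / sum(w0) * 1e6
    dropP <- ifelse(profRpm < cfg$dropout_floor_rpm, cfg$dropout_rate, 0)

    sigma <- if (cls == "degraded") cfg$degradation$noise_sd_log10
             else .calibrateNoise(profRpm, cfg$correlation_targets[[cls]],
                                  sus, dropP, cfg$depth_mean)

    set.seed(substreamSeed(cfg$seed, paste0("cells_", cls)))
    depth <- rlnorm(n, log(cfg$depth_mean), cfg$depth_sdlog)
    eps <- matrix(rnorm(G * n, 0, sigma * sus), G, n)
    lamLog <- profLog + eps
    if (isCtc && any(plFrac < 1)) {
      for (j in seq_along(plIdx)) {
        drop_cells <- runif(n) > plFrac[j]
        lamLog[plIdx[j], drop_cells] <-
          gt$baseline_log10[plIdx[j]] + U[cls, plIdx[j]] +
          eps[plIdx[j], drop_cells]
      }
    }
    wgt <- 10^lamLog
    p <- sweep(wgt, 2L, colSums(wgt), "/")
    cnt <- matrix(rpois(G * n, sweep(p, 2L, depth, "*")), G, n)
    dropIdx <- which(dropP > 0)
    if (length(dropIdx) && cfg$dropout_rate > 0) {
      keep <- matrix(rbinom(length(dropIdx) * n, 1L,
                            1 - cfg$dropout_rate), length(dropIdx), n)
      cnt[dropIdx, ] <- cnt[dropIdx, ] * keep
    }
    ids <- sprintf("%s_%03d", cls, seq_len(n))
    animal <- switch(cls,
      ctc_classical = , ctc_plt = , ctc_pro = , degraded =
        mice[(seq_len(n) - 1L) %% 5L + 1L],
      bulk_tumor = tumors[(seq_len(n) - 1L) %% 4L + 1L],
      primary_single = rep("TuGMP3", n),
      rep(paste0("ctrl_", cls), n))
    counts <- cbind(counts, cnt)
    meta <- rbind(meta, data.frame(cell_id = ids, class = cls,
                                   animal = animal, stringsAsFactors = FALSE))
  }
  colnames(counts) <- meta$cell_id
  rownames(counts) <- gt$gene_id

  meta$viable <- meta$class != "degraded"
  meta$candidate_ctc <- meta$class %in%
    c("ctc_classical", "ctc_plt", "ctc_pro", "degraded")
  # the clustering-level truth: bulk replicates and purified tumor single
  # cells belong to one tumor cluster
  meta$cluster_group <- ifelse(
    meta$class %in% c("bulk_tumor", "primary_single"), "tumor", meta$class)

  deDelta <- if ("ctc_classical" %in% classes && "bulk_tumor" %in% classes)
    E["ctc_classical", ] - E["bulk_tumor", ] else rep(0, G)
  genesTruth <- data.frame(
    gene_id = gt$gene_id, module = gt$module,
    baseline_log10 = gt$baseline_log10,
    planted = gt$gene_id %in% cfg$planted$gene,
    de_vs_tumor = ifelse(deDelta > 0.3, "up",
                         ifelse(deDelta < -0.3, "down", "null")),
    stringsAsFactors = FALSE)

  mat <- CTCExperiment(counts, unit = "counts",
                       cellMeta = meta[, -1L, drop = FALSE])
  list(matrix = mat,
       truth = list(cells = meta, genes = genesTruth))
}

#' Plant a high-expression signature into a matrix
#'
#' Raises the given genes above \code{level} in (at least) a fraction of
#' the target cells, leaving other cells untouched; used to build fixtures
#' for the threshold-selection screens. On rpm matrices the remaining
#' genes of an edited cell are rescaled so the column still sums to 10^6;
#' the planted value carries a 3x margin over \code{level} so the
#' exceedance survives rescaling. On counts matrices the planted counts
#' are chosen so the gene exceeds \code{level} after rpm normalization.
#'
#' @param x a \linkS4class{CTCExperiment} (\code{counts} or \code{rpm}).
#' @param genes character vector of gene ids to plant (must exist).
#' @param level target rpm level to exceed.
#' @param cellFraction fraction of target cells receiving the signature
#'   (0 leaves the matrix unchanged).
#' @param targetCells character vector of cell ids.
#' @param seed integer seed for choosing which cells receive it.
#' @return the modified \linkS4class{CTCExperiment}.
#' @export
plantSignature <- function(x, genes, level, cellFraction, targetCells,
                           seed = 1L) {
  gidx <- .matchGenes(genes, geneIds(x))
  cidx <- .matchGenes(targetCells, cellIds(x), what = "cell")
  nPick <- ceiling(cellFraction * length(cidx))
  if (nPick == 0L) return(x)
  set.seed(substreamSeed(seed, "plant"))
  pick <- cidx[sample(length(cidx), nPick)]
  v <- exprValues(x)
  target <- 3 * level
  for (j in pick) {
    if (exprUnit(x) == "rpm") {
      v[gidx, j] <- target
      others <- setdiff(seq_len(nrow(v)), gidx)
      s <- sum(v[others, j])
      if (s > 0) v[others, j] <- v[others, j] * (1e6 - target * length(gidx)) / s
    } else {
      L <- sum(v[, j])
      v[gidx, j] <- ceiling(target * (L - v[gidx, j]) / (1e6 - target))
    }
  }
  CTCExperiment(v, unit = exprUnit(x),
                cellMeta = as.data.frame(cellData(x)))
}
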