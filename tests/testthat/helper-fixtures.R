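# shared fixtures and independent oracles, built in code

# small counts matrix with names
tinyCounts <- function(values, genes = NULL, cells = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(cells)) cells <- sprintf("c%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, cells)
  CTCExperiment(m, unit = "counts")
}

rpmOf <- function(values, ...) normalizeRpm(tinyCounts(values, ...))

# reduced cohort configuration used by most tests (full marker modules,
# smaller filler complement and cohort)
smallCohort <- function(seed = 7, ...) {
  cohortConfig(
    n_genes = 600L,
    class_counts = c(ctc_classical = 10, ctc_plt = 8, ctc_pro = 6,
                     degraded = 12, wbc = 6, cell_line = 8, mef = 6,
                     bulk_tumor = 8, primary_single = 6),
    seed = seed, ...)
}

# the full-size default cohort and its processed states, computed once
# per test run and shared across test files
.cache <- new.env(parent = emptyenv())
cachedDefaultRun <- function() {
  if (!is.null(.cache$run)) return(.cache$run)
  sim <- simulateCohort(cohortConfig())
  qc <- qcFilter(sim$matrix)
  rpm <- normalizeRpm(qc$matrix)
  lg <- logTransform(rpm)
  pol <- medianPolishMatrix(lg)
  cl <- hierarchicalCluster(pol$matrix, k = 7)
  scores <- scorePanels(rpm, cl)
  mki67 <- proliferationLevel(rpm, cl)
  calls <- callClasses(scores, mki67)
  labs <- clusterLabels(cl)
  cellClass <- setNames(calls$class[match(labs, calls$cluster)], names(labs))
  classical <- names(cellClass)[cellClass == "CTC-classical"]
  bulk <- cellIds(rpm)[cellData(rpm)$class == "bulk_tumor"]
  rp <- rankProduct(rpm, classical, bulk)
  .cache$run <- list(sim = sim, qc = qc, rpm = rpm, lg = lg, pol = pol,
                     cl = cl, scores = scores, mki67 = mki67,
                     calls = calls, cellClass = cellClass,
                     classical = classical, bulk = bulk, rp = rp)
  .cache$run
}

truthGroupOf <- function(run, cells) {
  tc <- run$sim$truth$cells
  tc$cluster_group[match(cells, tc$cell_id)]
}

classMap <- c(ctc_classical = "CTC-classical", ctc_plt = "CTC-plt",
              ctc_pro = "CTC-pro", wbc = "WBC",
              cell_line = "cell-line-like", mef = "MEF-like",
              tumor = "tumor")

# ---- independent oracles --------------------------------------------------

# brute-force rank product: enumerate every A x B pair, rank the
# pseudocount-stabilized ratios by counting, average ties, take the
# geometric mean via prod()
bruteRankProduct <- function(rpmMat, aCols, bCols, pseudocount = 1) {
  G <- nrow(rpmMat)
  prodUp <- rep(1, G); prodDn <- rep(1, G); nP <- 0L
  for (a in aCols) for (b in bCols) {
    ratio <- (rpmMat[, a] + pseudocount) / (rpmMat[, b] + pseudocount)
    rUp <- vapply(seq_len(G), function(g) {
      gt <- sum(ratio > ratio[g])
      eq <- sum(ratio == ratio[g])
      gt + (eq + 1) / 2
    }, 1)
    prodUp <- prodUp * rUp
    prodDn <- prodDn * (G + 1 - rUp)
    nP <- nP + 1L
  }
  list(up = prodUp^(1 / nP), down = prodDn^(1 / nP))
}

# naive loop rpm normalization
bruteRpm <- function(counts) {
  out <- counts * 0
  for (j in seq_len(ncol(counts))) {
    s <- sum(counts[, j])
    if (s > 0) for (i in seq_len(nrow(counts)))
      out[i, j] <- counts[i, j] * 1e6 / s
  }
  out
}

# independent median polish (rows first, then columns)
bruteMedpolish <- function(x, maxIter = 10L, tol = 0.01) {
  r <- numeric(nrow(x)); cc <- numeric(ncol(x)); tt <- 0
  z <- x
  oldSum <- 0
  for (it in seq_len(maxIter)) {
    rd <- apply(z, 1, median)
    z <- z - rd
    r <- r + rd
    cd <- median(cc)
    tt <- tt + cd; cc <- cc - cd
    cd2 <- apply(z, 2, median)
    z <- sweep(z, 2, cd2)
    cc <- cc + cd2
    rd2 <- median(r)
    tt <- tt + rd2; r <- r - rd2
    newSum <- sum(abs(z))
    converged <- newSum == 0 || (abs(newSum - oldSum) < tol * newSum)
    oldSum <- newSum
    if (converged) break
  }
  list(overall = tt, row = r, col = cc, residuals = z)
}
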