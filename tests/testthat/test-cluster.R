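mkLog <- function(v) CTCExperiment(v, unit = "log_rpm")

test_that("hierarchical clustering recovers duplicated-column groups", {
  set.seed(5)
  g1 <- rnorm(40); g2 <- rnorm(40)
  v <- cbind(g1, g1 + rnorm(40, 0, 0.01), g1 + rnorm(40, 0, 0.01),
             g2, g2 + rnorm(40, 0, 0.01))
  dimnames(v) <- list(paste0("g", 1:40), paste0("c", 1:5))
  cl <- hierarchicalCluster(mkLog(v), k = 2)
  labs <- clusterLabels(cl)
  expect_identical(length(unique(labs[1:3])), 1L)
  expect_identical(length(unique(labs[4:5])), 1L)
  expect_false(labs[1] == labs[4])

  expect_identical(unname(unique(clusterLabels(
    hierarchicalCluster(mkLog(v), k = 1)))), 1L)
  expect_error(hierarchicalCluster(mkLog(v), k = 9), "k must lie")
})

test_that("a constant-expression cell raises an error naming the cell", {
  v <- matrix(c(1, 2, 3, 5, 5, 5), 3,
              dimnames = list(paste0("g", 1:3), c("ok", "flat")))
  expect_error(hierarchicalCluster(mkLog(v), k = 2), "flat")
})

test_that("clustering is invariant to cell-column permutation", {
  run <- cachedDefaultRun()
  pol <- run$pol$matrix
  set.seed(123)
  perm <- sample(ncol(pol))
  polp <- CTCExperiment(exprValues(pol)[, perm], unit = "polished")
  a <- clusterLabels(run$cl)
  b <- clusterLabels(hierarchicalCluster(polp, k = 7))
  # same partition: co-membership matrices agree
  cells <- names(a)
  expect_true(all(outer(a[cells], a[cells], "==") ==
                  outer(b[cells], b[cells], "==")))
})

test_that("PCA reports variance fractions and a fixed sign convention", {
  u <- c(1, 2, 3); w <- c(2, 1, 0, -1)
  v <- outer(u, w)
  dimnames(v) <- list(paste0("g", 1:3), paste0("c", 1:4))
  pc <- pcaCells(mkLog(v), 2)
  expect_equal(pc$variance_explained[1], 1)
  expect_true(all(diff(pc$variance_explained) <= 1e-12))
  expect_lte(sum(pc$variance_explained), 1 + 1e-12)
  # largest-magnitude loading entry is positive
  expect_gt(pc$loadings[which.max(abs(pc$loadings[, 1])), 1], 0)

  set.seed(8)
  v2 <- matrix(rnorm(200), 20, dimnames = list(paste0("g", 1:20),
                                               paste0("c", 1:10)))
  p1 <- pcaCells(mkLog(v2), 3)
  p2 <- pcaCells(mkLog(v2), 3)
  expect_identical(p1$coords, p2$coords)
})

test_that("two synthetic classes separate along the first component", {
  cfg <- smallCohort(seed = 2)
  cfg$class_counts[] <- 0L
  cfg$class_counts[c("wbc", "cell_line")] <- c(12L, 12L)
  sim <- simulateCohort(cfg)
  lg <- logTransform(normalizeRpm(sim$matrix))
  pc <- pcaCells(lg, 2)
  cls <- cellData(sim$matrix)$class
  sil <- cluster::silhouette(as.integer(factor(cls)),
                             dist(pc$coords[, 1, drop = FALSE]))
  expect_gt(mean(sil[, "sil_width"]), 0)
})

test_that("intracluster correlation handles the degenerate extremes", {
  v <- cbind(a = c(1, 5, 2, 4), b = c(1, 5, 2, 4), c = c(1, 5, 2, 4))
  rownames(v) <- paste0("g", 1:4)
  st <- intraclusterCorrelation(mkLog(v), nBoot = 100)
  expect_equal(st$r_mean, 1)
  expect_equal(st$ci_high - st$ci_low, 0)

  v2 <- cbind(a = c(1, 5, 2, 4), b = -c(1, 5, 2, 4))
  rownames(v2) <- paste0("g", 1:4)
  st2 <- intraclusterCorrelation(mkLog(v2), nBoot = 100)
  expect_equal(st2$r_mean, -1)

  v3 <- cbind(v, flat = rep(3, 4))
  expect_warning(st3 <- intraclusterCorrelation(mkLog(v3), nBoot = 100),
                 "constant")
  expect_equal(st3$n_cells, 3L)
  flat2 <- cbind(f1 = rep(1, 4), f2 = rep(2, 4))
  rownames(flat2) <- paste0("g", 1:4)
  expect_error(suppressWarnings(
    intraclusterCorrelation(mkLog(flat2), nBoot = 100)),
    "excluded|2 cells")
})

test_that("synthetic cell-line cells reach the reported homogeneity", {
  cfg <- cohortConfig(
    n_genes = 800L,
    class_counts = c(ctc_classical = 0, ctc_plt = 0, ctc_pro = 0,
                     degraded = 0, wbc = 0, cell_line = 16, mef = 0,
                     bulk_tumor = 0, primary_single = 0))
  sim <- simulateCohort(cfg)
  st <- intraclusterCorrelation(normalizeRpm(sim$matrix), nBoot = 500,
                                seed = 7)
  expect_gt(st$r_mean, 0.80)
  expect_lt(st$r_mean, 0.91)
})

test_that("bootstrap CI width shrinks with class size", {
  widths <- vapply(c(8L, 16L, 32L, 64L), function(n) {
    cfg <- cohortConfig(
      n_genes = 600L, seed = 21L,
      class_counts = c(ctc_classical = 0, ctc_plt = 0, ctc_pro = 0,
                       degraded = 0, wbc = n, cell_line = 0, mef = 0,
                       bulk_tumor = 0, primary_single = 0))
    sim <- simulateCohort(cfg)
    st <- intraclusterCorrelation(normalizeRpm(sim$matrix), nBoot = 400,
                                  seed = 3)
    st$ci_high - st$ci_low
  }, 1)
  expect_lt(widths[4], widths[1])
  expect_lt(cor(widths, c(8, 16, 32, 64), method = "spearman"), 0)
})

test_that("heterogeneity comparison: trivial, power, and calibration cases", {
  cfg <- cohortConfig(
    n_genes = 600L, seed = 13L,
    class_counts = c(ctc_classical = 16, ctc_plt = 0, ctc_pro = 0,
                     degraded = 0, wbc = 0, cell_line = 16, mef = 0,
                     bulk_tumor = 0, primary_single = 32))
  sim <- simulateCohort(cfg)
  lg <- logTransform(normalizeRpm(sim$matrix))
  cls <- cellData(sim$matrix)$class
  ctc <- cellIds(lg)[cls == "ctc_classical"]
  line <- cellIds(lg)[cls == "cell_line"]

  # near-identical groups: duplicate profiles -> p near 1
  v <- exprValues(lg)[, ctc]
  dup <- cbind(v, v + 1e-9)
  colnames(dup) <- c(paste0("a", seq_along(ctc)), paste0("b", seq_along(ctc)))
  cmp0 <- compareHeterogeneity(CTCExperiment(dup, unit = "log_rpm"),
                               colnames(dup)[seq_along(ctc)],
                               colnames(dup)[-seq_along(ctc)], nPerm = 199)
  expect_gt(cmp0$p_value, 0.5)

  # heterogeneous CTCs vs homogeneous cell line: strongly significant
  cmp <- compareHeterogeneity(lg, ctc, line, nPerm = 999, seed = 2)
  expect_gt(abs(cmp$statistic), 0.3)
  expect_lte(cmp$p_value, 0.002)

  # two random halves of one class: p approximately uniform
  prim <- cellIds(lg)[cls == "primary_single"]
  set.seed(99)
  pvals <- vapply(1:200, function(i) {
    sh <- sample(prim)
    compareHeterogeneity(lg, sh[1:16], sh[17:32], nPerm = 199,
                         seed = i)$p_value
  }, 1)
  expect_lt(mean(pvals < 0.05), 0.11)
  expect_gt(mean(pvals < 0.5), 0.3)

  expect_error(compareHeterogeneity(lg, ctc, ctc), "overlap")
})

test_that("digital transcript removal drops exactly the named genes", {
  run <- cachedDefaultRun()
  rpm <- run$rpm
  expect_identical(exprValues(suppressWarnings(
    removeTranscripts(rpm, character()))), exprValues(rpm))

  plt <- plateletTranscripts()
  out <- removeTranscripts(rpm, plt)
  expect_identical(nrow(out), nrow(rpm) - length(plt))
  expect_length(intersect(geneIds(out), plt), 0)
  expect_true(S4Vectors::metadata(out)$renormalized_after_removal)
  expect_true(all(abs(colSums(exprValues(out)) - 1e6) <= 1))

  expect_warning(removeTranscripts(rpm, c("NotThere", plt[1])), "absent")
  tiny <- rpmOf(matrix(c(3, 1), 1), genes = "only")
  expect_error(removeTranscripts(tiny, "only"), "zero genes")
})

test_that("platelet-adhered CTCs stay separable after platelet removal", {
  run <- cachedDefaultRun()
  cls <- cellData(run$rpm)$class
  keep <- cellIds(run$rpm)[cls %in% c("ctc_classical", "ctc_plt")]
  sub <- run$rpm[, keep]
  stripped <- removeTranscripts(sub, plateletTranscripts())
  pol <- medianPolishMatrix(logTransform(stripped))
  cl2 <- hierarchicalCluster(pol$matrix, k = 2)
  labs <- clusterLabels(cl2)
  truthCls <- cls[match(names(labs), cellIds(run$rpm))]
  tab <- table(truthCls, labs)
  agree <- sum(apply(tab, 2, max)) / length(labs)
  expect_gte(agree, 0.9)
})
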