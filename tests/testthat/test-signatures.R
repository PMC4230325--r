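test_that("panel scores are cell-mean detection fractions in [0, 1]", {
  panels <- GeneSetList(list(epithelial = c("e1", "e2"),
                             other = c("o1")))
  m <- rbind(e1 = c(2000, 2000, 0), e2 = c(2000, 2000, 0),
             o1 = c(0, 0, 0), fill = c(996000, 996000, 0))
  colnames(m) <- c("c1", "c2", "c3")
  x <- CTCExperiment(m, unit = "rpm")
  labels <- setNames(c(1L, 1L, 2L), colnames(m))
  sc <- scorePanels(x, labels, panels, rpmMin = 100)
  expect_equal(sc["1", "epithelial"], 1)     # all genes at 10x threshold
  expect_equal(sc["2", "epithelial"], 0)     # all-zero cluster
  expect_equal(sc["1", "other"], 0)

  gone <- GeneSetList(list(ghost = "absent_gene"))
  scg <- scorePanels(x, labels, gone)
  expect_true(is.na(scg["1", "ghost"]))
  expect_identical(attr(scg, "missing_panels"), "ghost")
  expect_error(scorePanels(x, labels, GeneSetList()), "non-empty")
})

test_that("the synthetic WBC class scores highest on the hematopoietic panel", {
  run <- cachedDefaultRun()
  wbcCluster <- names(which.max(table(
    clusterLabels(run$cl)[truthGroupOf(run, names(clusterLabels(run$cl))) == "wbc"])))
  lineage <- c("epithelial", "hematopoietic", "endothelial",
               "platelet", "mesenchymal")
  row <- run$scores[wbcCluster, lineage]
  expect_identical(names(which.max(row)), "hematopoietic")
})

test_that("ordered class rules annotate the default cohort correctly", {
  run <- cachedDefaultRun()
  truth <- truthGroupOf(run, names(run$cellClass))
  acc <- mean(run$cellClass == classMap[truth])
  expect_gte(acc, 0.95)
  # the platelet rule precedes the classical-epithelial rule
  s <- run$scores[1, ]
  s[] <- 0; s[c("epithelial", "platelet", "ctc_enriched")] <- c(0.9, 0.8, 0.9)
  call <- callClasses(matrix(s, 1, dimnames = list("x", names(s))),
                      setNames(0.1, "x"))
  expect_identical(call$class, "CTC-plt")
  # an all-zero cluster is unclassified
  z <- s; z[] <- 0
  expect_identical(callClasses(matrix(z, 1, dimnames = list("x", names(z))),
                               setNames(0, "x"))$class, "unclassified")
  expect_error(callClasses(run$scores, run$mki67, rules = list()), "empty")
})

test_that("class calls are stable under duplication of every cell", {
  run <- cachedDefaultRun()
  rpm <- run$rpm
  v <- exprValues(rpm)
  dup <- cbind(v, v)
  colnames(dup) <- c(colnames(v), paste0(colnames(v), "_dup"))
  xd <- CTCExperiment(dup, unit = "rpm")
  labs <- clusterLabels(run$cl)
  labsDup <- setNames(c(labs, labs), colnames(dup))
  scd <- scorePanels(xd, labsDup)
  mkd <- proliferationLevel(xd, labsDup)
  expect_identical(callClasses(scd, mkd), callClasses(run$scores, run$mki67))
})

test_that("EMT and stem summaries capture the constructed group differences", {
  run <- cachedDefaultRun()
  cls <- cellData(run$rpm)$class
  groups <- list(ctc = cellIds(run$rpm)[cls == "ctc_classical"],
                 tumor = cellIds(run$rpm)[cls == "bulk_tumor"])
  sm <- emtStemSummary(run$rpm, groups,
                       epithelial = c("Cdh1", "Muc1"),
                       mesenchymal = c("Cdh11", "Vim", "S100a4"),
                       stem = c("Aldh1a1", "Aldh1a2"))
  med <- function(g, grp) sm$median[sm$gene == g & sm$group == grp]
  expect_lt(med("Cdh1", "ctc"), med("Cdh1", "tumor"))
  expect_gt(med("Aldh1a2", "ctc"), med("Aldh1a2", "tumor"))
  expect_gt(med("Cdh11", "ctc"), med("Cdh11", "tumor"))

  same <- emtStemSummary(run$rpm, list(a = groups$ctc, b = groups$ctc),
                         "Cdh1", "Vim", "Aldh1a2")
  expect_equal(same$median[same$group == "a"], same$median[same$group == "b"])
  expect_error(emtStemSummary(run$rpm, groups, character(), "Vim", "Cd44"),
               "non-empty")
})

test_that("stem-marker level and mesenchymal score are uncorrelated in CTCs", {
  run <- cachedDefaultRun()
  cls <- cellData(run$rpm)$class
  ctc <- cellIds(run$rpm)[cls == "ctc_classical"]
  v <- log10(exprValues(run$rpm)[, ctc] + 1)
  stem <- v["Aldh1a2", ]
  mes <- colMeans(v[c("Cdh11", "Vim"), ])
  expect_lt(abs(cor(stem, mes)), 0.2)
})

test_that("selection cascade applies the printed boundary rules exactly", {
  # 10 cells; gene 'edge' above threshold in exactly 9 (90%) of them
  m <- rbind(edge = c(rep(200, 9), 50),
             low = rep(200, 10),
             out = c(rep(200, 8), 50, 50))
  colnames(m) <- sprintf("c%02d", 1:10)
  fill <- matrix(0, 1, 10, dimnames = list("fill", colnames(m)))
  v <- rbind(m, 1e6 - colSums(m))
  rownames(v)[4] <- "fill"
  x <- CTCExperiment(v, unit = "rpm")
  rp <- S4Vectors::DataFrame(
    gene_id = c("edge", "low", "out", "fill"),
    direction = "up_in_A",
    rp = c(100, 300, 100, 1000),  # 'low' sits exactly on the RP bound
    n_pairs = 1L)
  sel <- selectEnrichedGenes(rp, x, colnames(m),
                             rpMax = 300, rpmMin = 100,
                             cellFractionMin = 0.90)
  expect_identical(sel, "edge")   # >= 90% inclusive, RP < 300 strict
  expect_identical(selectEnrichedGenes(rp, x, colnames(m), rpmMin = Inf),
                   character())
  expect_error(selectEnrichedGenes(rp, x, character()), "empty")
})

test_that("selection and ECM screen equal a naive double-loop filter", {
  set.seed(61)
  for (i in 1:25) {
    nG <- 30; nC <- 12
    m <- matrix(rexp(nG * nC, 1 / 150), nG, nC)
    x <- rpmOf(m)
    v <- exprValues(x)
    rpv <- sample(50:600, nG)
    rp <- S4Vectors::DataFrame(gene_id = geneIds(x), direction = "up_in_A",
                               rp = rpv, n_pairs = 1L)
    sel <- selectEnrichedGenes(rp, x, cellIds(x), rpMax = 300,
                               rpmMin = 100, cellFractionMin = 0.5)
    naive <- character()
    for (g in seq_len(nG)) {
      cnt <- 0
      for (cc in seq_len(nC)) if (v[g, cc] > 100) cnt <- cnt + 1
      if (rpv[g] < 300 && cnt / nC >= 0.5)
        naive <- c(naive, geneIds(x)[g])
    }
    expect_identical(sel, naive)

    scr <- ecmScreen(x, geneIds(x), rpmMin = 100, cellFractionMin = 0.25)
    naive2 <- character()
    for (g in seq_len(nG)) {
      cnt <- sum(v[g, ] > 100)
      if (cnt / nC > 0.25) naive2 <- c(naive2, geneIds(x)[g])
    }
    expect_identical(as.character(scr), naive2)
  }
})

test_that("selection output is invariant to gene and cell order", {
  set.seed(71)
  m <- matrix(rexp(200, 1 / 150), 20, 10)
  x <- rpmOf(m)
  rp <- S4Vectors::DataFrame(gene_id = geneIds(x), direction = "up_in_A",
                             rp = sample(50:500, 20), n_pairs = 1L)
  sel <- selectEnrichedGenes(rp, x, cellIds(x), cellFractionMin = 0.4)
  gperm <- sample(nrow(m)); cperm <- sample(ncol(m))
  xp <- CTCExperiment(exprValues(x)[gperm, cperm], unit = "rpm")
  rpp <- rp[gperm, ]
  selp <- selectEnrichedGenes(rpp, xp, cellIds(xp), cellFractionMin = 0.4)
  expect_setequal(sel, selp)
})

test_that("the human ECM screen returns exactly the six planted genes", {
  # fixture: 20 human CTC profiles, 12 candidate ECM genes, six planted
  # above 100 rpm in > 15% of cells
  cand <- c("SPARC", "MGP", "SPON2", "COL1A1", "COL3A1", "TIMP1",
            "DCN", "CCDC80", "FN1", "LAMB1", "POSTN", "BGN")
  planted <- cand[1:6]
  m <- matrix(1, length(cand), 20, dimnames = list(cand, sprintf("h%02d", 1:20)))
  m[planted, 1:4] <- 5000          # 4/20 = 20% of cells, above threshold
  m[cand[7:12], 1] <- 5000         # only 1/20 = 5% -> excluded
  filler <- matrix(0, 1, 20, dimnames = list(c("KRT19"), colnames(m)))
  filler[1, ] <- 1e6 - colSums(m)
  x <- CTCExperiment(rbind(m, filler), unit = "rpm")
  hits <- ecmScreen(x, cand, rpmMin = 100, cellFractionMin = 0.15)
  expect_setequal(as.character(hits), planted)

  # boundary: exactly 15% of cells is excluded under the strict rule
  m2 <- matrix(0, 1, 20, dimnames = list("EDGE", sprintf("h%02d", 1:20)))
  m2[1, 1:3] <- 5000               # 3/20 = 15%
  f2 <- matrix(1e6 - colSums(m2), 1, 20,
               dimnames = list("fill", colnames(m2)))
  x2 <- CTCExperiment(rbind(m2, f2), unit = "rpm")
  expect_length(ecmScreen(x2, "EDGE", 100, 0.15, strictFraction = TRUE), 0)
  expect_identical(as.character(
    ecmScreen(x2, "EDGE", 100, 0.15, strictFraction = FALSE)), "EDGE")
  expect_error(ecmScreen(x2, "MISSING"), "no candidate")
})

test_that("coexpression counting reproduces the 1-of-20 fixture", {
  # 20 purified tumor single cells: keratin high everywhere, the ECM gene
  # planted in exactly one cell
  m <- rbind(Krt19 = rep(5000, 20), Sparc = c(5000, rep(0, 19)))
  colnames(m) <- sprintf("t%02d", 1:20)
  fill <- matrix(1e6 - colSums(m), 1, 20,
                 dimnames = list("fill", colnames(m)))
  x <- CTCExperiment(rbind(m, fill), unit = "rpm")
  co <- coexpressionCount(x, "Sparc", "Krt19", rpmMin = 100)
  expect_identical(co$count, 1L)
  expect_equal(co$fraction, 0.05)

  expect_identical(coexpressionCount(x, "Sparc", "Krt19", Inf)$count, 0L)
  expect_identical(coexpressionCount(x, "Krt19", "Krt19")$count, 20L)
  expect_error(coexpressionCount(x, "Sparc", "NOPE"), "unknown gene")
})

test_that("over-representation reports exact tables, ORs and BH q-values", {
  universe <- sprintf("u%03d", 1:100)
  gl <- universe[1:10]
  sets <- GeneSetList(list(hit = universe[c(1:5, 11:15)],
                           disjoint = universe[90:99]))
  res <- overRepresentation(gl, sets, universe)
  hit <- res[res$set == "hit", ]
  expect_identical(c(hit$a, hit$b, hit$c, hit$d), c(5L, 5L, 5L, 85L))
  expect_equal(hit$odds_ratio, 17)
  # dual route: the exact tail must match fisher.test
  ft <- fisher.test(matrix(c(5, 5, 5, 85), 2), alternative = "greater")
  expect_equal(hit$p, ft$p.value, tolerance = 1e-12)

  dis <- res[res$set == "disjoint", ]
  expect_lte(dis$odds_ratio, 1)
  expect_gte(dis$p, 0.5)
  expect_equal(res$q, p.adjust(res$p, "BH"))
  expect_error(overRepresentation(gl, sets, character()), "empty")
  expect_error(overRepresentation("alien", sets, universe), "subset")
})

test_that("over-representation q-values are calibrated under the null", {
  universe <- sprintf("u%03d", 1:200)
  set.seed(41)
  falseRates <- vapply(1:200, function(i) {
    gl <- sample(universe, 15)
    sets <- GeneSetList(setNames(
      lapply(1:50, function(j) sample(universe, 10)),
      paste0("s", 1:50)))
    any(overRepresentation(gl, sets, universe)$q <= 0.05)
  }, TRUE)
  expect_lte(mean(falseRates), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})
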