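#' Score marker panels per cluster
#'
#' For each cluster and panel, the score is the mean over the cluster's
#' cells of the fraction of panel genes expressed above \code{rpmMin}
#' (strict >). Scores lie in [0, 1]; a panel with no genes present in the
#' matrix is reported as missing (NA) and listed in the
#' \code{"missing_panels"} attribute.
#'
#' @param x an rpm \linkS4class{CTCExperiment}.
#' @param assignment a \linkS4class{ClusterAssignment} (or named label
#'   vector) covering cells of \code{x}.
#' @param panels a \linkS4class{GeneSetList} (non-empty).
#' @param rpmMin expression threshold (default 100 rpm).
#' @return a clusters x panels numeric matrix.
#' @export
scorePanels <- function(x, assignment, panels = markerPanels(),
                        rpmMin = 100) {
  if (!length(panels)) stop("panels must be non-empty", call. = FALSE)
  labels <- if (is(assignment, "ClusterAssignment"))
    clusterLabels(assignment) else assignment
  cells <- intersect(names(labels), cellIds(x))
  v <- exprValues(x)[, cells, drop = FALSE]
  labels <- labels[cells]
  clusters <- sort(unique(labels))
  out <- matrix(NA_real_, length(clusters), length(panels),
                dimnames = list(as.character(clusters), names(panels)))
  missing <- character()
  for (pn in names(panels)) {
    genes <- intersect(panels[[pn]], rownames(v))
    if (!length(genes)) { missing <- c(missing, pn); next }
    frac <- colMeans(v[genes, , drop = FALSE] > rpmMin)
    for (cl in clusters)
      out[as.character(cl), pn] <- mean(frac[labels == cl])
  }
  attr(out, "missing_panels") <- missing
  out
}

#' Default class-call rules
#'
#' The ordered annotation rules applied to per-cluster panel scores; the
#' first matching rule wins and unmatched clusters are
#' \code{"unclassified"}. Precedence is platelet > leukocyte > fibroblast
#' > proliferative > classical-epithelial > tumor, mirroring the cohort
#' structure: platelet and proliferative signatures override epithelial
#' content, tumor-derived CTC classes carry the CTC-enriched trio that
#' cultured cell-line cells lack, and bulk/primary tumor cells are
#' epithelial without it. Each rule is a predicate over the cluster's
#' panel-score row and its mean Mki67 log10(rpm+1) level.
#'
#' @param scoreMin panel-score threshold treated as "strong expression".
#' @param mki67LogRpm Mki67 mean log10(rpm+1) above which a cluster is
#'   called proliferative (2 corresponds to ~100 rpm).
#' @return an ordered list of \code{list(class=, test=)} rules.
#' @export
defaultClassRules <- function(scoreMin = 0.5, mki67LogRpm = 2) {
  list(
    list(class = "CTC-plt", test = function(s, mki67)
      isTRUE(s[["platelet"]] >= scoreMin)),
    list(class = "WBC", test = function(s, mki67)
      isTRUE(s[["hematopoietic"]] >= scoreMin &&
             s[["epithelial"]] < scoreMin)),
    list(class = "MEF-like", test = function(s, mki67)
      isTRUE(s[["mesenchymal"]] >= scoreMin &&
             s[["epithelial"]] < 0.25)),
    list(class = "CTC-pro", test = function(s, mki67)
      isTRUE(s[["epithelial"]] >= scoreMin && mki67 > mki67LogRpm &&
             s[["ctc_enriched"]] >= scoreMin)),
    list(class = "cell-line-like", test = function(s, mki67)
      isTRUE(s[["epithelial"]] >= scoreMin && mki67 > mki67LogRpm)),
    list(class = "CTC-classical", test = function(s, mki67)
      isTRUE(s[["epithelial"]] >= scoreMin &&
             s[["ctc_enriched"]] >= scoreMin)),
    list(class = "tumor", test = function(s, mki67)
      isTRUE(s[["epithelial"]] >= scoreMin))
  )
}

#' Annotate clusters with cell classes
#'
#' Applies an ordered rule list to per-cluster panel scores plus the
#' cluster's mean Mki67 log expression; every clustered cell inherits
#' exactly one class through its cluster. Stable under duplication of
#' every cell.
#'
#' @param scores clusters x panels matrix from \code{\link{scorePanels}}.
#' @param mki67 named numeric vector: per-cluster mean log10(rpm+1) of
#'   Mki67 (clusters as names), or a single number recycled.
#' @param rules ordered rule list (non-empty); see
#'   \code{\link{defaultClassRules}}.
#' @return a data.frame with columns \code{cluster} and \code{class}.
#' @export
callClasses <- function(scores, mki67, rules = defaultClassRules()) {
  if (!length(rules)) stop("rule list must not be empty", call. = FALSE)
  clusters <- rownames(scores)
  if (length(mki67) == 1L && is.null(names(mki67)))
    mki67 <- setNames(rep(mki67, length(clusters)), clusters)
  cls <- vapply(clusters, function(cl) {
    s <- scores[cl, ]
    m <- mki67[[cl]]
    for (r in rules) if (isTRUE(r$test(s, m))) return(r$class)
    "unclassified"
  }, "")
  data.frame(cluster = clusters, class = unname(cls),
             stringsAsFactors = FALSE)
}

#' Mean Mki67 log expression per cluster
#'
#' Convenience helper computing, per cluster, the mean log10(rpm + 1)
#' level of a proliferation marker gene.
#'
#' @param x an rpm \linkS4class{CTCExperiment}.
#' @param assignment a \linkS4class{ClusterAssignment} or named labels.
#' @param gene marker gene id (default Mki67).
#' @return named numeric vector over clusters.
#' @export
proliferationLevel <- function(x, assignment, gene = "Mki67") {
  labels <- if (is(assignment, "ClusterAssignment"))
    clusterLabels(assignment) else assignment
  cells <- intersect(names(labels), cellIds(x))
  gidx <- .matchGenes(gene, geneIds(x))
  v <- log10(exprValues(x)[gidx, cells] + 1)
  vapply(split(v, labels[cells]), mean, 1)
}

#' Epithelial / mesenchymal / stem marker distribution summaries
#'
#' Per-gene, per-group medians and quartiles on log10(rpm + 1), with the
#' direction of the median difference against the first group; used to
#' examine loss of epithelial markers and heterogeneous gain of
#' mesenchymal and stem markers in CTCs relative to tumors.
#'
#' @param x an rpm \linkS4class{CTCExperiment}.
#' @param cellsByGroup named list of cell-id vectors.
#' @param epithelial,mesenchymal,stem non-empty gene-id vectors.
#' @return a data.frame: gene, panel, group, n, q1, median, q3.
#' @export
emtStemSummary <- function(x, cellsByGroup, epithelial, mesenchymal, stem) {
  if (!length(epithelial) || !length(mesenchymal) || !length(stem))
    stop("gene lists must be non-empty", call. = FALSE)
  genes <- c(epithelial, mesenchymal, stem)
  panel <- rep(c("epithelial", "mesenchymal", "stem"),
               c(length(epithelial), length(mesenchymal), length(stem)))
  gidx <- .matchGenes(genes, geneIds(x))
  out <- do.call(rbind, lapply(names(cellsByGroup), function(grp) {
    cidx <- .matchGenes(cellsByGroup[[grp]], cellIds(x), what = "cell")
    v <- log10(exprValues(x)[gidx, cidx, drop = FALSE] + 1)
    qs <- t(apply(v, 1L, quantile, probs = c(0.25, 0.5, 0.75), names = FALSE))
    data.frame(gene = genes, panel = panel, group = grp,
               n = length(cidx), q1 = qs[, 1L], median = qs[, 2L],
               q3 = qs[, 3L], row.names = NULL, stringsAsFactors = FALSE)
  }))
  out
}

#' Select highly CTC-enriched genes
#'
#' The stringent selection cascade: a gene qualifies iff its rank-product
#' score (in the up-in-target direction) is strictly below \code{rpMax}
#' AND it is expressed strictly above \code{rpmMin} in at least
#' \code{cellFractionMin} of the target cells (inclusive >=). Boundary
#' strictness follows the printed criteria exactly: RP < 300, > 100 rpm,
#' >= 90\% of cells.
#'
#' @param rpResults \link[S4Vectors]{DataFrame} from
#'   \code{\link{rankProduct}} (the \code{up_in_A} rows are used, A being
#'   the target group).
#' @param x an rpm \linkS4class{CTCExperiment}.
#' @param cells target cell ids (non-empty).
#' @param rpMax RP score bound (strict <), default 300.
#' @param rpmMin expression bound (strict >), default 100.
#' @param cellFractionMin required fraction of cells (inclusive >=),
#'   default 0.90.
#' @return character vector of qualifying gene ids (in gene order of the
#'   RP results).
#' @export
selectEnrichedGenes <- function(rpResults, x, cells, rpMax = 300,
                                rpmMin = 100, cellFractionMin = 0.90) {
  stopifnot(rpMax > 0, rpmMin >= 0,
            cellFractionMin > 0, cellFractionMin <= 1)
  if (!length(cells)) stop("target cell set is empty", call. = FALSE)
  cidx <- .matchGenes(cells, cellIds(x), what = "cell")
  res <- as.data.frame(rpResults)
  res <- res[res$direction == "up_in_A", , drop = FALSE]
  v <- exprValues(x)[, cidx, drop = FALSE]
  qual <- vapply(seq_len(nrow(res)), function(i) {
    g <- res$gene_id[i]
    res$rp[i] < rpMax &&
      mean(v[g, ] > rpmMin) >= cellFractionMin
  }, TRUE)
  res$gene_id[qual]
}

#' Screen candidate ECM genes for high expression across CTCs
#'
#' Returns the candidates expressed above \code{rpmMin} (strict >) in
#' more than \code{cellFractionMin} of the cells; the fraction comparison
#' is strict by default (the human screen's "> 15\% of all CTC samples"),
#' with \code{strictFraction = FALSE} giving the inclusive variant.
#' Candidates absent from the matrix are reported via the
#' \code{"missing_candidates"} attribute; if none are present this is an
#' error.
#'
#' @param x an rpm \linkS4class{CTCExperiment}.
#' @param candidates candidate gene ids.
#' @param rpmMin expression threshold (strict >).
#' @param cellFractionMin cell-fraction threshold.
#' @param strictFraction logical; strict (>) or inclusive (>=) fraction
#'   comparison.
#' @return character vector of passing gene ids.
#' @export
ecmScreen <- function(x, candidates, rpmMin = 100, cellFractionMin = 0.15,
                      strictFraction = TRUE) {
  present <- intersect(candidates, geneIds(x))
  if (!length(present))
    stop("no candidate genes present in the matrix", call. = FALSE)
  v <- exprValues(x)[present, , drop = FALSE]
  frac <- rowMeans(v > rpmMin)
  pass <- if (strictFraction) frac > cellFractionMin
          else frac >= cellFractionMin
  out <- present[pass]
  attr(out, "missing_candidates") <- setdiff(candidates, present)
  out
}

#' Count cells coexpressing two genes at high level
#'
#' @param x an rpm \linkS4class{CTCExperiment}.
#' @param geneA,geneB gene ids (must exist; if equal, the count equals the
#'   single-gene exceedance count).
#' @param rpmMin threshold (strict > for both genes).
#' @return a list with \code{count} and \code{fraction} (of all cells in
#'   \code{x}).
#' @export
coexpressionCount <- function(x, geneA, geneB, rpmMin = 100) {
  ia <- .matchGenes(geneA, geneIds(x))
  ib <- .matchGenes(geneB, geneIds(x))
  v <- exprValues(x)
  both <- (v[ia, ] > rpmMin) & (v[ib, ] > rpmMin)
  list(count = sum(both), fraction = mean(both))
}

#' Over-representation of gene sets in a gene list
#'
#' Generic 2x2 over-representation statistic on user-supplied gene sets:
#' for each set, the table (a = list-and-set, b = list-not-set,
#' c = set-not-list, d = neither) over the given universe, the odds ratio
#' \code{ad/bc} (with a Haldane 0.5 correction applied to all cells when
#' any cell is zero, so reported ORs stay finite without changing the
#' exact test), the one-sided exact hypergeometric tail p-value, and
#' Benjamini-Hochberg q-values across sets. Sets are intersected with the
#' universe; the gene list must be a subset of the universe.
#'
#' @param geneList character vector of selected genes.
#' @param sets a \linkS4class{GeneSetList}.
#' @param universe character vector of all tested genes (non-empty).
#' @return a data.frame: set, a, b, c, d, odds_ratio, p, q.
#' @export
overRepresentation <- function(geneList, sets, universe) {
  if (!length(universe)) stop("universe must not be empty", call. = FALSE)
  if (length(setdiff(geneList, universe)))
    stop("gene list must be a subset of the universe", call. = FALSE)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    a <- length(intersect(geneList, s))
    b <- length(geneList) - a
    cc <- length(s) - a
    d <- length(universe) - a - b - cc
    or <- if (a == 0 || b == 0 || cc == 0 || d == 0)
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
    else (a * d) / (b * cc)
    p <- phyper(a - 1, a + cc, b + d, a + b, lower.tail = FALSE)
    data.frame(set = nm, a = a, b = b, c = cc, d = d, odds_ratio = or,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out
}
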