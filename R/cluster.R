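#' Unsupervised hierarchical clustering of cells
#'
#' Clusters cells on 1 - Pearson correlation (default) over genes detected
#' (> 0) in at least \code{minCellsDetected} cells, with average linkage,
#' and cuts the tree at \code{k} clusters. Correlation distance with
#' average linkage is the standard expression-heat-map choice and matches
#' the correlation-based heterogeneity metric; \code{k} defaults to 7 in
#' the pipeline configuration (the number of labeled cohort groups), with
#' no automatic selection. Deterministic given input and parameters, and
#' invariant to cell-column permutation.
#'
#' @param x a polished or log_rpm \linkS4class{CTCExperiment}.
#' @param distance \code{"pearson"}, \code{"spearman"}, or
#'   \code{"euclidean"}.
#' @param linkage any \code{\link[stats]{hclust}} method.
#' @param k number of clusters (1 to n cells).
#' @param minCellsDetected detection filter for the gene subset used.
#' @return a \linkS4class{ClusterAssignment}.
#' @export
hierarchicalCluster <- function(x, distance = c("pearson", "spearman",
                                                "euclidean"),
                                linkage = "average", k = 7L,
                                minCellsDetected = 2L) {
  distance <- match.arg(distance)
  v <- exprValues(x)
  if (ncol(v) < 2L) stop("need at least 2 cells to cluster", call. = FALSE)
  if (k < 1L || k > ncol(v))
    stop("k must lie between 1 and the number of cells", call. = FALSE)
  if (exprUnit(x) %in% c("counts", "rpm") && distance != "euclidean")
    keep <- rowSums(v > 0) >= minCellsDetected
  else keep <- rowSums(abs(v) > 0) >= minCellsDetected
  vv <- v[keep, , drop = FALSE]
  if (distance %in% c("pearson", "spearman")) {
    sds <- apply(vv, 2L, sd)
    if (any(sds == 0))
      stop("constant expression in cell(s) under correlation distance: ",
           paste(head(colnames(vv)[sds == 0], 3L), collapse = ", "),
           call. = FALSE)
    cm <- cor(vv, method = distance)
    d <- as.dist(1 - cm)
  } else d <- dist(t(vv))
  tree <- hclust(d, method = linkage)
  labels <- cutree(tree, k = k)
  new("ClusterAssignment", labels = labels, tree = tree,
      distance = distance, linkage = linkage, k = as.integer(k))
}

#' Principal component analysis of cells
#'
#' Centered (unscaled) PCA of the cell profiles. Sign convention: each
#' component's gene-loading vector is flipped so its largest-magnitude
#' entry is positive, making projections reproducible across platforms.
#'
#' @param x a \linkS4class{CTCExperiment}.
#' @param nComponents number of components (at most min(genes, cells)).
#' @return a list with \code{coords} (cells x components),
#'   \code{variance_explained} (non-increasing fractions summing to at
#'   most 1) and \code{loadings}.
#' @export
pcaCells <- function(x, nComponents = 2L) {
  v <- exprValues(x)
  nComponents <- min(nComponents, nrow(v), ncol(v))
  pc <- prcomp(t(v), center = TRUE, scale. = FALSE)
  nComponents <- min(nComponents, ncol(pc$rotation))
  flip <- vapply(seq_len(nComponents), function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, 1)
  coords <- sweep(pc$x[, seq_len(nComponents), drop = FALSE], 2L, flip, "*")
  loadings <- sweep(pc$rotation[, seq_len(nComponents), drop = FALSE],
                    2L, flip, "*")
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(coords = coords,
       variance_explained = ve[seq_len(nComponents)],
       loadings = loadings)
}

.logRpmForCor <- function(x) {
  if (exprUnit(x) == "counts") x <- normalizeRpm(x)
  if (exprUnit(x) == "rpm") x <- logTransform(x)
  if (!exprUnit(x) %in% c("log_rpm", "polished"))
    stop("cannot derive log rpm from unit ", exprUnit(x), call. = FALSE)
  exprValues(x)
}

#' Intracluster correlation heterogeneity statistic
#'
#' The heterogeneity of a cell group is summarized by the mean pairwise
#' Pearson correlation over all unordered cell pairs, computed on
#' log10(rpm + 1) so the statistic does not depend on the clustering
#' display transform; lower values reflect higher heterogeneity. The
#' confidence interval is a percentile bootstrap over cells: cells are
#' resampled with replacement and the mean recomputed over pairs of
#' distinct resampled cells (pairs duplicating one original cell are
#' excluded, since their correlation is identically 1).
#'
#' @param x a \linkS4class{CTCExperiment} (counts, rpm or log_rpm).
#' @param cells cell ids of the group (>= 2).
#' @param nBoot bootstrap replicates (>= 100).
#' @param level confidence level.
#' @param seed integer seed.
#' @param cluster optional label recorded in the output.
#' @return a one-row data.frame: cluster, n_cells, r_mean, ci_low,
#'   ci_high, level, n_boot, seed.
#' @export
intraclusterCorrelation <- function(x, cells = cellIds(x), nBoot = 1000L,
                                    level = 0.95, seed = 1L,
                                    cluster = NA) {
  if (length(cells) < 2L) stop("need at least 2 cells", call. = FALSE)
  if (nBoot < 100L) stop("nBoot must be >= 100", call. = FALSE)
  cidx <- .matchGenes(cells, cellIds(x), what = "cell")
  v <- .logRpmForCor(x)[, cidx, drop = FALSE]
  sds <- apply(v, 2L, sd)
  if (any(sds == 0)) {
    warning("constant cell(s) excluded from correlation pairs: ",
            paste(head(cells[sds == 0], 3L), collapse = ", "))
    v <- v[, sds > 0, drop = FALSE]
    if (ncol(v) < 2L)
      stop("all correlation pairs excluded", call. = FALSE)
  }
  cm <- cor(v)
  ut <- upper.tri(cm)
  rMean <- mean(cm[ut])
  n <- ncol(v)
  set.seed(substreamSeed(seed, "icc_boot"))
  boots <- vapply(seq_len(nBoot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    sub <- cm[idx, idx]
    keep <- upper.tri(sub) & outer(idx, idx, "!=")
    if (!any(keep)) return(NA_real_)
    mean(sub[keep])
  }, 1)
  ci <- quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                 na.rm = TRUE, names = FALSE)
  data.frame(cluster = cluster, n_cells = n, r_mean = rMean,
             ci_low = min(ci[1L], rMean), ci_high = max(ci[2L], rMean),
             level = level, n_boot = nBoot, seed = seed)
}

#' Permutation comparison of two groups' intracluster correlation
#'
#' Two-sided permutation test for the difference in mean pairwise
#' correlation between two disjoint cell groups, obtained by shuffling
#' group labels; the attainable p-value is bounded below by
#' 1/(nPerm + 1).
#'
#' @param x a \linkS4class{CTCExperiment}.
#' @param cellsA,cellsB disjoint cell-id vectors (each >= 2).
#' @param nPerm number of permutations.
#' @param seed integer seed.
#' @return a list with \code{statistic} (observed difference in r),
#'   \code{p_value} and \code{n_perm}.
#' @export
compareHeterogeneity <- function(x, cellsA, cellsB, nPerm = 999L, seed = 1L) {
  if (length(intersect(cellsA, cellsB)))
    stop("groups must not overlap", call. = FALSE)
  if (length(cellsA) < 2L || length(cellsB) < 2L)
    stop("both groups need >= 2 cells", call. = FALSE)
  all <- c(cellsA, cellsB)
  cidx <- .matchGenes(all, cellIds(x), what = "cell")
  v <- .logRpmForCor(x)[, cidx, drop = FALSE]
  cm <- cor(v)
  nA <- length(cellsA)
  meanR <- function(idx) {
    sub <- cm[idx, idx, drop = FALSE]
    mean(sub[upper.tri(sub)])
  }
  obs <- meanR(seq_len(nA)) - meanR(nA + seq_along(cellsB))
  set.seed(substreamSeed(seed, "het_perm"))
  nTot <- length(all)
  nullDiff <- vapply(seq_len(nPerm), function(p) {
    sh <- sample.int(nTot)
    meanR(sh[seq_len(nA)]) - meanR(sh[-seq_len(nA)])
  }, 1)
  p <- (1 + sum(abs(nullDiff) >= abs(obs))) / (nPerm + 1)
  list(statistic = obs, p_value = p, n_perm = nPerm)
}

#' Digital removal of a transcript set
#'
#' Drops the intersection of \code{genes} with the matrix genes (absent
#' genes are ignored with a warning); counts elsewhere are unchanged. For
#' rpm matrices the remaining columns are re-normalized to 10^6 and the
#' re-normalization is recorded in the metadata.
#'
#' @param x a \linkS4class{CTCExperiment}.
#' @param genes gene ids to remove (e.g. annotated platelet transcripts).
#' @return a \linkS4class{CTCExperiment} without those genes.
#' @export
removeTranscripts <- function(x, genes) {
  present <- intersect(genes, geneIds(x))
  absent <- setdiff(genes, geneIds(x))
  if (length(absent))
    warning("ignoring ", length(absent), " gene(s) absent from the matrix")
  if (!length(present)) return(x)
  keep <- setdiff(geneIds(x), present)
  if (!length(keep))
    stop("removal would leave zero genes", call. = FALSE)
  out <- CTCExperiment(exprValues(x)[keep, , drop = FALSE],
                       unit = if (exprUnit(x) == "rpm") "counts"
                              else exprUnit(x),
                       cellMeta = as.data.frame(cellData(x)))
  if (exprUnit(x) == "rpm") {
    out <- normalizeRpm(out)
    S4Vectors::metadata(out)$renormalized_after_removal <- TRUE
  }
  out
}
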