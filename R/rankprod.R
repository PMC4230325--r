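#' Rank-product differential expression between two cell groups
#'
#' A nonparametric two-group statistic robust to variation in absolute
#' transcript levels and uneven transcriptome representation from cell to
#' cell. For every between-group cell pair (a, b) the pseudocount-
#' stabilized fold change \code{(rpm_a + pc) / (rpm_b + pc)} of each gene
#' is ranked across genes (rank 1 = most extreme, average ranks on ties),
#' and a gene's RP score is the geometric mean of its ranks over pairs:
#' consistently extreme genes get RP near 1 regardless of their absolute
#' abundance. One-sided RP is computed separately per direction, as in the
#' original rank-product formulation. Two single-cell adaptations are
#' applied: genes detected (> 0 rpm) in less than \code{minDetectFraction}
#' of the cells of both groups are excluded (and reported via the
#' \code{"filtered_genes"} attribute), and for large groups the cell pairs
#' are subsampled to \code{maxPairs} (seeded, unbiased).
#'
#' @param x an rpm \linkS4class{CTCExperiment}.
#' @param groupA,groupB disjoint cell-id vectors, each with >= 2 cells.
#' @param minDetectFraction detection filter (fraction of cells, in at
#'   least one group).
#' @param pseudocount rpm pseudocount stabilizing the ratios.
#' @param maxPairs cap on the number of A x B pairs used.
#' @param seed integer seed (used only if pairs are subsampled).
#' @return a \link[S4Vectors]{DataFrame} with one row per retained gene
#'   and direction (\code{up_in_A} / \code{up_in_B}): gene_id, direction,
#'   rp, n_pairs; attribute \code{"filtered_genes"} lists excluded genes.
#' @export
rankProduct <- function(x, groupA, groupB, minDetectFraction = 0.2,
                        pseudocount = 1, maxPairs = 10000L, seed = 1L) {
  if (exprUnit(x) != "rpm") stop("rankProduct expects rpm", call. = FALSE)
  if (length(intersect(groupA, groupB)))
    stop("groups must be disjoint", call. = FALSE)
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs >= 2 cells", call. = FALSE)
  ia <- .matchGenes(groupA, cellIds(x), what = "cell")
  ib <- .matchGenes(groupB, cellIds(x), what = "cell")
  v <- exprValues(x)
  detA <- rowMeans(v[, ia, drop = FALSE] > 0)
  detB <- rowMeans(v[, ib, drop = FALSE] > 0)
  keep <- detA >= minDetectFraction | detB >= minDetectFraction
  if (!any(keep)) stop("all genes failed the detection filter", call. = FALSE)
  filtered <- rownames(v)[!keep]
  vv <- log(v[keep, , drop = FALSE] + pseudocount)

  pairs <- expand.grid(a = ia, b = ib, KEEP.OUT.ATTRS = FALSE)
  if (nrow(pairs) > maxPairs) {
    set.seed(substreamSeed(seed, "rp_pairs"))
    pairs <- pairs[sample.int(nrow(pairs), maxPairs), , drop = FALSE]
  }
  rp <- .rpScores(vv, pairs$a, pairs$b)
  out <- S4Vectors::DataFrame(
    gene_id = rep(rownames(vv), 2L),
    direction = rep(c("up_in_A", "up_in_B"), each = nrow(vv)),
    rp = c(rp$up, rp$down),
    n_pairs = nrow(pairs))
  attr(out, "filtered_genes") <- filtered
  attr(out, "groups") <- list(A = groupA, B = groupB)
  attr(out, "params") <- list(min_detect_fraction = minDetectFraction,
                              pseudocount = pseudocount,
                              max_pairs = maxPairs, seed = seed)
  out
}

# geometric-mean ranks over the given cell pairs of a log-expression
# matrix; rank 1 = largest log ratio (up direction) resp. smallest (down)
.rpScores <- function(logv, ia, ib) {
  G <- nrow(logv)
  sumUp <- numeric(G); sumDn <- numeric(G)
  for (p in seq_along(ia)) {
    ratio <- logv[, ia[p]] - logv[, ib[p]]
    rUp <- rank(-ratio, ties.method = "average")
    sumUp <- sumUp + log(rUp)
    sumDn <- sumDn + log(G + 1 - rUp)
  }
  # average tied ranks satisfy rank_down = G + 1 - rank_up exactly
  list(up = exp(sumUp / length(ia)), down = exp(sumDn / length(ia)))
}

#' Permutation significance and FDR for rank-product results
#'
#' Builds the null RP distribution by permuting the cell group labels
#' \code{nPerm} times and recomputing all gene RPs. For each observed RP:
#' \code{p = (1 + #\{null RP <= observed\}) / (1 + nPerm * G)} (so the
#' attainable floor is \code{1/(1 + nPerm * G)}), the expected number of
#' false positives is \code{E = #\{null RP <= observed\} / nPerm}, and the
#' q-value (pFDR) is \code{E} divided by the gene's rank position within
#' its direction, enforced monotone non-decreasing in RP rank and capped
#' at 1.
#'
#' @param results the \link[S4Vectors]{DataFrame} from
#'   \code{\link{rankProduct}}.
#' @param x the same rpm \linkS4class{CTCExperiment}.
#' @param nPerm number of label permutations (>= 100).
#' @param seed integer seed.
#' @return \code{results} with columns \code{p}, \code{E}, \code{q}
#'   appended.
#' @export
rpSignificance <- function(results, x, nPerm = 200L, seed = 1L) {
  if (nPerm < 100L) stop("nPerm must be >= 100", call. = FALSE)
  groups <- attr(results, "groups")
  prm <- attr(results, "params")
  if (is.null(groups)) stop("results lack group attributes", call. = FALSE)
  nA <- length(groups$A); nB <- length(groups$B)
  if (choose(nA + nB, nA) < 2)
    stop("groups too small for any distinct permutation", call. = FALSE)
  pool <- c(groups$A, groups$B)
  ipool <- .matchGenes(pool, cellIds(x), what = "cell")
  v <- exprValues(x)
  genes <- unique(results$gene_id)
  vv <- log(v[genes, , drop = FALSE] + prm$pseudocount)
  G <- length(genes)

  set.seed(substreamSeed(seed, "rp_null"))
  nullRp <- vector("list", nPerm)
  for (b in seq_len(nPerm)) {
    sh <- sample(ipool)
    ia <- sh[seq_len(nA)]; ib <- sh[nA + seq_len(nB)]
    pairs <- expand.grid(a = ia, b = ib, KEEP.OUT.ATTRS = FALSE)
    if (nrow(pairs) > prm$max_pairs)
      pairs <- pairs[sample.int(nrow(pairs), prm$max_pairs), , drop = FALSE]
    nullRp[[b]] <- .rpScores(vv, pairs$a, pairs$b)$up
  }
  nullAll <- sort(unlist(nullRp))

  res <- as.data.frame(results)
  res$p <- NA_real_; res$E <- NA_real_; res$q <- NA_real_
  for (dir in c("up_in_A", "up_in_B")) {
    sel <- which(res$direction == dir)
    obs <- res$rp[sel]
    cnt <- findInterval(obs, nullAll)          # null RP <= observed
    res$p[sel] <- (1 + cnt) / (1 + nPerm * G)
    res$E[sel] <- cnt / nPerm
    pos <- rank(obs, ties.method = "max")      # rank position by RP
    q <- res$E[sel] / pos
    ord <- order(obs)
    q[ord] <- pmin(cummax(q[ord]), 1)          # monotone step-up
    res$q[sel] <- q
  }
  out <- S4Vectors::DataFrame(res)
  for (a in c("filtered_genes", "groups", "params"))
    attr(out, a) <- attr(results, a)
  attr(out, "n_perm") <- nPerm
  out
}

#' Summarize differential expression calls
#'
#' Counts and lists the genes called at \code{qMax} in each direction.
#' Each gene is counted once, in its better (smaller-RP) direction; lists
#' are sorted by q then RP.
#'
#' @param results a \link[S4Vectors]{DataFrame} from
#'   \code{\link{rpSignificance}}.
#' @param qMax q-value cutoff (inclusive).
#' @return a list with \code{n_up_A}, \code{n_up_B}, \code{up_A},
#'   \code{up_B} (character vectors of gene ids).
#' @export
deSummary <- function(results, qMax = 0.01) {
  res <- as.data.frame(results)
  if (!"q" %in% colnames(res))
    stop("results are not populated; run rpSignificance first", call. = FALSE)
  # better direction per gene
  sp <- split(res, res$gene_id)
  best <- do.call(rbind, lapply(sp, function(d) d[which.min(d$rp)[1L], ]))
  hit <- best[best$q <= qMax, , drop = FALSE]
  hit <- hit[order(hit$q, hit$rp), , drop = FALSE]
  upA <- hit$gene_id[hit$direction == "up_in_A"]
  upB <- hit$gene_id[hit$direction == "up_in_B"]
  list(n_up_A = length(upA), n_up_B = length(upB),
       up_A = upA, up_B = upB)
}
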