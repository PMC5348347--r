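# Expression analysis of paired cohorts: filtering, the SAM two-class
# paired permutation statistic with q-values, per-pair fold-change rules,
# unsupervised clustering/MDS and a gene-set over-representation test.

#' Remove genes with low expression across samples
#'
#' Retains genes whose value exceeds `floor` in at least `min_samples`
#' samples. Defaults: `floor` is the 25th percentile of all values in the
#' matrix and `min_samples` a quarter of the samples.
#'
#' @param x genes x samples log2 matrix.
#' @param floor expression floor (same scale as the data).
#' @param min_samples minimum samples above the floor.
#' @return filtered matrix.
#' @export
low_expression_filter <- function(x, floor = NULL, min_samples = NULL) {
  if (is.null(floor)) floor <- stats::quantile(x, 0.25)
  if (is.null(min_samples)) min_samples <- ceiling(ncol(x) / 4)
  keep <- rowSums(x > floor) >= min_samples
  if (!any(keep)) warning("low_expression_filter: no genes retained")
  x[keep, , drop = FALSE]
}

#' Remove the least-variable genes
#'
#' Drops the `drop_fraction` of genes with the lowest variance across
#' samples; ties are broken by gene id so the result is deterministic.
#'
#' @param x genes x samples matrix.
#' @param drop_fraction fraction of genes removed (default 0.5).
#' @return filtered matrix.
#' @export
variance_filter <- function(x, drop_fraction = 0.5) {
  stopifnot(drop_fraction >= 0, drop_fraction < 1)
  if (drop_fraction == 0) return(x)
  v <- apply(x, 1, stats::var)
  ord <- order(v, rownames(x))
  n_drop <- floor(drop_fraction * nrow(x))
  if (n_drop == 0L) return(x)
  x[sort(ord[-seq_len(n_drop)]), , drop = FALSE]
}

# sign-flip matrix: all 2^n when n <= exhaustive_max, else random
.sign_flips <- function(n, n_permutations, seed, exhaustive_max = 10L) {
  if (n <= exhaustive_max) {
    as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    set.seed(seed)
    matrix(sample(c(-1, 1), n * n_permutations, replace = TRUE), ncol = n)
  }
}

#' SAM two-class paired statistic with permutation q-values
#'
#' Per gene, the paired differences `z_i = relapse_i - diagnosis_i` give
#' `zbar = mean(z)` and standard error `s = sd(z)/sqrt(n)`; the statistic
#' is `d = zbar / (s + s0)` with the fudge factor `s0` chosen from the
#' percentile grid \{0, 5, ..., 100\} of `s` as the value minimizing the
#' coefficient of variation of the median |d| across `s`-quantile bins
#' (Tusher-style). The null distribution of `d` comes from sign-flip
#' permutations of the pair labels (all `2^n` flips when `n <= 10`). The
#' q-value of gene g is the median over permutations of the number of
#' null |d| at or above |d_g|, divided by the observed count at or above
#' |d_g|, clipped to [0, 1] and monotonized in |d| rank. No pi0
#' estimation is applied (conservative).
#'
#' @param x genes x samples matrix (log2 scale).
#' @param design a [cohort_design()] (uses `design$pairs`), or a
#'   data.frame with `diagnosis` and `relapse` columns of sample names.
#' @param n_permutations random sign flips when n_pairs > 10
#'   (default 1000).
#' @param seed RNG seed for the random flips.
#' @return data.frame (one row per gene): `gene`, `mean_diff`, `se`, `d`,
#'   `fc_log2`, `fc_ratio`, `q`; the chosen `s0` is attached as an
#'   attribute.
#' @export
sam_paired <- function(x, design, n_permutations = 1000L, seed = 1L) {
  pairs <- if (is.data.frame(design)) design else design$pairs
  n <- nrow(pairs)
  if (n < 3L) stop("sam_paired: need at least 3 pairs")
  if (!all(c(pairs$diagnosis, pairs$relapse) %in% colnames(x))) {
    stop("sam_paired: paired columns missing from the matrix")
  }
  D <- x[, pairs$relapse, drop = FALSE] - x[, pairs$diagnosis, drop = FALSE]
  G <- nrow(D)
  zbar <- rowMeans(D)
  ss <- rowSums(D^2)
  s <- sqrt(pmax(ss - n * zbar^2, 0) / (n - 1)) / sqrt(n)

  s0 <- .sam_fudge(zbar, s)
  d <- zbar / (s + s0)

  flips <- .sign_flips(n, n_permutations, seed)
  P <- nrow(flips)
  Znull <- (D %*% t(flips)) / n                       # G x P
  Snull <- sqrt(pmax(ss - n * Znull^2, 0) / (n - 1)) / sqrt(n)
  Dnull <- Znull / (Snull + s0)

  abs_d <- abs(d)
  ord <- order(-abs_d)
  sorted_abs <- abs_d[ord]
  obs_count <- seq_len(G)                # #{|d| >= |d_(k)|} in sorted order
  counts <- matrix(0L, nrow = G, ncol = P)
  eps <- 1e-12
  for (p in seq_len(P)) {
    nc <- sort(abs(Dnull[, p]))
    # #{null >= t} for each sorted observed threshold t
    counts[, p] <- length(nc) - findInterval(sorted_abs - eps, nc)
  }
  med_null <- apply(counts, 1, stats::median)
  q_sorted <- pmin(med_null / obs_count, 1)
  q_sorted <- rev(cummin(rev(q_sorted)))   # monotone in |d| rank
  q <- numeric(G)
  q[ord] <- q_sorted

  res <- data.frame(
    gene = if (!is.null(rownames(x))) rownames(x) else as.character(seq_len(G)),
    mean_diff = zbar, se = s, d = d, fc_log2 = zbar, fc_ratio = 2^zbar,
    q = q, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "s0") <- s0
  res
}

# Tusher-style fudge factor: candidate s0 from the percentile grid of s,
# minimizing the CV of median |d| across s-quantile bins
.sam_fudge <- function(zbar, s) {
  G <- length(s)
  cand <- unique(stats::quantile(s, probs = seq(0, 1, by = 0.05),
                                 names = FALSE))
  # keep d finite when some genes have zero spread
  if (min(s) == 0) cand <- cand[cand > 0]
  if (length(cand) == 0L) return(1)  # fully degenerate matrix: d = zbar
  nbins <- max(3L, min(100L, floor(G / 10)))
  bin <- cut(rank(s, ties.method = "first"), breaks = nbins, labels = FALSE)
  cv <- vapply(cand, function(s0c) {
    dd <- abs(zbar / (s + s0c))
    v <- tapply(dd, bin, stats::median)
    m <- mean(v)
    if (!is.finite(m) || m == 0) return(Inf)
    stats::sd(v) / m
  }, numeric(1))
  if (all(!is.finite(cv))) return(cand[1])
  cand[which.min(cv)]
}

#' Per-pair fold changes
#'
#' Log2 relapse - diagnosis differences for every gene and pair. A ratio
#' fold change of t corresponds to |log2 difference| >= log2(t).
#'
#' @param x genes x samples log2 matrix.
#' @param design a [cohort_design()] or pairs data.frame.
#' @return genes x pairs matrix of log2 fold changes (columns named by
#'   pair id).
#' @export
fold_changes <- function(x, design) {
  pairs <- if (is.data.frame(design)) design else design$pairs
  if (!all(c(pairs$diagnosis, pairs$relapse) %in% colnames(x))) {
    stop("fold_changes: paired columns missing")
  }
  fc <- x[, pairs$relapse, drop = FALSE] - x[, pairs$diagnosis, drop = FALSE]
  colnames(fc) <- pairs$pair_id
  fc
}

#' Genes with concordant fold changes across pairs
#'
#' A gene is "up" when at least `min_pairs` pairs show a ratio fold change
#' of at least `min_ratio_fc` upward; "down" analogously. Genes meeting
#' both rules land in both lists and are flagged.
#'
#' @param fc genes x pairs log2 fold-change matrix ([fold_changes()]).
#' @param min_ratio_fc ratio-scale threshold (default 2, i.e. |log2 FC|
#'   >= 1).
#' @param min_pairs minimum supporting pairs (default 5).
#' @return list with `up`, `down`, `both` character vectors.
#' @export
concordance_filter <- function(fc, min_ratio_fc = 2, min_pairs = 5L) {
  stopifnot(min_ratio_fc > 0, min_pairs >= 1L)
  t <- log2(min_ratio_fc)
  up <- rownames(fc)[rowSums(fc >= t) >= min_pairs]
  down <- rownames(fc)[rowSums(fc <= -t) >= min_pairs]
  list(up = up, down = down, both = intersect(up, down))
}

#' Candidate genes for correlation screens
#'
#' Genes whose expression changes at least `min_ratio_fc`-fold (either
#' direction) in at least `min_pairs` pairs.
#'
#' @param fc genes x pairs log2 fold-change matrix.
#' @param min_ratio_fc ratio threshold (2 for the CNA screen, 1.5 for the
#'   methylation screen).
#' @param min_pairs minimum pairs (default 3).
#' @return character vector of gene ids.
#' @export
select_candidates <- function(fc, min_ratio_fc = 2, min_pairs = 3L) {
  stopifnot(min_ratio_fc > 1)
  t <- log2(min_ratio_fc)
  rownames(fc)[rowSums(abs(fc) >= t) >= min_pairs]
}

#' UPGMA hierarchical clustering of samples
#'
#' Euclidean distances between sample columns, group-average (UPGMA)
#' linkage; optional flat clusters at a height or count cutoff.
#'
#' @param x genes x samples matrix.
#' @param h optional height cutoff for flat clusters.
#' @param k optional number of flat clusters.
#' @return list with `hclust` (the merge tree) and `clusters` (named
#'   integer vector, NULL when neither `h` nor `k` given).
#' @export
hierarchical_cluster <- function(x, h = NULL, k = NULL) {
  if (ncol(x) < 2L) stop("need at least 2 samples")
  hc <- stats::hclust(stats::dist(t(x), method = "euclidean"),
                      method = "average")
  cl <- NULL
  if (!is.null(h) || !is.null(k)) cl <- stats::cutree(hc, k = k, h = h)
  list(hclust = hc, clusters = cl)
}

#' Classical multidimensional scaling to 2-D
#'
#' Classical (Torgerson) scaling on double-centered squared distances.
#' Accepts a data matrix (genes x samples; Euclidean distances between
#' columns), a `dist` object, or a symmetric distance matrix. Orientation
#' is fixed by making the first nonzero loading of each axis positive.
#'
#' @param x matrix or dist.
#' @param k output dimensions (default 2).
#' @return samples x k coordinate matrix.
#' @export
run_mds <- function(x, k = 2L) {
  if (inherits(x, "dist")) {
    d <- x
  } else if (is.matrix(x) && nrow(x) == ncol(x) && all(diag(x) == 0)) {
    if (!isSymmetric(unname(x))) stop("distance matrix must be symmetric")
    d <- stats::as.dist(x)
  } else {
    d <- stats::dist(t(x), method = "euclidean")
  }
  co <- stats::cmdscale(d, k = k)
  for (j in seq_len(ncol(co))) {
    nz <- which(abs(co[, j]) > 1e-12)
    if (length(nz) && co[nz[1], j] < 0) co[, j] <- -co[, j]
  }
  co
}

#' Gene-set over-representation analysis
#'
#' One-sided hypergeometric test of each set's overlap with the gene
#' list, against the supplied universe; Benjamini-Hochberg correction
#' across sets. Sets with no members in the universe are skipped.
#'
#' @param gene_list character vector (must be a subset of `universe`).
#' @param universe character vector of all testable genes.
#' @param gene_sets named list of character vectors.
#' @return data.frame: `set`, `set_size`, `overlap`, `p.value`,
#'   `p.adjust`.
#' @export
ora <- function(gene_list, universe, gene_sets) {
  if (!all(gene_list %in% universe)) {
    stop("ora: gene list must be a subset of the universe")
  }
  N <- length(universe)
  n <- length(gene_list)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    if (length(set) == 0L) return(NULL) # skipped: empty after intersection
    k <- length(intersect(set, gene_list))
    p <- stats::phyper(k - 1, length(set), N - length(set), n,
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(set), overlap = k, p.value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set = character(), set_size = integer(),
                      overlap = integer(), p.value = numeric(),
                      p.adjust = numeric()))
  }
  out$p.adjust <- stats::p.adjust(out$p.value, method = "BH")
  rownames(out) <- NULL
  out
}
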