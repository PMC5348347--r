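# Methylation-array workflows on probe-level values: quantile
# normalization, empirical-Bayes batch correction, peak counting,
# differentially methylated region (DMR) detection with sign-flip
# permutation p-values, and strand-aware promoter-window aggregation.

#' Quantile-normalize a probes-by-samples matrix
#'
#' Forces every column onto the common reference distribution (the
#' row-wise mean of the sorted columns), preserving within-column ranks;
#' ties are averaged. Delegates to [limma::normalizeQuantiles()].
#'
#' @param x numeric matrix, probes x samples.
#' @return matrix of the same dimensions.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) {
    warning("quantile_normalize: single sample, returning input unchanged")
    return(x)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Remove a batch effect from a probes-by-samples matrix
#'
#' Parametric empirical-Bayes location/scale adjustment (ComBat, via the
#' sva package): per-probe standardization, batch parameters shrunk toward
#' their batch means, data returned on the original scale. A per-batch
#' mean-centering fallback (`method = "center"`, grand mean preserved) is
#' available for cohorts too small for the EB fit.
#'
#' @param x numeric matrix, probes x samples.
#' @param batch vector of batch labels, one per column.
#' @param condition optional biological condition per column; a batch
#'   perfectly confounded with it triggers a warning (the correction would
#'   remove signal).
#' @param method "eb" (ComBat) or "center".
#' @return adjusted matrix.
#' @export
batch_correct <- function(x, batch, condition = NULL, method = c("eb", "center")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  stopifnot(length(batch) == ncol(x))
  batch <- as.character(batch)
  if (length(unique(batch)) < 2L) return(x)
  if (!is.null(condition)) {
    tab <- table(batch, as.character(condition))
    if (all(rowSums(tab > 0) == 1L)) {
      warning("batch is perfectly confounded with condition; ",
              "correction will remove biological signal")
    }
  }
  if (min(table(batch)) < 2L) method <- "center"
  if (method == "center") {
    grand <- rowMeans(x)
    out <- x
    for (b in unique(batch)) {
      idx <- batch == b
      out[, idx] <- x[, idx] - rowMeans(x[, idx, drop = FALSE]) + grand
    }
    return(out)
  }
  out <- suppressMessages(sva::ComBat(dat = x, batch = batch))
  dimnames(out) <- dimnames(x)
  out
}

#' Per-probe methylation peak scores
#'
#' Score for probe i in a sample: -log10 of the one-sided normal-
#' approximation rank-sum p-value comparing the probes within `width` bp
#' of i (inclusive window, same chromosome) against the sample's global
#' value distribution. High local values relative to the rest of the
#' sample give high scores; a cutoff of 2 corresponds to p < 0.01. This is
#' a documented stand-in for the scanner software's proprietary peak
#' score and is configurable throughout.
#'
#' @param probes data.frame (`chrom`, `pos`), sorted per chromosome.
#' @param values numeric vector of one sample's probe log2 ratios (same
#'   order as `probes`).
#' @param width window width in bp (default 750).
#' @return numeric vector of scores, one per probe.
#' @export
peak_scores <- function(probes, values, width = 750) {
  stopifnot(nrow(probes) == length(values), width > 0)
  n <- length(values)
  r <- rank(values)
  score <- numeric(n)
  half <- width / 2
  for (ch in unique(probes$chrom)) {
    idx <- which(probes$chrom == ch)
    pos <- probes$pos[idx]
    cr <- c(0, cumsum(r[idx]))
    lo <- findInterval(pos - half, pos, left.open = TRUE) + 1L
    hi <- findInterval(pos + half, pos)
    m <- hi - lo + 1L
    W <- cr[hi + 1L] - cr[lo]
    mu <- m * (n + 1) / 2
    sg <- sqrt(m * (n - m) * (n + 1) / 12)
    z <- ifelse(sg > 0, (W - mu) / sg, 0)
    p <- stats::pnorm(z, lower.tail = FALSE)
    score[idx] <- -log10(pmax(p, 1e-300))
  }
  score
}

#' Call methylation peaks in one sample
#'
#' A peak is a run of at least `min_probes` probes with score at or above
#' `score_cutoff` in which consecutive qualifying probes are within
#' `width` bp of each other.
#'
#' @param probes data.frame (`chrom`, `pos`).
#' @param values one sample's probe log2 ratios.
#' @param width peak width in bp (default 750).
#' @param min_probes minimum qualifying probes per peak (default 2).
#' @param score_cutoff minimum probe score (default 2).
#' @param scores optional precomputed probe scores (skips [peak_scores()]).
#' @return data.frame of peaks: `chrom`, `start`, `end`, `n_probes`,
#'   `max_score`.
#' @export
call_peaks <- function(probes, values, width = 750, min_probes = 2L,
                       score_cutoff = 2, scores = NULL) {
  stopifnot(min_probes >= 1L)
  if (is.null(scores)) scores <- peak_scores(probes, values, width = width)
  qual <- which(scores >= score_cutoff)
  if (length(qual) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_probes = integer(),
                      max_score = numeric()))
  }
  ch <- probes$chrom[qual]
  pos <- probes$pos[qual]
  new_run <- c(TRUE, ch[-1] != ch[-length(ch)] |
                 diff(pos) > width)
  run_id <- cumsum(new_run)
  out <- do.call(rbind, lapply(split(seq_along(qual), run_id), function(ii) {
    data.frame(chrom = ch[ii[1]], start = pos[ii[1]],
               end = pos[ii[length(ii)]] + 1, n_probes = length(ii),
               max_score = max(scores[qual[ii]]), stringsAsFactors = FALSE)
  }))
  out <- out[out$n_probes >= min_probes, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count peaks per sample (and optionally per chromosome)
#'
#' @param probes probe data.frame.
#' @param values probes x samples matrix.
#' @param by "sample" or "chromosome".
#' @param ... passed to [call_peaks()].
#' @return data.frame of counts.
#' @export
count_peaks <- function(probes, values, by = c("sample", "chromosome"), ...) {
  by <- match.arg(by)
  out <- lapply(colnames(values), function(s) {
    pk <- call_peaks(probes, values[, s], ...)
    if (by == "sample") {
      data.frame(sample = s, n_peaks = nrow(pk), stringsAsFactors = FALSE)
    } else {
      cnt <- table(factor(pk$chrom, levels = unique(probes$chrom)))
      data.frame(sample = s, chrom = names(cnt),
                 n_peaks = as.integer(cnt), stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Relapse/diagnosis ratio of peak counts
#'
#' Fold change of the number of methylated regions between the two
#' timepoints, per pair (or per chromosome when counts carry a `chrom`
#' column).
#'
#' @param counts data.frame from [count_peaks()].
#' @param design a [cohort_design()].
#' @return data.frame with per-pair (x per-chromosome) count ratios.
#' @export
peak_ratio <- function(counts, design) {
  p <- design$pairs
  per_chrom <- "chrom" %in% names(counts)
  out <- NULL
  for (k in seq_len(nrow(p))) {
    d <- counts[counts$sample == p$diagnosis[k], , drop = FALSE]
    r <- counts[counts$sample == p$relapse[k], , drop = FALSE]
    if (per_chrom) {
      m <- merge(d[, c("chrom", "n_peaks")], r[, c("chrom", "n_peaks")],
                 by = "chrom", suffixes = c("_d", "_r"))
      out <- rbind(out, data.frame(pair_id = p$pair_id[k], m,
                                   ratio = ifelse(m$n_peaks_d > 0,
                                                  m$n_peaks_r / m$n_peaks_d,
                                                  NA_real_)))
    } else {
      out <- rbind(out, data.frame(
        pair_id = p$pair_id[k], n_peaks_d = d$n_peaks, n_peaks_r = r$n_peaks,
        ratio = ifelse(d$n_peaks > 0, r$n_peaks / d$n_peaks, NA_real_)))
    }
  }
  rownames(out) <- NULL
  out
}

#' Detect differentially methylated regions between paired samples
#'
#' Per-probe mean paired difference (relapse - diagnosis, fraction scale)
#' is smoothed by a running mean over `smooth_window` probes, with runs
#' broken at inter-probe gaps larger than `max_gap`. Candidate DMRs are
#' maximal same-sign runs with |smoothed difference| above `delta_cutoff`;
#' run flanks whose raw |difference| does not itself exceed the cutoff are
#' trimmed so that region bounds are not blurred by the smoother. Regions
#' with fewer than `min_probes` probes are removed; each remaining region
#' gets a p-value from sign-flip permutations of the pair labels using the
#' area statistic (sum of smoothed differences over the region).
#'
#' @param values probes x samples fraction matrix.
#' @param probes probe data.frame (`chrom`, `pos`), sorted.
#' @param design a [cohort_design()] naming the paired columns.
#' @param smooth_window running-mean width in probes (default 3).
#' @param max_gap bp gap breaking smoothing runs (default 1000).
#' @param delta_cutoff fraction-scale cutoff (default 0.05, i.e. 5
#'   percentage points).
#' @param min_probes minimum probes per reported DMR (default 4).
#' @param p_cutoff report DMRs with permutation p below this (default
#'   0.05); set to 1 to keep all candidates.
#' @param n_permutations sign-flip permutations (all 2^n when n_pairs <=
#'   10, otherwise this many random flips; default 1000).
#' @param seed RNG seed for the random flips.
#' @return data.frame of DMRs: `chrom`, `start`, `end`, `n_probes`,
#'   `mean_delta`, `direction` ("hyper"/"hypo"), `p.value`.
#' @export
detect_dmrs <- function(values, probes, design, smooth_window = 3L,
                        max_gap = 1000, delta_cutoff = 0.05,
                        min_probes = 4L, p_cutoff = 0.05,
                        n_permutations = 1000L, seed = 1L) {
  p <- design$pairs
  if (!all(c(p$diagnosis, p$relapse) %in% colnames(values))) {
    stop("detect_dmrs: paired columns missing from the matrix")
  }
  n <- nrow(p)
  D <- values[, p$relapse, drop = FALSE] - values[, p$diagnosis, drop = FALSE]

  # smoothing runs: consecutive probes on one chromosome with gaps <= max_gap
  np <- nrow(probes)
  new_run <- c(TRUE, probes$chrom[-1] != probes$chrom[-np] |
                 diff(probes$pos) > max_gap)
  run_id <- cumsum(new_run)

  running_mean <- function(v, w) {
    if (length(v) < w || w <= 1L) return(v)
    cs <- c(0, cumsum(v))
    lo <- pmax(seq_along(v) - (w - 1L) %/% 2L, 1L)
    hi <- pmin(seq_along(v) + w %/% 2L, length(v))
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  SD <- D
  for (rid in unique(run_id)) {
    idx <- which(run_id == rid)
    for (j in seq_len(ncol(D))) {
      SD[idx, j] <- running_mean(D[idx, j], smooth_window)
    }
  }
  sm <- rowMeans(SD)
  raw <- rowMeans(D)

  # candidate regions: maximal same-sign runs above cutoff within a run
  cand_id <- integer(np)
  active <- abs(sm) > delta_cutoff
  sgn <- sign(sm)
  brk <- c(TRUE, run_id[-1] != run_id[-np] | sgn[-1] != sgn[-np])
  grp <- cumsum(brk)
  grp[!active] <- 0L

  # sign-flip null for the area statistic
  if (n <= 10L) {
    flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    set.seed(seed)
    flips <- matrix(sample(c(-1, 1), n * n_permutations, replace = TRUE),
                    ncol = n)
  }

  out <- NULL
  for (g in setdiff(unique(grp), 0L)) {
    idx <- which(grp == g)
    # trim flanks the smoother blurred past the true boundary
    while (length(idx) > 0L && abs(raw[idx[1]]) <= delta_cutoff) {
      idx <- idx[-1]
    }
    while (length(idx) > 0L && abs(raw[idx[length(idx)]]) <= delta_cutoff) {
      idx <- idx[-length(idx)]
    }
    if (length(idx) < min_probes) next
    area_obs <- sum(sm[idx])
    w <- colSums(SD[idx, , drop = FALSE]) / n
    area_null <- as.vector(flips %*% w)
    pv <- (1 + sum(abs(area_null) >= abs(area_obs) - 1e-12)) /
      (1 + nrow(flips))
    md <- mean(raw[idx])
    out <- rbind(out, data.frame(
      chrom = probes$chrom[idx[1]], start = probes$pos[idx[1]],
      end = probes$pos[idx[length(idx)]] + 1, n_probes = length(idx),
      mean_delta = md, direction = if (md > 0) "hyper" else "hypo",
      p.value = pv, stringsAsFactors = FALSE))
  }
  if (is.null(out)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_probes = integer(),
                      mean_delta = numeric(), direction = character(),
                      p.value = numeric()))
  }
  out <- out[out$p.value < p_cutoff & abs(out$mean_delta) > delta_cutoff, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign a genomic region to its nearest gene by TSS distance
#'
#' The gene whose TSS is closest to the region midpoint; ties broken by
#' the smaller TSS coordinate (then gene id) for determinism. Regions on
#' chromosomes without genes get NA.
#'
#' @param regions data.frame (`chrom`, `start`, `end`).
#' @param genes annotation (`gene`, `chrom`, `tss`).
#' @return character vector of gene ids (NA when unassignable).
#' @export
assign_region_to_gene <- function(regions, genes) {
  if (nrow(genes) == 0L) stop("empty gene annotation")
  mid <- (regions$start + regions$end) / 2
  vapply(seq_len(nrow(regions)), function(i) {
    g <- genes[genes$chrom == regions$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) return(NA_character_)
    dd <- abs(g$tss - mid[i])
    g <- g[order(dd, g$tss, g$gene), , drop = FALSE]
    g$gene[1]
  }, character(1))
}

#' Strand-aware promoter and core-promoter windows
#'
#' Promoter: 2000 bp upstream of the TSS (strand-aware; `[tss-2000, tss)`
#' on "+", `[tss, tss+2000)` on "-"). Core promoter: 250 bp either side of
#' the TSS. Windows are clipped at 0.
#'
#' @param genes annotation (`gene`, `chrom`, `strand`, `tss`).
#' @param upstream promoter depth in bp (default 2000).
#' @param core_halfwidth core half-width in bp (default 250).
#' @return list of two data.frames (`promoter`, `core`), each with
#'   `gene`, `chrom`, `start`, `end`.
#' @export
promoter_windows <- function(genes, upstream = 2000, core_halfwidth = 250) {
  plus <- genes$strand == "+"
  prom <- data.frame(
    gene = genes$gene, chrom = genes$chrom,
    start = pmax(0, ifelse(plus, genes$tss - upstream, genes$tss)),
    end = ifelse(plus, genes$tss, genes$tss + upstream),
    stringsAsFactors = FALSE)
  core <- data.frame(
    gene = genes$gene, chrom = genes$chrom,
    start = pmax(0, genes$tss - core_halfwidth),
    end = genes$tss + core_halfwidth,
    stringsAsFactors = FALSE)
  list(promoter = prom, core = core)
}

# aggregate probe values over per-gene windows; NA when no probe in window
.aggregate_probes <- function(values, probes, windows, fun = c("mean", "max")) {
  fun <- match.arg(fun)
  out <- matrix(NA_real_, nrow = nrow(windows), ncol = ncol(values),
                dimnames = list(windows$gene, colnames(values)))
  for (i in seq_len(nrow(windows))) {
    idx <- which(probes$chrom == windows$chrom[i] &
                   probes$pos >= windows$start[i] &
                   probes$pos < windows$end[i])
    if (length(idx) == 0L) next
    block <- values[idx, , drop = FALSE]
    out[i, ] <- if (fun == "mean") colMeans(block) else
      apply(block, 2, max)
  }
  out
}

#' Aggregate probe methylation over promoter windows
#'
#' Gene-level methylation per sample for the (promoter, core) x
#' (mean, max) combinations; genes without probes in a window get NA.
#'
#' @param values probes x samples matrix.
#' @param probes probe data.frame.
#' @param genes gene annotation (`gene`, `chrom`, `strand`, `tss`).
#' @param windows optional precomputed [promoter_windows()].
#' @return list of four genes x samples matrices: `promoter_mean`,
#'   `promoter_max`, `core_mean`, `core_max`.
#' @export
promoter_aggregate <- function(values, probes, genes, windows = NULL) {
  if (is.null(windows)) windows <- promoter_windows(genes)
  list(
    promoter_mean = .aggregate_probes(values, probes, windows$promoter, "mean"),
    promoter_max = .aggregate_probes(values, probes, windows$promoter, "max"),
    core_mean = .aggregate_probes(values, probes, windows$core, "mean"),
    core_max = .aggregate_probes(values, probes, windows$core, "max"))
}

#' Paired differential methylation at gene level
#'
#' Applies the low-variance filter (drop the least-variable half) and the
#' SAM two-class paired statistic to gene-level aggregated methylation.
#' Genes with any missing aggregate are excluded.
#'
#' @param gene_values genes x samples matrix (one aggregation of
#'   [promoter_aggregate()]).
#' @param design a [cohort_design()].
#' @param drop_fraction fraction of low-variance genes removed first
#'   (default 0.5).
#' @param ... passed to [sam_paired()].
#' @return a SAM result data.frame (see [sam_paired()]).
#' @export
promoter_differential <- function(gene_values, design, drop_fraction = 0.5,
                                  ...) {
  keep <- stats::complete.cases(gene_values)
  x <- gene_values[keep, , drop = FALSE]
  x <- variance_filter(x, drop_fraction = drop_fraction)
  sam_paired(x, design, ...)
}
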