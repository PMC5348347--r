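# Copy-number analysis of paired probe-level log2-ratio profiles:
# winsorization, exact penalized least-squares segmentation, CNA calling
# under marker/length/CNV-mask filters, paired lesion evolution, genomic
# burden classification and group count statistics.

#' Winsorize probe log2 ratios
#'
#' Clips outlying probe values to `median +/- k * MAD` (MAD scaled by the
#' usual 1.4826 consistency constant). Applied per chromosome when `chrom`
#' is supplied. When the MAD is zero (constant-majority vector) the values
#' are returned unchanged: there is no robust scale to clip against.
#'
#' @param values numeric vector of probe log2 ratios.
#' @param k multiple of the MAD defining the clipping range (default 2.5).
#' @param chrom optional factor/character of the same length; clipping is
#'   done within each chromosome.
#' @return numeric vector of the same length.
#' @export
winsorize <- function(values, k = 2.5, chrom = NULL) {
  if (length(values) == 0L) stop("winsorize: empty input vector")
  if (!is.null(chrom)) {
    stopifnot(length(chrom) == length(values))
    out <- values
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      out[idx] <- winsorize(values[idx], k = k)
    }
    return(out)
  }
  m <- stats::median(values)
  s <- stats::mad(values)     # 1.4826 * median(|x - median|)
  if (s == 0) return(values)  # no-op: degenerate scale
  pmin(pmax(values, m - k * s), m + k * s)
}

#' Segment a probe profile by exact penalized least squares
#'
#' Finds the piecewise-constant fit minimizing
#' \deqn{\sum_i (x_i - \mu_{seg(i)})^2 + \lambda \cdot \#breakpoints}
#' by O(n^2) dynamic programming; the solution is the exact global
#' minimizer, with segment means equal to the arithmetic means of member
#' probes. Segment bounds span from the first member probe to one past the
#' last member probe (0-based half-open).
#'
#' @param pos integer/numeric vector of probe positions (one chromosome),
#'   strictly increasing.
#' @param value numeric vector of probe log2 ratios.
#' @param penalty non-negative breakpoint penalty \eqn{\lambda}.
#' @param chrom chromosome name stamped on the output (default "chr").
#' @return data.frame with columns `chrom`, `start`, `end`, `mean_log2`,
#'   `n_markers`.
#' @export
segment_profile <- function(pos, value, penalty = 1, chrom = "chr") {
  n <- length(pos)
  stopifnot(length(value) == n, penalty >= 0)
  if (n == 0L) stop("segment_profile: empty profile")
  if (is.unsorted(pos, strictly = TRUE)) {
    stop("segment_profile: probe positions must be strictly increasing")
  }
  # cost(i..j) = SS of residuals around the mean, via cumulative sums
  cs <- c(0, cumsum(value))
  cs2 <- c(0, cumsum(value^2))
  # F[j+1] = min cost of fitting probes 1..j (penalty per breakpoint, i.e.
  # per additional segment beyond the first); inner minimization vectorized
  F <- c(0, rep(NA_real_, n))
  back <- integer(n)
  pen <- c(0, rep(penalty, n)) # no penalty for the first segment
  for (j in seq_len(n)) {
    i <- seq_len(j)
    s <- cs[j + 1L] - cs[i]
    s2 <- cs2[j + 1L] - cs2[i]
    cost <- F[i] + (s2 - s^2 / (j - i + 1L)) + pen[i]
    bi <- which.min(cost)
    F[j + 1L] <- cost[bi]
    back[j] <- bi
  }
  # traceback
  bounds <- list()
  j <- n
  while (j >= 1L) {
    i <- back[j]
    bounds[[length(bounds) + 1L]] <- c(i, j)
    j <- i - 1L
  }
  bounds <- rev(bounds)
  segs <- do.call(rbind, lapply(bounds, function(b) {
    i <- b[1]; j <- b[2]
    data.frame(
      chrom = chrom,
      start = pos[i],
      end = pos[j] + 1,
      mean_log2 = (cs[j + 1L] - cs[i]) / (j - i + 1L),
      n_markers = j - i + 1L,
      stringsAsFactors = FALSE
    )
  }))
  rownames(segs) <- NULL
  segs
}

#' Segment a whole-genome probe table
#'
#' Convenience wrapper running [segment_profile()] per chromosome.
#'
#' @param probes data.frame with columns `chrom`, `pos`, `value`.
#' @param penalty breakpoint penalty passed through.
#' @return data.frame of segments across all chromosomes.
#' @export
segment_genome <- function(probes, penalty = 1) {
  stopifnot(all(c("chrom", "pos", "value") %in% names(probes)))
  out <- lapply(split(probes, probes$chrom), function(p) {
    p <- p[order(p$pos), , drop = FALSE]
    segment_profile(p$pos, p$value, penalty = penalty, chrom = p$chrom[1])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Default CNA-calling parameters
#'
#' Thresholds used to report a segment as a copy-number aberration: log2
#' ratio beyond +0.1 (gain) or -0.1 (loss), at least 25 markers, at least
#' 100 kb, and less than 50% overlap with known copy-number variants.
#'
#' @param gain_thresh,loss_thresh log2-ratio call thresholds.
#' @param min_markers minimum probes per reported segment.
#' @param min_length minimum genomic size in bp.
#' @param max_cnv_overlap maximum tolerated overlap fraction with the CNV
#'   mask (segments at or above this fraction are dropped).
#' @return named list of parameters.
#' @export
cna_call_params <- function(gain_thresh = 0.1, loss_thresh = -0.1,
                            min_markers = 25L, min_length = 1e5,
                            max_cnv_overlap = 0.5) {
  stopifnot(loss_thresh < 0, gain_thresh > 0, min_length > 0)
  list(gain_thresh = gain_thresh, loss_thresh = loss_thresh,
       min_markers = as.integer(min_markers), min_length = min_length,
       max_cnv_overlap = max_cnv_overlap)
}

#' Call copy-number aberrations from segments
#'
#' Keeps segments whose mean log2 ratio exceeds the gain threshold or falls
#' below the loss threshold, with at least `min_markers` probes, at least
#' `min_length` bp, and whose overlap fraction with the known-CNV mask is
#' below `max_cnv_overlap`.
#'
#' @param segments data.frame as returned by [segment_profile()].
#' @param params list from [cna_call_params()].
#' @param cnv_mask optional data.frame of known-CNV intervals
#'   (`chrom`, `start`, `end`).
#' @return data.frame of calls: segment columns plus `state`
#'   ("gain"/"loss") and `cnv_overlap_fraction`.
#' @export
call_cnas <- function(segments, params = cna_call_params(), cnv_mask = NULL) {
  if (is.null(segments) || nrow(segments) == 0L) {
    return(cbind(segments, state = character(0),
                 cnv_overlap_fraction = numeric(0)))
  }
  state <- ifelse(segments$mean_log2 > params$gain_thresh, "gain",
                  ifelse(segments$mean_log2 < params$loss_thresh, "loss", NA))
  len <- segments$end - segments$start
  ovl <- rep(0, nrow(segments))
  if (!is.null(cnv_mask) && nrow(cnv_mask) > 0L) {
    for (i in seq_len(nrow(segments))) {
      seg_i <- segments[i, c("chrom", "start", "end")]
      ovl[i] <- interval_overlap_bp(seg_i, cnv_mask) / len[i]
    }
  }
  keep <- !is.na(state) &
    segments$n_markers >= params$min_markers &
    len >= params$min_length &
    ovl < params$max_cnv_overlap
  out <- segments[keep, , drop = FALSE]
  out$state <- state[keep]
  out$cnv_overlap_fraction <- ovl[keep]
  rownames(out) <- NULL
  out
}

#' Summarize a sample's CNA calls into a burden profile
#'
#' Computes the total gained, lost and changed genomic lengths (changed =
#' union of all call intervals, overlaps counted once) and classifies the
#' sample as carrying "small" or "large" DNA changes at a total-length
#' cutoff (default 100 Mb).
#'
#' @param calls data.frame of CNA calls (from [call_cnas()]).
#' @param sample_id sample label.
#' @param cutoff burden cutoff in bp (default 1e8); "large" means
#'   changed bp strictly greater than the cutoff.
#' @return list with `sample_id`, `calls`, `gained_bp`, `lost_bp`,
#'   `changed_bp`, `burden_class`.
#' @export
cna_profile <- function(calls, sample_id = "sample", cutoff = 1e8) {
  gained <- calls[calls$state == "gain", , drop = FALSE]
  lost <- calls[calls$state == "loss", , drop = FALSE]
  changed_bp <- total_length(calls)
  structure(list(
    sample_id = sample_id,
    calls = calls,
    gained_bp = total_length(gained),
    lost_bp = total_length(lost),
    changed_bp = changed_bp,
    burden_class = classify_burden(changed_bp, cutoff = cutoff)
  ), class = "cna_profile")
}

#' Classify genomic burden as small or large
#'
#' @param changed_bp total bp covered by CNA calls (union), or a
#'   `cna_profile` object.
#' @param cutoff bp cutoff; strictly more than `cutoff` is "large".
#' @return "small" or "large".
#' @export
classify_burden <- function(changed_bp, cutoff = 1e8) {
  if (inherits(changed_bp, "cna_profile")) changed_bp <- changed_bp$changed_bp
  if (changed_bp > cutoff) "large" else "small"
}

#' Compare a pair's diagnosis and relapse CNA calls
#'
#' Classifies each lesion as acquired (present at relapse only), lost
#' (present at diagnosis only) or unchanged. Gains and losses are compared
#' separately. A relapse call is "acquired" when the fraction of its length
#' covered by same-state diagnosis calls is below `reciprocal_overlap`;
#' symmetrically for "lost".
#'
#' @param diagnosis_calls,relapse_calls data.frames of CNA calls.
#' @param reciprocal_overlap overlap fraction deciding lesion identity
#'   (default 0.5).
#' @return list with `acquired`, `lost`, `unchanged` call data.frames.
#' @export
compare_pair <- function(diagnosis_calls, relapse_calls,
                         reciprocal_overlap = 0.5) {
  classify <- function(calls, against) {
    if (nrow(calls) == 0L) {
      return(list(new = calls, shared = calls))
    }
    frac <- vapply(seq_len(nrow(calls)), function(i) {
      ci <- calls[i, c("chrom", "start", "end")]
      if (nrow(against) == 0L) return(0)
      interval_overlap_bp(ci, against) / (ci$end - ci$start)
    }, numeric(1))
    list(new = calls[frac < reciprocal_overlap, , drop = FALSE],
         shared = calls[frac >= reciprocal_overlap, , drop = FALSE])
  }
  acq <- list(); lost <- list(); unch <- list()
  for (st in c("gain", "loss")) {
    d <- diagnosis_calls[diagnosis_calls$state == st, , drop = FALSE]
    r <- relapse_calls[relapse_calls$state == st, , drop = FALSE]
    ra <- classify(r, d)
    dl <- classify(d, r)
    acq[[st]] <- ra$new
    lost[[st]] <- dl$new
    unch[[st]] <- ra$shared
  }
  list(acquired = do.call(rbind, acq),
       lost = do.call(rbind, lost),
       unchanged = do.call(rbind, unch))
}

#' Per-sample aberration counts and group comparisons
#'
#' Counts imbalances, gains and losses per sample in two groups (e.g.
#' diagnosis vs relapse) and compares the groups with a two-sided
#' Mann-Whitney U test (exact when both groups have at most 8 samples and
#' no ties, normal approximation with continuity correction otherwise).
#'
#' @param diagnosis_profiles,relapse_profiles lists of `cna_profile`
#'   objects (or plain call data.frames).
#' @return list with `counts` (data.frame: sample, group, n_imbalances,
#'   n_gains, n_losses) and `tests` (data.frame: statistic compared, U,
#'   p.value).
#' @export
count_stats <- function(diagnosis_profiles, relapse_profiles) {
  if (length(diagnosis_profiles) == 0L || length(relapse_profiles) == 0L) {
    stop("count_stats: both groups must be non-empty")
  }
  count_one <- function(p, group, id) {
    calls <- if (inherits(p, "cna_profile")) p$calls else p
    sid <- if (inherits(p, "cna_profile")) p$sample_id else id
    data.frame(sample = sid, group = group,
               n_imbalances = nrow(calls),
               n_gains = sum(calls$state == "gain"),
               n_losses = sum(calls$state == "loss"),
               stringsAsFactors = FALSE)
  }
  cd <- do.call(rbind, lapply(seq_along(diagnosis_profiles), function(i)
    count_one(diagnosis_profiles[[i]], "diagnosis", paste0("D", i))))
  cr <- do.call(rbind, lapply(seq_along(relapse_profiles), function(i)
    count_one(relapse_profiles[[i]], "relapse", paste0("R", i))))
  counts <- rbind(cd, cr)
  tests <- do.call(rbind, lapply(
    c("n_imbalances", "n_gains", "n_losses"),
    function(v) {
      res <- mann_whitney_u(cd[[v]], cr[[v]])
      data.frame(statistic = v, U = res$U, p.value = res$p.value)
    }))
  list(counts = counts, tests = tests)
}

#' Two-sided Mann-Whitney U test
#'
#' Thin wrapper over [stats::wilcox.test()] that reports the U statistic
#' and uses the exact null distribution when both groups have at most 8
#' observations and there are no ties.
#'
#' @param x,y numeric vectors.
#' @param exact_max largest group size for which the exact distribution is
#'   used (default 8).
#' @return list with `U` and `p.value`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 8L) {
  if (length(x) == 0L || length(y) == 0L) stop("empty group")
  use_exact <- length(x) <= exact_max && length(y) <= exact_max &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = "two.sided", exact = use_exact, correct = TRUE))
  list(U = unname(wt$statistic), p.value = wt$p.value)
}

#' Recurrently acquired aberrations across pairs
#'
#' For genomic bins, counts the pairs whose acquired lesions (of a given
#' state) overlap the bin, and assigns a permutation p-value by randomly
#' re-placing each pair's acquired intervals (lengths preserved, uniform
#' start within the genome) and recounting; Benjamini-Hochberg correction
#' across bins within each state.
#'
#' @param evolutions list of [compare_pair()] results.
#' @param bins data.frame of genomic windows (`chrom`, `start`, `end`).
#' @param layout genome layout (list with `chromosomes` data.frame:
#'   `name`, `length`) used for random placement.
#' @param n_permutations number of null placements (default 1000).
#' @param seed RNG seed for reproducible placement.
#' @return data.frame: bin coordinates, state, n_pairs supporting,
#'   frequency, p.value, q.value.
#' @export
recurrent_acquisition_test <- function(evolutions, bins, layout,
                                       n_permutations = 1000L, seed = 1L) {
  if (length(evolutions) < 2L) stop("need at least 2 pairs")
  set.seed(seed)
  n_pairs <- length(evolutions)
  chroms <- layout$chromosomes
  bin_hits <- function(intervals, state) {
    # logical per bin: does any interval of this state overlap the bin
    iv <- intervals[intervals$state == state, , drop = FALSE]
    if (is.null(iv) || nrow(iv) == 0L) return(rep(FALSE, nrow(bins)))
    vapply(seq_len(nrow(bins)), function(b) {
      any(iv$chrom == bins$chrom[b] & iv$start < bins$end[b] &
            iv$end > bins$start[b])
    }, logical(1))
  }
  random_place <- function(intervals) {
    if (is.null(intervals) || nrow(intervals) == 0L) return(intervals)
    out <- intervals
    for (i in seq_len(nrow(out))) {
      len <- out$end[i] - out$start[i]
      ok <- chroms[chroms$length >= len, , drop = FALSE]
      j <- sample.int(nrow(ok), 1L)
      s <- floor(stats::runif(1, 0, ok$length[j] - len + 1))
      out$chrom[i] <- ok$name[j]
      out$start[i] <- s
      out$end[i] <- s + len
    }
    out
  }
  res <- list()
  for (st in c("gain", "loss")) {
    obs <- Reduce(`+`, lapply(evolutions, function(ev)
      bin_hits(ev$acquired, st)))
    exceed <- rep(0L, nrow(bins))
    for (p in seq_len(n_permutations)) {
      perm <- Reduce(`+`, lapply(evolutions, function(ev)
        bin_hits(random_place(ev$acquired), st)))
      exceed <- exceed + as.integer(perm >= obs)
    }
    pval <- (1 + exceed) / (1 + n_permutations)
    pval[obs == 0L] <- 1
    res[[st]] <- data.frame(
      bins, state = st, n_pairs = obs, frequency = obs / n_pairs,
      p.value = pval, q.value = stats::p.adjust(pval, method = "BH"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Gain/loss frequency track over a genomic grid
#'
#' At each grid position, the fraction of samples whose calls of each state
#' overlap the position.
#'
#' @param call_list list of per-sample call data.frames.
#' @param layout genome layout (as in [recurrent_acquisition_test()]).
#' @param grid_step grid spacing in bp.
#' @return data.frame: `chrom`, `pos`, `gain_freq`, `loss_freq`.
#' @export
frequency_track <- function(call_list, layout, grid_step = 1e6) {
  stopifnot(grid_step > 0)
  n <- length(call_list)
  grids <- do.call(rbind, lapply(seq_len(nrow(layout$chromosomes)),
    function(i) {
      ch <- layout$chromosomes$name[i]
      len <- layout$chromosomes$length[i]
      data.frame(chrom = ch, pos = seq(0, len - 1, by = grid_step),
                 stringsAsFactors = FALSE)
    }))
  gain <- rep(0L, nrow(grids)); loss <- rep(0L, nrow(grids))
  for (calls in call_list) {
    for (st in c("gain", "loss")) {
      cv <- calls[calls$state == st, , drop = FALSE]
      if (nrow(cv) == 0L) next
      hit <- rep(FALSE, nrow(grids))
      for (i in seq_len(nrow(cv))) {
        hit <- hit | (grids$chrom == cv$chrom[i] & grids$pos >= cv$start[i] &
                        grids$pos < cv$end[i])
      }
      if (st == "gain") gain <- gain + hit else loss <- loss + hit
    }
  }
  data.frame(grids, gain_freq = gain / n, loss_freq = loss / n)
}
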