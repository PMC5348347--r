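# Synthetic paired diagnosis/relapse cohort generator with planted ground
# truth across the three platforms (copy number, methylation, expression).
# Zero-noise settings make every downstream estimate exact and are used as
# oracle fixtures in the test suite.

#' Cohort design for a paired two-timepoint study
#'
#' @param n_pairs number of diagnosis/relapse pairs (default 17, the size
#'   of a typical paired expression cohort in this setting).
#' @param n_batches number of processing batches the samples are spread
#'   over (default 2); batches are assigned to whole pairs round-robin.
#' @param seed integer seed driving all randomness downstream.
#' @return list with `n_pairs`, `pairs` (data.frame: pair_id, diagnosis,
#'   relapse, batch), `seed`.
#' @export
cohort_design <- function(n_pairs = 17L, n_batches = 2L, seed = 1L) {
  stopifnot(n_pairs >= 1L, n_batches >= 1L)
  pid <- sprintf("P%02d", seq_len(n_pairs))
  pairs <- data.frame(
    pair_id = pid,
    diagnosis = paste0(pid, "_D"),
    relapse = paste0(pid, "_R"),
    batch = paste0("batch", (seq_len(n_pairs) - 1L) %% n_batches + 1L),
    stringsAsFactors = FALSE
  )
  list(n_pairs = as.integer(n_pairs), pairs = pairs, seed = as.integer(seed))
}

#' Sample sheet for a cohort design
#'
#' One row per sample with patient, timepoint and batch labels.
#'
#' @param design a [cohort_design()].
#' @return data.frame: sample_id, patient_id, timepoint, batch.
#' @export
design_sample_sheet <- function(design) {
  p <- design$pairs
  data.frame(
    sample_id = c(p$diagnosis, p$relapse),
    patient_id = c(p$pair_id, p$pair_id),
    timepoint = rep(c("diagnosis", "relapse"), each = nrow(p)),
    batch = c(p$batch, p$batch),
    stringsAsFactors = FALSE
  )
}

#' Generate a toy genome layout, probe sets and gene annotation
#'
#' Lays out `n_chrom` chromosomes of equal length, a uniform copy-number
#' probe grid, a methylation probe set (uniform grid at its own spacing,
#' optionally augmented with dense tiles around every TSS, as on promoter
#' tiling arrays) and `n_genes` genes with unique TSS positions and random
#' strands. All coordinates are 0-based half-open.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param probe_spacing copy-number probe spacing in bp (> 0).
#' @param n_genes total number of genes.
#' @param seed RNG seed.
#' @param meth_probe_spacing background methylation probe spacing
#'   (defaults to `probe_spacing`).
#' @param promoter_tiling add dense probe tiles around each TSS
#'   (default FALSE).
#' @param tile_halfwidth half-width in bp of the promoter tile
#'   (default 2400).
#' @param tile_spacing probe spacing inside the tile (default 400).
#' @param gene_length gene span in bp (default 20000).
#' @return list with `layout` (list: chromosomes data.frame name/length),
#'   `cn_probes`, `meth_probes` (data.frames chrom/pos, sorted), and
#'   `genes` (data.frame gene/chrom/strand/tss/start/end).
#' @export
generate_genome <- function(n_chrom = 2L, chrom_length = 1e7,
                            probe_spacing = 5000, n_genes = 100L,
                            seed = 1L, meth_probe_spacing = probe_spacing,
                            promoter_tiling = FALSE, tile_halfwidth = 2400,
                            tile_spacing = 400, gene_length = 20000) {
  if (probe_spacing <= 0 || meth_probe_spacing <= 0) {
    stop("probe spacing must be > 0")
  }
  stopifnot(n_chrom >= 1L, chrom_length > 0)
  set.seed(seed)
  chrom_names <- paste0("chr", seq_len(n_chrom))
  layout <- list(chromosomes = data.frame(
    name = chrom_names, length = rep(chrom_length, n_chrom),
    stringsAsFactors = FALSE))
  grid_probes <- function(spacing) {
    do.call(rbind, lapply(chrom_names, function(ch) {
      data.frame(chrom = ch, pos = seq(0, chrom_length - 1, by = spacing),
                 stringsAsFactors = FALSE)
    }))
  }
  cn_probes <- grid_probes(probe_spacing)

  # genes: unique TSS, away from chromosome edges so promoter windows and
  # tiles stay in bounds
  margin <- max(tile_halfwidth, 2000) + gene_length
  if (chrom_length <= 2 * margin) stop("chromosome too short to place genes")
  per_chrom <- ceiling(n_genes / n_chrom)
  genes <- do.call(rbind, lapply(seq_len(n_chrom), function(i) {
    k <- min(per_chrom, n_genes - (i - 1L) * per_chrom)
    if (k <= 0L) return(NULL)
    slots <- floor((chrom_length - 2 * margin) / (2 * gene_length))
    if (slots < k) stop("cannot place genes without TSS collisions")
    at <- sort(sample.int(slots, k)) * 2 * gene_length + margin
    strand <- sample(c("+", "-"), k, replace = TRUE)
    data.frame(
      gene = sprintf("g%s_%03d", i, seq_len(k)),
      chrom = chrom_names[i], strand = strand, tss = at,
      start = ifelse(strand == "+", at, at - gene_length),
      end = ifelse(strand == "+", at + gene_length, at),
      stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL

  meth_probes <- grid_probes(meth_probe_spacing)
  if (promoter_tiling) {
    tiles <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
      at <- seq(genes$tss[i] - tile_halfwidth, genes$tss[i] + tile_halfwidth,
                by = tile_spacing)
      at <- at[at >= 0 & at < chrom_length]
      data.frame(chrom = genes$chrom[i], pos = at, stringsAsFactors = FALSE)
    }))
    meth_probes <- rbind(meth_probes, tiles)
    meth_probes <- meth_probes[!duplicated(meth_probes), , drop = FALSE]
  }
  meth_probes <- meth_probes[order(meth_probes$chrom, meth_probes$pos), ,
                             drop = FALSE]
  rownames(meth_probes) <- NULL
  list(layout = layout, cn_probes = cn_probes, meth_probes = meth_probes,
       genes = genes)
}

# draw a set of non-overlapping segments on the layout
.draw_segments <- function(n, layout, length_range, existing = NULL,
                           max_tries = 200L) {
  chroms <- layout$chromosomes
  placed <- existing
  out <- NULL
  for (i in seq_len(n)) {
    for (try in seq_len(max_tries)) {
      len <- exp(stats::runif(1, log(length_range[1]), log(length_range[2])))
      len <- round(len)
      ok <- chroms[chroms$length > len, , drop = FALSE]
      if (nrow(ok) == 0L) stop("segment longer than every chromosome")
      j <- sample.int(nrow(ok), 1L)
      s <- floor(stats::runif(1, 0, ok$length[j] - len))
      cand <- data.frame(chrom = ok$name[j], start = s, end = s + len,
                         stringsAsFactors = FALSE)
      clash <- !is.null(placed) && nrow(placed) > 0L &&
        any(placed$chrom == cand$chrom & placed$start < cand$end &
              placed$end > cand$start)
      if (!clash) break
      if (try == max_tries) stop("could not place non-overlapping segments")
    }
    placed <- if (is.null(placed)) cand else
      rbind(placed[, c("chrom", "start", "end")], cand)
    out <- rbind(out, cand)
  }
  out
}

#' Simulate paired copy-number profiles with planted lesions
#'
#' Per pair, plants shared segments (present at both timepoints),
#' relapse-acquired segments, and optionally diagnosis-only (lost)
#' segments; probe values are the local segment mean plus Gaussian noise.
#'
#' @param design a [cohort_design()].
#' @param layout genome layout from [generate_genome()].
#' @param probes copy-number probe data.frame (`chrom`, `pos`).
#' @param n_shared,n_acquired,n_lost planted segment counts per pair.
#' @param segment_length_range bp range (log-uniform draw).
#' @param gain_log2,loss_log2 planted segment means (must be callable at
#'   the +-0.1 thresholds: gain > 0.1, loss < -0.1).
#' @param noise_sd Gaussian probe noise SD.
#' @param p_gain probability a planted segment is a gain (default 0.5).
#' @return list with `values` (probes x samples matrix), `truth`
#'   (data.frame: sample, pair_id, timepoint, chrom, start, end, state,
#'   mean_log2, origin in shared/acquired/lost).
#' @export
simulate_cna <- function(design, layout, probes, n_shared = 5L,
                         n_acquired = 4L, n_lost = 1L,
                         segment_length_range = c(5e5, 3e6),
                         gain_log2 = 0.4, loss_log2 = -0.4,
                         noise_sd = 0.1, p_gain = 0.5) {
  if (!(gain_log2 > 0.1 && loss_log2 < -0.1)) {
    stop("planted means must clear the +-0.1 call thresholds")
  }
  max_len <- max(layout$chromosomes$length)
  if (segment_length_range[2] > max_len) {
    stop("segment length range exceeds chromosome bounds")
  }
  set.seed(design$seed + 101L)
  samples <- c(rbind(design$pairs$diagnosis, design$pairs$relapse))
  vals <- matrix(0, nrow = nrow(probes), ncol = length(samples),
                 dimnames = list(NULL, samples))
  truth <- NULL
  for (k in seq_len(design$n_pairs)) {
    segs <- .draw_segments(n_shared + n_acquired + n_lost, layout,
                           segment_length_range)
    if (is.null(segs)) {
      segs <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), state = character(),
                         mean_log2 = numeric(), origin = character())
    }
    origin <- rep(c("shared", "acquired", "lost"),
                  c(n_shared, n_acquired, n_lost))
    if (nrow(segs) > 0L) {
      state <- ifelse(stats::runif(nrow(segs)) < p_gain, "gain", "loss")
      m <- ifelse(state == "gain", gain_log2, loss_log2)
      segs$state <- state
      segs$mean_log2 <- m
      segs$origin <- origin
    }
    add_segments <- function(col, keep_origin) {
      sel <- segs[segs$origin %in% keep_origin, , drop = FALSE]
      v <- rep(0, nrow(probes))
      for (i in seq_len(nrow(sel))) {
        hit <- probes$chrom == sel$chrom[i] & probes$pos >= sel$start[i] &
          probes$pos < sel$end[i]
        v[hit] <- v[hit] + sel$mean_log2[i]
      }
      v
    }
    d_col <- design$pairs$diagnosis[k]
    r_col <- design$pairs$relapse[k]
    vals[, d_col] <- add_segments(d_col, c("shared", "lost"))
    vals[, r_col] <- add_segments(r_col, c("shared", "acquired"))
    if (nrow(segs) > 0L) {
      tr_d <- segs[segs$origin %in% c("shared", "lost"), , drop = FALSE]
      tr_r <- segs[segs$origin %in% c("shared", "acquired"), , drop = FALSE]
      if (nrow(tr_d)) truth <- rbind(truth, data.frame(
        sample = d_col, pair_id = design$pairs$pair_id[k],
        timepoint = "diagnosis", tr_d, stringsAsFactors = FALSE))
      if (nrow(tr_r)) truth <- rbind(truth, data.frame(
        sample = r_col, pair_id = design$pairs$pair_id[k],
        timepoint = "relapse", tr_r, stringsAsFactors = FALSE))
    }
  }
  if (noise_sd > 0) {
    vals <- vals + matrix(stats::rnorm(length(vals), 0, noise_sd),
                          nrow = nrow(vals))
  }
  rownames(truth) <- NULL
  list(values = vals, truth = truth)
}

#' Convert methylation fractions to paired log2 ratios and back
#'
#' `x = log2(m / (1 - m))`; its inverse is `m = 2^x / (1 + 2^x)`. A
#' bijection on (0, 1), used because normalization operates on log ratios
#' while region thresholds are stated in percentage units.
#'
#' @param m methylation fractions in (0, 1).
#' @param x methylation log2 ratios.
#' @return transformed numeric vector/matrix.
#' @export
meth_fraction_to_log2 <- function(m) log2(m / (1 - m))

#' @rdname meth_fraction_to_log2
#' @export
meth_log2_to_fraction <- function(x) 2^x / (1 + 2^x)

#' Simulate paired methylation fractions with planted DMRs and a batch
#' effect
#'
#' Baseline per-probe methylation fractions are drawn from a Beta
#' distribution shared by the pair; planted DMRs shift the relapse sample
#' by `dmr_delta` over contiguous probe runs; `batch_shift` is added to
#' every sample of batches other than the first before clipping to [0, 1].
#'
#' @param design a [cohort_design()].
#' @param probes methylation probe data.frame (`chrom`, `pos`).
#' @param baseline_shape1,baseline_shape2 Beta parameters of the baseline
#'   fraction distribution (default 1, 4: mostly unmethylated).
#' @param batch_shift additive fraction shift for non-reference batches.
#' @param n_dmrs number of DMRs to plant at random contiguous probe runs
#'   (ignored when `dmr_sites` is given).
#' @param dmr_probe_count probes per planted DMR.
#' @param dmr_delta methylation-fraction change at relapse (positive =
#'   hypermethylation); sign is drawn per DMR unless `dmr_sign` is given.
#' @param dmr_sign optional fixed sign (+1/-1) for all planted DMRs.
#' @param dmr_sites optional data.frame (`chrom`, `start`, `end`,
#'   optionally `delta`) of explicit regions to plant instead of random
#'   placement.
#' @param noise_sd Gaussian probe noise SD (on the fraction scale).
#' @return list with `values` (probes x samples fraction matrix), `dmrs`
#'   (data.frame: chrom, start, end, n_probes, delta).
#' @export
simulate_methylation <- function(design, probes, baseline_shape1 = 1,
                                 baseline_shape2 = 4, batch_shift = 0,
                                 n_dmrs = 10L, dmr_probe_count = 6L,
                                 dmr_delta = 0.2, dmr_sign = NULL,
                                 dmr_sites = NULL, noise_sd = 0.05) {
  stopifnot(dmr_probe_count >= 1L, abs(dmr_delta) <= 1)
  set.seed(design$seed + 202L)
  np <- nrow(probes)
  samples <- c(rbind(design$pairs$diagnosis, design$pairs$relapse))
  baseline <- stats::rbeta(np, baseline_shape1, baseline_shape2)
  vals <- matrix(rep(baseline, length(samples)), nrow = np,
                 dimnames = list(NULL, samples))

  # planted DMRs: indices of member probes
  dmrs <- NULL
  dmr_rows <- list()
  if (!is.null(dmr_sites)) {
    for (i in seq_len(nrow(dmr_sites))) {
      idx <- which(probes$chrom == dmr_sites$chrom[i] &
                     probes$pos >= dmr_sites$start[i] &
                     probes$pos < dmr_sites$end[i])
      if (length(idx) == 0L) next
      delta <- if ("delta" %in% names(dmr_sites)) dmr_sites$delta[i] else {
        sgn <- if (is.null(dmr_sign)) sample(c(-1, 1), 1) else dmr_sign
        sgn * dmr_delta
      }
      dmr_rows[[length(dmr_rows) + 1L]] <- idx
      dmrs <- rbind(dmrs, data.frame(
        chrom = dmr_sites$chrom[i], start = probes$pos[idx[1]],
        end = probes$pos[idx[length(idx)]] + 1,
        n_probes = length(idx), delta = delta, stringsAsFactors = FALSE))
    }
  } else if (n_dmrs > 0L) {
    # random contiguous probe runs, non-overlapping, within one chromosome
    used <- rep(FALSE, np)
    chrom_rle <- rle(probes$chrom)
    chrom_end <- cumsum(chrom_rle$lengths)
    chrom_start <- chrom_end - chrom_rle$lengths + 1L
    for (i in seq_len(n_dmrs)) {
      for (try in seq_len(500L)) {
        ci <- sample.int(length(chrom_rle$values), 1L)
        lo <- chrom_start[ci]; hi <- chrom_end[ci] - dmr_probe_count + 1L
        if (hi < lo) next
        s <- sample(lo:hi, 1L)
        idx <- s:(s + dmr_probe_count - 1L)
        # one probe of padding so neighboring DMRs never merge
        pad <- max(lo, s - 1L):min(chrom_end[ci], s + dmr_probe_count)
        if (!any(used[pad])) break
        if (try == 500L) stop("could not place non-overlapping DMRs")
      }
      used[max(1L, s - 1L):min(np, s + dmr_probe_count)] <- TRUE
      sgn <- if (is.null(dmr_sign)) sample(c(-1, 1), 1) else dmr_sign
      delta <- sgn * dmr_delta
      dmr_rows[[length(dmr_rows) + 1L]] <- idx
      dmrs <- rbind(dmrs, data.frame(
        chrom = probes$chrom[s], start = probes$pos[idx[1]],
        end = probes$pos[idx[length(idx)]] + 1,
        n_probes = dmr_probe_count, delta = delta, stringsAsFactors = FALSE))
    }
  }
  if (!is.null(dmrs)) {
    for (i in seq_along(dmr_rows)) {
      vals[dmr_rows[[i]], design$pairs$relapse] <-
        vals[dmr_rows[[i]], design$pairs$relapse] + dmrs$delta[i]
    }
  }

  if (batch_shift != 0) {
    sheet <- design_sample_sheet(design)
    ref <- sort(unique(sheet$batch))[1]
    shifted <- sheet$sample_id[sheet$batch != ref]
    vals[, shifted] <- vals[, shifted] + batch_shift
  }
  if (noise_sd > 0) {
    vals <- vals + matrix(stats::rnorm(length(vals), 0, noise_sd),
                          nrow = np)
  }
  vals[vals < 0] <- 0
  vals[vals > 1] <- 1
  list(values = vals, dmrs = dmrs)
}

#' Simulate gene expression driven by planted CNA dosage, promoter
#' methylation and direct relapse effects
#'
#' Per gene g and sample s:
#' `expr = baseline_g + dosage_slope * cna_log2(g, s)
#'        + meth_slope * promoter_fraction(g, s) + de effect + noise`,
#' where `cna_log2` is the planted segment mean over the gene span and
#' `promoter_fraction` the mean planted methylation fraction over the
#' strand-aware promoter window.
#'
#' @param design a [cohort_design()].
#' @param genes gene annotation from [generate_genome()].
#' @param cna_truth planted-segment data.frame from [simulate_cna()]
#'   (or NULL for no dosage component).
#' @param cna_probes optional copy-number probe table (`chrom`, `pos`);
#'   when given, the gene-level CNA log2 driving expression is the
#'   probe-weighted mean of the planted (noiseless) segment values over
#'   the gene span — the same summary the downstream association step
#'   measures — so partial overlaps are handled continuously. Without it,
#'   only genes fully inside a segment receive the dosage term.
#' @param meth optional result of [simulate_methylation()] plus its probe
#'   table, as `list(values=, probes=)`, used for the methylation
#'   component.
#' @param de_genes character vector of genes with a direct relapse effect.
#' @param de_log2fc log2 effect added to relapse samples of `de_genes`.
#' @param dosage_slope multiplier on the gene-level CNA log2 ratio.
#' @param meth_slope multiplier on the promoter methylation fraction
#'   (negative = repression).
#' @param baseline_mean,baseline_sd per-gene baseline distribution (log2).
#' @param noise_sd Gaussian noise SD (log2).
#' @return list with `values` (genes x samples log2 matrix) and `truth`
#'   (list: de_genes, de_log2fc, dosage_genes, meth_genes).
#' @export
simulate_expression <- function(design, genes, cna_truth = NULL,
                                cna_probes = NULL,
                                meth = NULL, de_genes = character(),
                                de_log2fc = -1, dosage_slope = 1,
                                meth_slope = -3, baseline_mean = 8,
                                baseline_sd = 1, noise_sd = 0.3) {
  if (length(de_genes) && !all(de_genes %in% genes$gene)) {
    stop("unknown gene id in de_genes")
  }
  set.seed(design$seed + 303L)
  samples <- c(rbind(design$pairs$diagnosis, design$pairs$relapse))
  G <- nrow(genes)
  baseline <- stats::rnorm(G, baseline_mean, baseline_sd)
  vals <- matrix(rep(baseline, length(samples)), nrow = G,
                 dimnames = list(genes$gene, samples))

  dosage_genes <- character()
  if (!is.null(cna_truth) && nrow(cna_truth) > 0L && dosage_slope != 0) {
    if (!is.null(cna_probes)) {
      # probe-weighted planted copy number over each gene span
      gene_probes <- lapply(seq_len(nrow(genes)), function(i) {
        which(cna_probes$chrom == genes$chrom[i] &
                cna_probes$pos >= genes$start[i] &
                cna_probes$pos < genes$end[i])
      })
      for (s in samples) {
        segs <- cna_truth[cna_truth$sample == s, , drop = FALSE]
        v <- rep(0, nrow(cna_probes))
        for (i in seq_len(nrow(segs))) {
          hit <- cna_probes$chrom == segs$chrom[i] &
            cna_probes$pos >= segs$start[i] & cna_probes$pos < segs$end[i]
          v[hit] <- v[hit] + segs$mean_log2[i]
        }
        gv <- vapply(gene_probes, function(idx) {
          if (length(idx) == 0L) 0 else mean(v[idx])
        }, numeric(1))
        vals[, s] <- vals[, s] + dosage_slope * gv
        dosage_genes <- union(dosage_genes, genes$gene[gv != 0])
      }
    } else {
      for (s in samples) {
        segs <- cna_truth[cna_truth$sample == s, , drop = FALSE]
        for (i in seq_len(nrow(segs))) {
          inside <- genes$chrom == segs$chrom[i] &
            genes$start >= segs$start[i] & genes$end <= segs$end[i]
          vals[inside, s] <- vals[inside, s] + dosage_slope * segs$mean_log2[i]
          dosage_genes <- union(dosage_genes, genes$gene[inside])
        }
      }
    }
  }

  meth_genes <- character()
  if (!is.null(meth) && meth_slope != 0) {
    win <- promoter_windows(genes)
    pm <- .aggregate_probes(meth$values, meth$probes, win$promoter, "mean")
    pm[is.na(pm)] <- 0
    vals[rownames(pm), samples] <- vals[rownames(pm), samples] +
      meth_slope * pm[, samples]
    # genes whose promoter methylation changes between timepoints
    dfrac <- pm[, design$pairs$relapse, drop = FALSE] -
      pm[, design$pairs$diagnosis, drop = FALSE]
    meth_genes <- rownames(pm)[rowSums(abs(dfrac) > 1e-9) > 0]
  }

  if (length(de_genes)) {
    vals[de_genes, design$pairs$relapse] <-
      vals[de_genes, design$pairs$relapse] + de_log2fc
  }
  if (noise_sd > 0) {
    vals <- vals + matrix(stats::rnorm(length(vals), 0, noise_sd), nrow = G)
  }
  list(values = vals,
       truth = list(de_genes = de_genes, de_log2fc = de_log2fc,
                    dosage_genes = dosage_genes, meth_genes = meth_genes))
}

#' Simulate a full matched three-platform cohort with planted truth
#'
#' Orchestrates [generate_genome()], [simulate_cna()],
#' [simulate_methylation()] (DMRs planted inside promoter windows of a
#' chosen gene set so the methylation-repression route is testable) and
#' [simulate_expression()].
#'
#' @param n_pairs pairs in the cohort.
#' @param seed master seed.
#' @param n_chrom,chrom_length,probe_spacing,n_genes genome parameters.
#' @param n_meth_genes genes given planted promoter hypermethylation at
#'   relapse.
#' @param n_de_genes genes given a direct relapse expression effect.
#' @param de_genes optional explicit gene ids for the direct effect
#'   (overrides the random choice of `n_de_genes`; useful for planting
#'   the same signature in several simulated studies).
#' @param dmr_delta planted promoter methylation-fraction increase.
#' @param de_log2fc planted direct relapse log2 effect.
#' @param cna_noise_sd,meth_noise_sd,expr_noise_sd platform noise levels.
#' @param batch_shift methylation batch effect (fraction units).
#' @param ... further arguments passed to [simulate_cna()].
#' @return list with `design`, `genome`, `cna`, `meth`, `expr`, and
#'   `truth` (merged ground-truth list).
#' @export
simulate_cohort <- function(n_pairs = 17L, seed = 1L, n_chrom = 2L,
                            chrom_length = 1e7, probe_spacing = 5000,
                            n_genes = 120L, n_meth_genes = 5L,
                            n_de_genes = 5L, de_genes = NULL,
                            dmr_delta = 0.25,
                            de_log2fc = -1.5, cna_noise_sd = 0.1,
                            meth_noise_sd = 0.05, expr_noise_sd = 0.3,
                            batch_shift = 0.05, ...) {
  design <- cohort_design(n_pairs = n_pairs, seed = seed)
  genome <- generate_genome(n_chrom = n_chrom, chrom_length = chrom_length,
                            probe_spacing = probe_spacing, n_genes = n_genes,
                            seed = seed, promoter_tiling = TRUE)
  cna <- simulate_cna(design, genome$layout, genome$cn_probes,
                      noise_sd = cna_noise_sd, ...)
  set.seed(seed + 404L)
  meth_genes <- sample(genome$genes$gene, n_meth_genes)
  gsel <- genome$genes[match(meth_genes, genome$genes$gene), ]
  win <- promoter_windows(gsel)
  dmr_sites <- data.frame(chrom = win$promoter$chrom,
                          start = win$promoter$start,
                          end = win$promoter$end,
                          delta = dmr_delta, stringsAsFactors = FALSE)
  meth <- simulate_methylation(design, genome$meth_probes,
                               dmr_sites = dmr_sites,
                               batch_shift = batch_shift,
                               noise_sd = meth_noise_sd)
  if (is.null(de_genes)) {
    de_genes <- sample(setdiff(genome$genes$gene, meth_genes), n_de_genes)
  } else {
    de_genes <- intersect(de_genes, genome$genes$gene)
  }
  expr <- simulate_expression(
    design, genome$genes, cna_truth = cna$truth,
    cna_probes = genome$cn_probes,
    meth = list(values = meth$values, probes = genome$meth_probes),
    de_genes = de_genes, de_log2fc = de_log2fc,
    noise_sd = expr_noise_sd)
  list(design = design, genome = genome, cna = cna, meth = meth,
       expr = expr,
       truth = list(cna_segments = cna$truth, dmrs = meth$dmrs,
                    meth_genes = meth_genes, de_genes = de_genes,
                    de_log2fc = de_log2fc,
                    dosage_genes = expr$truth$dosage_genes))
}
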