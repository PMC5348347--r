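test_that("genome generation places probes and genes deterministically", {
  g <- generate_genome(n_chrom = 2, chrom_length = 1e7, probe_spacing = 5000,
                       n_genes = 20, seed = 9)
  # uniform grid arithmetic: 1e7 / 5000 probes per chromosome per platform
  expect_equal(sum(g$cn_probes$chrom == "chr1"), 2000L)
  expect_equal(sum(g$cn_probes$chrom == "chr2"), 2000L)
  expect_equal(nrow(g$meth_probes), 4000L)
  expect_equal(nrow(g$genes), 20L)
  expect_false(any(duplicated(g$genes$tss)))
  expect_true(all(g$genes$tss > 0 & g$genes$tss < 1e7))
  for (p in list(g$cn_probes, g$meth_probes)) {
    for (ch in unique(p$chrom)) {
      expect_false(is.unsorted(p$pos[p$chrom == ch], strictly = TRUE))
    }
  }

  g2 <- generate_genome(n_chrom = 2, chrom_length = 1e7,
                        probe_spacing = 5000, n_genes = 20, seed = 9)
  expect_identical(g, g2)

  expect_error(generate_genome(probe_spacing = 0), "spacing")
  expect_error(generate_genome(n_chrom = 1, chrom_length = 1e5,
                               n_genes = 50), "place")
})

test_that("promoter tiling adds dense probes around every TSS", {
  g <- generate_genome(n_chrom = 1, chrom_length = 5e6, probe_spacing = 5000,
                       n_genes = 8, seed = 2, promoter_tiling = TRUE)
  for (i in seq_len(8)) {
    win <- c(g$genes$tss[i] - 2400, g$genes$tss[i] + 2400)
    n_in <- sum(g$meth_probes$pos >= win[1] & g$meth_probes$pos <= win[2])
    expect_gte(n_in, 13L)
  }
})

test_that("planted CNA segments appear exactly in zero-noise probe values", {
  d <- cohort_design(n_pairs = 4, seed = 5)
  g <- generate_genome(n_chrom = 2, chrom_length = 1e7, probe_spacing = 5000,
                       n_genes = 10, seed = 5)
  sim <- simulate_cna(d, g$layout, g$cn_probes, n_shared = 2, n_acquired = 2,
                      n_lost = 1, gain_log2 = 0.3, loss_log2 = -0.3,
                      noise_sd = 0)
  # every probe inside a planted segment carries the segment mean exactly
  for (k in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[k, ]
    idx <- g$cn_probes$chrom == tr$chrom & g$cn_probes$pos >= tr$start &
      g$cn_probes$pos < tr$end
    expect_true(all(sim$values[idx, tr$sample] == tr$mean_log2))
  }
  # probes outside any planted segment are exactly zero
  s1 <- colnames(sim$values)[1]
  tr1 <- sim$truth[sim$truth$sample == s1, ]
  out <- rep(TRUE, nrow(g$cn_probes))
  for (k in seq_len(nrow(tr1))) {
    out <- out & !(g$cn_probes$chrom == tr1$chrom[k] &
                     g$cn_probes$pos >= tr1$start[k] &
                     g$cn_probes$pos < tr1$end[k])
  }
  expect_true(all(sim$values[out, s1] == 0))
})

test_that("without acquired or lost segments the pair profiles are identical", {
  d <- cohort_design(n_pairs = 3, seed = 6)
  g <- generate_genome(n_chrom = 1, chrom_length = 1e7, probe_spacing = 5000,
                       n_genes = 5, seed = 6)
  sim <- simulate_cna(d, g$layout, g$cn_probes, n_shared = 3, n_acquired = 0,
                      n_lost = 0, noise_sd = 0)
  expect_equal(sim$values[, d$pairs$diagnosis],
               sim$values[, d$pairs$relapse], ignore_attr = TRUE)
})

test_that("planted segment means must clear the call thresholds", {
  d <- cohort_design(n_pairs = 2, seed = 1)
  g <- generate_genome(seed = 1)
  expect_error(simulate_cna(d, g$layout, g$cn_probes, gain_log2 = 0.05),
               "threshold")
  expect_error(simulate_cna(d, g$layout, g$cn_probes,
                            segment_length_range = c(1e6, 1e9)), "bounds")
})

test_that("zero-noise methylation DMRs shift relapse fractions exactly", {
  d <- cohort_design(n_pairs = 4, seed = 8)
  g <- generate_genome(n_chrom = 1, chrom_length = 2e6, probe_spacing = 500,
                       n_genes = 5, seed = 8)
  sim <- simulate_methylation(d, g$meth_probes, baseline_shape1 = 10,
                              baseline_shape2 = 30, n_dmrs = 3,
                              dmr_probe_count = 6, dmr_delta = 0.2,
                              dmr_sign = 1, noise_sd = 0, batch_shift = 0)
  delta <- sim$values[, d$pairs$relapse[1]] - sim$values[, d$pairs$diagnosis[1]]
  in_dmr <- rep(FALSE, nrow(g$meth_probes))
  for (k in seq_len(nrow(sim$dmrs))) {
    in_dmr <- in_dmr | (g$meth_probes$chrom == sim$dmrs$chrom[k] &
                          g$meth_probes$pos >= sim$dmrs$start[k] &
                          g$meth_probes$pos < sim$dmrs$end[k])
  }
  expect_true(all(abs(delta[in_dmr] - 0.2) < 1e-12))
  expect_true(all(delta[!in_dmr] == 0))
  expect_equal(sum(in_dmr), 3L * 6L)
  expect_true(all(sim$values >= 0 & sim$values <= 1))
})

test_that("a planted batch shift moves the batch mean by the stated amount", {
  d <- cohort_design(n_pairs = 10, n_batches = 2, seed = 4)
  g <- generate_genome(n_chrom = 1, chrom_length = 2e6, probe_spacing = 500,
                       n_genes = 5, seed = 4)
  sim <- simulate_methylation(d, g$meth_probes, baseline_shape1 = 10,
                              baseline_shape2 = 30, batch_shift = 0.1,
                              n_dmrs = 0, noise_sd = 0.02)
  sheet <- design_sample_sheet(d)
  b <- sheet$batch[match(colnames(sim$values), sheet$sample_id)]
  diff <- mean(sim$values[, b == "batch2"]) - mean(sim$values[, b == "batch1"])
  expect_equal(diff, 0.1, tolerance = 0.02)
})

test_that("expression construction is exact arithmetic at zero noise", {
  d <- cohort_design(n_pairs = 3, seed = 12)
  g <- generate_genome(n_chrom = 1, chrom_length = 1e7, probe_spacing = 1000,
                       n_genes = 6, seed = 12, promoter_tiling = TRUE)
  # dosage: place one acquired gain over gene 1's span in pair 1
  gene1 <- g$genes[1, ]
  truth <- data.frame(sample = d$pairs$relapse[1], pair_id = "P01",
                      timepoint = "relapse", chrom = gene1$chrom,
                      start = gene1$start - 1000, end = gene1$end + 1000,
                      state = "gain", mean_log2 = 0.3, origin = "acquired")
  expr <- simulate_expression(d, g$genes, cna_truth = truth,
                              dosage_slope = 1, meth_slope = 0,
                              noise_sd = 0)
  fc <- expr$values[, d$pairs$relapse] - expr$values[, d$pairs$diagnosis]
  expect_equal(unname(fc[gene1$gene, 1]), 0.3)
  expect_true(all(fc[, 2:3] == 0))
  expect_equal(expr$truth$dosage_genes, gene1$gene)

  # methylation repression: promoter fraction up 0.2 -> drop slope*0.2
  win <- promoter_windows(g$genes[2, , drop = FALSE])
  msim <- simulate_methylation(
    d, g$meth_probes, baseline_shape1 = 10, baseline_shape2 = 30,
    dmr_sites = data.frame(win$promoter[, c("chrom", "start", "end")],
                           delta = 0.2),
    noise_sd = 0, batch_shift = 0)
  expr2 <- simulate_expression(d, g$genes, meth = list(
    values = msim$values, probes = g$meth_probes),
    meth_slope = -2, noise_sd = 0)
  fc2 <- expr2$values[, d$pairs$relapse] - expr2$values[, d$pairs$diagnosis]
  expect_equal(unname(fc2[g$genes$gene[2], ]), rep(-0.4, 3))
  expect_equal(expr2$truth$meth_genes, g$genes$gene[2])

  # direct effect applied to all relapse samples
  expr3 <- simulate_expression(d, g$genes, de_genes = g$genes$gene[3],
                               de_log2fc = -1, meth_slope = 0, noise_sd = 0)
  fc3 <- expr3$values[, d$pairs$relapse] - expr3$values[, d$pairs$diagnosis]
  expect_equal(unname(fc3[g$genes$gene[3], ]), rep(-1, 3))

  expect_error(simulate_expression(d, g$genes, de_genes = "nope"),
               "unknown gene")
})

test_that("the cohort simulator is deterministic and internally consistent", {
  co1 <- simulate_cohort(n_pairs = 4, seed = 33, n_genes = 30,
                         n_meth_genes = 2, n_de_genes = 2)
  co2 <- simulate_cohort(n_pairs = 4, seed = 33, n_genes = 30,
                         n_meth_genes = 2, n_de_genes = 2)
  expect_identical(co1$cna$values, co2$cna$values)
  expect_identical(co1$meth$values, co2$meth$values)
  expect_identical(co1$expr$values, co2$expr$values)
  expect_identical(co1$truth, co2$truth)
  expect_equal(length(co1$truth$meth_genes), 2L)
  expect_equal(length(co1$truth$de_genes), 2L)
  # de and meth gene sets are disjoint by construction
  expect_length(intersect(co1$truth$de_genes, co1$truth$meth_genes), 0)
  # planted promoter DMRs all lie in promoter windows of meth genes
  ann <- co1$genome$genes
  win <- promoter_windows(ann[match(co1$truth$meth_genes, ann$gene), ])
  for (k in seq_len(nrow(co1$meth$dmrs))) {
    hit <- any(win$promoter$chrom == co1$meth$dmrs$chrom[k] &
                 win$promoter$start <= co1$meth$dmrs$start[k] &
                 win$promoter$end >= co1$meth$dmrs$end[k])
    expect_true(hit)
  }
})

test_that("fraction/log-ratio conversion is a bijection on (0,1)", {
  m <- c(1e-4, 0.1, 0.25, 0.5, 0.77, 1 - 1e-4)
  expect_equal(meth_log2_to_fraction(meth_fraction_to_log2(m)), m)
  x <- seq(-8, 8, by = 0.5)
  expect_equal(meth_fraction_to_log2(meth_log2_to_fraction(x)), x)
})

test_that("planted truth round-trips through the plain-text writers", {
  co <- simulate_cohort(n_pairs = 3, seed = 21, n_genes = 30,
                        n_meth_genes = 2, n_de_genes = 2)
  tmp <- withr::local_tempdir()

  segs <- data.frame(sample = co$truth$cna_segments$sample,
                     co$truth$cna_segments[, c("chrom", "start", "end",
                                               "mean_log2")],
                     n_markers = 10L)
  write_seg(segs, file.path(tmp, "truth.seg"))
  back <- read_seg(file.path(tmp, "truth.seg"))
  expect_equal(back$start, segs$start)
  expect_equal(back$end, segs$end)
  expect_equal(back$mean_log2, segs$mean_log2)

  write_bed(co$truth$dmrs, file.path(tmp, "dmrs.bed"))
  bed <- read_bed(file.path(tmp, "dmrs.bed"))
  expect_equal(bed$start, co$truth$dmrs$start)
  expect_equal(bed$end, co$truth$dmrs$end)

  write_matrix(co$expr$values, file.path(tmp, "expr.tsv"), key = "gene")
  m <- read_matrix(file.path(tmp, "expr.tsv"))
  expect_equal(m, co$expr$values, tolerance = 1e-9)
})
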