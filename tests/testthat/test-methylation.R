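test_that("quantile normalization forces identical column distributions", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, "b"]), c(2.5, 3.5, 4.5))

  # identical columns unchanged
  m2 <- cbind(x = c(0.3, 0.9, 0.1), y = c(0.3, 0.9, 0.1))
  expect_equal(quantile_normalize(m2), m2)

  # property: all column distributions identical after normalization
  set.seed(3)
  m3 <- matrix(rnorm(500), 100, 5, dimnames = list(NULL, letters[1:5]))
  qn3 <- quantile_normalize(m3)
  sorted <- apply(qn3, 2, sort)
  expect_equal(max(apply(sorted, 1, function(r) diff(range(r)))), 0,
               tolerance = 1e-12)
  # ranks preserved within columns
  expect_equal(apply(qn3, 2, rank), apply(m3, 2, rank))

  expect_warning(quantile_normalize(m3[, 1, drop = FALSE]), "single")
})

test_that("batch correction removes a planted location shift", {
  set.seed(14)
  n <- 200
  batch <- rep(c("A", "B"), each = 6)
  m <- matrix(rnorm(n * 12, 5, 1), n, 12,
              dimnames = list(NULL, paste0("s", 1:12)))
  m[, batch == "B"] <- m[, batch == "B"] + 0.5
  corr <- batch_correct(m, batch)
  sep <- mean(corr[, batch == "B"]) - mean(corr[, batch == "A"])
  expect_lt(abs(sep), 0.05)

  # null case: without a batch effect the data are barely touched
  m0 <- matrix(rnorm(n * 12, 5, 1), n, 12)
  corr0 <- batch_correct(m0, batch)
  expect_lt(max(abs(corr0 - m0)), 1) # small relative to the noise SD
  expect_gt(cor(as.vector(corr0), as.vector(m0)), 0.95)

  # single batch: identity
  expect_identical(batch_correct(m, rep("A", 12)), m)
  # centering fallback preserves the grand mean
  cc <- batch_correct(m, batch, method = "center")
  expect_equal(rowMeans(cc), rowMeans(m))
  expect_warning(batch_correct(m, batch, condition = batch,
                               method = "center"), "confounded")
})

test_that("peak calling honors width, probe-count and score rules", {
  probes <- data.frame(chrom = "chr1",
                       pos = c(1000, 1500, 3500, 10000, 12000))
  # scores supplied directly: probes 1,2 qualify (500 bp apart)
  pk <- call_peaks(probes, values = rep(0, 5),
                   scores = c(3, 2.5, 0, 0, 0))
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$start, 1000)
  expect_equal(pk$end, 1501)
  expect_equal(pk$n_probes, 2L)

  # a single qualifying probe is not a peak
  pk1 <- call_peaks(probes, rep(0, 5), scores = c(3, 0, 0, 0, 0))
  expect_equal(nrow(pk1), 0L)

  # two qualifying probes 2000 bp apart -> two 1-probe runs -> no peaks
  pk2 <- call_peaks(probes, rep(0, 5), scores = c(0, 0, 0, 3, 3))
  expect_equal(nrow(pk2), 0L)

  # peak counts invariant to adding probes below the cutoff
  probes3 <- data.frame(chrom = "chr1", pos = c(1000, 1500, 1700))
  pk3a <- call_peaks(probes3, rep(0, 3), scores = c(3, 2.5, 0))
  expect_equal(nrow(pk3a), nrow(pk))
})

test_that("peak scores highlight locally elevated windows", {
  set.seed(5)
  probes <- data.frame(chrom = "chr1", pos = seq(0, 99750, by = 250))
  v <- rnorm(400, 0, 0.3)
  v[200:205] <- v[200:205] + 3 # strong local methylation
  sc <- peak_scores(probes, v, width = 750)
  expect_gt(max(sc[200:205]), 2)
  expect_lt(max(sc[-(198:207)]), max(sc[200:205]))
  pk <- call_peaks(probes, v, width = 750, min_probes = 2, score_cutoff = 2)
  expect_gte(nrow(pk), 1L)
  expect_true(any(pk$start <= probes$pos[205] & pk$end > probes$pos[200]))
})

test_that("peak counting and relapse/diagnosis ratios work per sample", {
  set.seed(6)
  d <- cohort_design(n_pairs = 2, seed = 6)
  probes <- data.frame(chrom = "chr1", pos = seq(0, 49750, by = 250))
  base <- matrix(rnorm(200 * 4, 0, 0.3), 200, 4,
                 dimnames = list(NULL, c("P01_D", "P01_R", "P02_D", "P02_R")))
  base[50:53, "P01_R"] <- base[50:53, "P01_R"] + 3
  base[120:123, c("P02_D", "P02_R")] <-
    base[120:123, c("P02_D", "P02_R")] + 3
  cnt <- count_peaks(probes, base)
  expect_equal(cnt$n_peaks[cnt$sample == "P01_R"],
               cnt$n_peaks[cnt$sample == "P01_D"] + 1L)
  rat <- peak_ratio(cnt, d)
  expect_equal(rat$ratio[rat$pair_id == "P02"], 1)
})

test_that("DMR detection recovers planted regions and applies all filters", {
  d <- cohort_design(n_pairs = 10, seed = 3)
  g <- generate_genome(n_chrom = 2, chrom_length = 2e6, probe_spacing = 500,
                       n_genes = 10, seed = 3)
  base_args <- list(design = d, probes = g$meth_probes,
                    baseline_shape1 = 10, baseline_shape2 = 30,
                    batch_shift = 0, dmr_sign = 1)

  # zero noise: bounds exact, all planted found, p significant
  m0 <- do.call(simulate_methylation,
                c(base_args, list(n_dmrs = 8, dmr_probe_count = 6,
                                  dmr_delta = 0.2, noise_sd = 0)))
  dm0 <- detect_dmrs(m0$values, g$meth_probes, d, seed = 1)
  key <- function(x) sort(paste(x$chrom, x$start, x$end))
  expect_equal(key(dm0), key(m0$dmrs))
  expect_true(all(dm0$n_probes == 6L))
  expect_true(all(abs(dm0$mean_delta - 0.2) < 1e-9))
  expect_true(all(dm0$p.value < 0.05))
  expect_true(all(dm0$direction == "hyper"))

  # modest noise: all planted still found at p < 0.05
  m1 <- do.call(simulate_methylation,
                c(base_args, list(n_dmrs = 8, dmr_probe_count = 6,
                                  dmr_delta = 0.2, noise_sd = 0.05)))
  dm1 <- detect_dmrs(m1$values, g$meth_probes, d, seed = 1)
  found <- vapply(seq_len(nrow(m1$dmrs)), function(k) {
    any(dm1$chrom == m1$dmrs$chrom[k] & dm1$start < m1$dmrs$end[k] &
          dm1$end > m1$dmrs$start[k])
  }, logical(1))
  expect_true(all(found))
  expect_true(all(dm1$p.value < 0.05))

  # 3-probe regions always removed by the >=4-probe rule
  m3 <- do.call(simulate_methylation,
                c(base_args, list(n_dmrs = 8, dmr_probe_count = 3,
                                  dmr_delta = 0.3, noise_sd = 0)))
  expect_equal(nrow(detect_dmrs(m3$values, g$meth_probes, d, seed = 1)), 0L)

  # sub-threshold delta (2%) never reported
  m2 <- do.call(simulate_methylation,
                c(base_args, list(n_dmrs = 8, dmr_probe_count = 6,
                                  dmr_delta = 0.02, noise_sd = 0)))
  expect_equal(nrow(detect_dmrs(m2$values, g$meth_probes, d, seed = 1)), 0L)

  # relapse == diagnosis: no DMRs
  mm <- m0$values
  mm[, d$pairs$relapse] <- mm[, d$pairs$diagnosis]
  expect_equal(nrow(detect_dmrs(mm, g$meth_probes, d, seed = 1)), 0L)

  bad <- m0$values[, 1:3]
  expect_error(detect_dmrs(bad, g$meth_probes, d), "paired")
})

test_that("regions are assigned to the nearest TSS with a deterministic tie rule", {
  genes <- data.frame(gene = c("a", "b"), chrom = "chr1",
                      tss = c(1000, 5000))
  # midpoint at a TSS
  expect_equal(assign_region_to_gene(
    data.frame(chrom = "chr1", start = 900, end = 1100), genes), "a")
  # equidistant: lower coordinate wins
  expect_equal(assign_region_to_gene(
    data.frame(chrom = "chr1", start = 2900, end = 3100), genes), "a")
  # chromosome without genes
  expect_true(is.na(assign_region_to_gene(
    data.frame(chrom = "chrX", start = 0, end = 100), genes)))
  expect_error(assign_region_to_gene(
    data.frame(chrom = "chr1", start = 0, end = 1), genes[0, ]), "empty")
})

test_that("promoter windows are strand-aware and aggregation handles gaps", {
  genes <- data.frame(gene = c("plus", "minus"), chrom = "chr1",
                      strand = c("+", "-"), tss = c(10000, 10000))
  win <- promoter_windows(genes)
  expect_equal(win$promoter$start, c(8000, 10000))
  expect_equal(win$promoter$end, c(10000, 12000))
  expect_equal(win$core$start, c(9750, 9750))
  expect_equal(win$core$end, c(10250, 10250))

  probes <- data.frame(chrom = "chr1", pos = c(8100, 9900, 11000))
  vals <- matrix(c(0.1, 0.9, 0.5), 3, 2,
                 dimnames = list(NULL, c("s1", "s2")))
  ag <- promoter_aggregate(vals, probes, genes)
  expect_equal(unname(ag$promoter_mean["plus", "s1"]), 0.5) # mean(0.1, 0.9)
  expect_equal(unname(ag$promoter_max["plus", "s1"]), 0.9)
  expect_equal(unname(ag$promoter_mean["minus", "s1"]), 0.5) # probe at 11000
  expect_equal(unname(ag$core_mean["plus", "s1"]), 0.9)
  # no probes in the minus core beyond shared ones -> uses 9900 only
  expect_equal(unname(ag$core_mean["minus", "s1"]), 0.9)

  # genes with zero probes get NA
  far <- data.frame(gene = "far", chrom = "chr1", strand = "+", tss = 5e6)
  ag2 <- promoter_aggregate(vals, probes, far)
  expect_true(all(is.na(ag2$promoter_mean)))
})

test_that("promoter-level paired testing flags planted hypermethylation", {
  co <- simulate_cohort(n_pairs = 10, seed = 17, n_genes = 60,
                        n_meth_genes = 4, n_de_genes = 0,
                        dmr_delta = 0.3, meth_noise_sd = 0.02,
                        batch_shift = 0)
  ag <- promoter_aggregate(co$meth$values, co$genome$meth_probes,
                           co$genome$genes)
  res <- promoter_differential(ag$promoter_mean, co$design, seed = 1)
  flagged <- res$gene[res$q < 0.05]
  expect_true(all(co$truth$meth_genes %in% flagged))
  expect_lt(length(setdiff(flagged, co$truth$meth_genes)), 5)
  expect_error(promoter_differential(ag$promoter_mean,
                                     cohort_design(2, seed = 1)), "3 pairs")
})
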