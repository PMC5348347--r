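# End-to-end pipeline over the synthetic cohort: simulate -> copy number
# -> methylation -> expression -> integration -> meta-analysis, driven by
# a single (YAML-serializable) config, with per-stage record counts and a
# JSON run manifest for reproducibility.

#' Default pipeline configuration
#'
#' Every analysis threshold is a named key defaulting to its standard
#' value: call thresholds +-0.1 log2, 25 markers, 100 kb, 50% CNV
#' overlap, 100 Mb burden cutoff, peak width 750 bp / 2 probes / score 2,
#' DMR p < 0.05 / 5% / 4 probes, promoter -2000..0 and core +-250 bp,
#' fold-change rules 2.0 (>=5 pairs; >=3 pairs for the copy-number
#' screen) and 1.5 (>=3 pairs, methylation screen), q < 0.05, r > 0.8.
#'
#' @param seed master seed.
#' @param n_pairs cohort size in pairs.
#' @return nested named list of per-stage settings.
#' @export
default_config <- function(seed = 1L, n_pairs = 17L) {
  list(
    seed = as.integer(seed),
    cohort = list(n_pairs = as.integer(n_pairs), n_chrom = 2L,
                  chrom_length = 1e7, probe_spacing = 5000, n_genes = 120L,
                  n_meth_genes = 5L, n_de_genes = 5L, dmr_delta = 0.25,
                  de_log2fc = -1.5, cna_noise_sd = 0.1,
                  meth_noise_sd = 0.05, expr_noise_sd = 0.3,
                  batch_shift = 0.05, n_shared = 5L, n_acquired = 4L,
                  n_lost = 1L, segment_length_range = c(5e5, 3e6),
                  gain_log2 = 0.4, loss_log2 = -0.4, p_gain = 0.5),
    cna = list(gain_thresh = 0.1, loss_thresh = -0.1, min_markers = 25L,
               min_length = 1e5, max_cnv_overlap = 0.5,
               segment_penalty = 2, winsor_k = 2.5, burden_cutoff = 1e8),
    methylation = list(peak_width = 750, peak_min_probes = 2L,
                       peak_score_cutoff = 2, smooth_window = 3L,
                       max_gap = 1000, delta_cutoff = 0.05,
                       dmr_min_probes = 4L, dmr_p_cutoff = 0.05),
    expression = list(q_cutoff = 0.05, concordance_ratio_fc = 2,
                      concordance_min_pairs = 5L, n_permutations = 1000L),
    integration = list(cna_ratio_fc = 2, meth_ratio_fc = 1.5,
                       candidate_min_pairs = 3L, r_cutoff = 0.8,
                       fdr_cutoff = 0.05),
    meta = list(n_external_studies = 2L, external_n_pairs = 10L)
  )
}

#' Run the full pipeline on a synthetic cohort
#'
#' Simulates a paired cohort with planted truth, then runs copy-number
#' calling and burden classification, methylation normalization/batch
#' correction/DMR detection/promoter aggregation, paired differential
#' expression and fold-change rules, cross-platform association screens,
#' and a random-effects meta-analysis against additional simulated
#' external studies. Per-stage record counts are logged to stderr; when
#' `out_dir` is given, main tables and a JSON run manifest are written.
#'
#' @param config nested list from [default_config()] (partial overrides
#'   are merged over the defaults), or a path to a YAML file of the same
#'   shape.
#' @param out_dir optional output directory for TSV/BED/JSON artifacts.
#' @param quiet suppress stage logging.
#' @return list with all stage results (`cohort`, `cna`, `methylation`,
#'   `expression`, `integration`, `meta`, `manifest`).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(default_config(), config)
  .check_config(config)
  log <- function(stage, msg) {
    if (!quiet) message(sprintf("[%s] %s", stage, msg))
  }
  seed <- config$seed

  ## simulate
  co <- do.call(simulate_cohort, c(list(seed = seed), config$cohort))
  design <- co$design
  genome <- co$genome
  log("simulate", sprintf("%d pairs, %d cn probes, %d meth probes, %d genes",
                          design$n_pairs, nrow(genome$cn_probes),
                          nrow(genome$meth_probes), nrow(genome$genes)))

  ## copy number
  ccna <- config$cna
  params <- cna_call_params(ccna$gain_thresh, ccna$loss_thresh,
                            ccna$min_markers, ccna$min_length,
                            ccna$max_cnv_overlap)
  samples <- colnames(co$cna$values)
  profiles <- lapply(samples, function(s) {
    v <- winsorize(co$cna$values[, s], k = ccna$winsor_k,
                   chrom = genome$cn_probes$chrom)
    segs <- segment_genome(data.frame(genome$cn_probes, value = v),
                           penalty = ccna$segment_penalty)
    cna_profile(call_cnas(segs, params), sample_id = s,
                cutoff = ccna$burden_cutoff)
  })
  names(profiles) <- samples
  evolutions <- lapply(seq_len(design$n_pairs), function(k) {
    compare_pair(profiles[[design$pairs$diagnosis[k]]]$calls,
                 profiles[[design$pairs$relapse[k]]]$calls)
  })
  names(evolutions) <- design$pairs$pair_id
  burden <- vapply(profiles[design$pairs$relapse],
                   function(p) p$burden_class, character(1))
  names(burden) <- design$pairs$pair_id
  stats <- count_stats(profiles[design$pairs$diagnosis],
                       profiles[design$pairs$relapse])
  log("cna", sprintf("%d calls total; burden large=%d small=%d",
                     sum(vapply(profiles, function(p) nrow(p$calls), 1L)),
                     sum(burden == "large"), sum(burden == "small")))

  ## methylation
  cm <- config$methylation
  frac <- co$meth$values
  lr <- meth_fraction_to_log2(pmin(pmax(frac, 1e-4), 1 - 1e-4))
  lr <- quantile_normalize(lr)
  sheet <- design_sample_sheet(design)
  lr <- batch_correct(lr, sheet$batch[match(colnames(lr), sheet$sample_id)])
  frac_corr <- meth_log2_to_fraction(lr)
  dmrs <- detect_dmrs(frac_corr, genome$meth_probes, design,
                      smooth_window = cm$smooth_window,
                      max_gap = cm$max_gap,
                      delta_cutoff = cm$delta_cutoff,
                      min_probes = cm$dmr_min_probes,
                      p_cutoff = cm$dmr_p_cutoff, seed = seed)
  if (nrow(dmrs)) dmrs$gene <- assign_region_to_gene(dmrs, genome$genes)
  peaks <- count_peaks(genome$meth_probes, lr, width = cm$peak_width,
                       min_probes = cm$peak_min_probes,
                       score_cutoff = cm$peak_score_cutoff)
  prom <- promoter_aggregate(frac_corr, genome$meth_probes, genome$genes)
  prom_diff <- promoter_differential(prom$promoter_mean, design, seed = seed)
  log("methylation", sprintf("%d DMRs; %d genes in promoter test",
                             nrow(dmrs), nrow(prom_diff)))

  ## expression
  ce <- config$expression
  expr <- low_expression_filter(co$expr$values)
  sam <- sam_paired(expr, design, n_permutations = ce$n_permutations,
                    seed = seed)
  fc <- fold_changes(expr, design)
  conc <- concordance_filter(fc, min_ratio_fc = ce$concordance_ratio_fc,
                             min_pairs = ce$concordance_min_pairs)
  clust <- hierarchical_cluster(expr)
  mds_xy <- run_mds(expr)
  log("expression", sprintf("%d genes; %d DEG (q<%.2f); %d up / %d down",
                            nrow(expr), sum(sam$q < ce$q_cutoff),
                            ce$q_cutoff, length(conc$up),
                            length(conc$down)))

  ## integration
  ci <- config$integration
  cna_delta <- gene_cna_delta(co$cna$values, genome$cn_probes,
                              genome$genes, design)
  cand_cna <- select_candidates(fc, min_ratio_fc = ci$cna_ratio_fc,
                                min_pairs = ci$candidate_min_pairs)
  assoc_cna <- correlate_fc(fc, cna_delta, genes = cand_cna,
                            sign_filter = "positive",
                            r_cutoff = ci$r_cutoff,
                            fdr_cutoff = ci$fdr_cutoff)
  meth_fc <- fold_changes(prom$promoter_mean, design)
  cand_meth <- select_candidates(fc, min_ratio_fc = ci$meth_ratio_fc,
                                 min_pairs = ci$candidate_min_pairs)
  assoc_meth <- correlate_fc(fc, meth_fc, genes = cand_meth,
                             sign_filter = "negative",
                             r_cutoff = ci$r_cutoff,
                             fdr_cutoff = ci$fdr_cutoff)
  inverse <- if (nrow(dmrs)) {
    dmr_deg_intersect(dmrs, fc, min_ratio_fc = ci$meth_ratio_fc,
                      min_pairs = ci$candidate_min_pairs)
  } else {
    data.frame(gene = character(), direction = character(),
               n_pairs_expression = integer())
  }
  strat <- burden_stratified_de(expr, design, burden, seed = seed)
  log("integration",
      sprintf("%d CNA-assoc, %d meth-assoc, %d inverse DMR/DEG",
              sum(assoc_cna$significant), sum(assoc_meth$significant),
              nrow(inverse)))

  ## meta-analysis (external studies simulated at distinct seeds)
  cmeta <- config$meta
  studies <- list(study_summary(
    expr, sheet$timepoint[match(colnames(expr), sheet$sample_id)],
    study = "cohort"))
  for (i in seq_len(cmeta$n_external_studies)) {
    ext <- simulate_cohort(n_pairs = cmeta$external_n_pairs,
                           seed = seed + 1000L * i,
                           n_chrom = config$cohort$n_chrom,
                           chrom_length = config$cohort$chrom_length,
                           probe_spacing = config$cohort$probe_spacing,
                           n_genes = config$cohort$n_genes,
                           de_genes = co$truth$de_genes,
                           de_log2fc = config$cohort$de_log2fc)
    esheet <- design_sample_sheet(ext$design)
    studies[[i + 1L]] <- study_summary(
      ext$expr$values,
      esheet$timepoint[match(colnames(ext$expr$values), esheet$sample_id)],
      study = paste0("external", i))
  }
  # meta-analyze the genes the cohort flagged as relapse-deregulated,
  # restricted to genes measured in every study
  common <- Reduce(intersect, lapply(studies, function(s) s$gene))
  ranked <- sam$gene[order(sam$q)]
  meta_genes <- utils::head(ranked[ranked %in% common], 10L)
  meta <- meta_analyze(studies, genes = meta_genes)
  trend <- negative_trend_check(meta)
  log("meta", sprintf("%d genes pooled; %d with negative trend",
                      length(meta), sum(trend$flagged)))

  manifest <- list(
    package_version = as.character(utils::packageVersion("pairomics")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    stage_counts = list(
      cn_probes = nrow(genome$cn_probes),
      meth_probes = nrow(genome$meth_probes),
      genes = nrow(genome$genes),
      cna_calls = sum(vapply(profiles, function(p) nrow(p$calls), 1L)),
      dmrs = nrow(dmrs),
      deg = sum(sam$q < ce$q_cutoff),
      meta_genes = length(meta)))

  res <- list(cohort = co, cna = list(profiles = profiles,
                                      evolutions = evolutions,
                                      burden = burden, stats = stats),
              methylation = list(values_log2 = lr, dmrs = dmrs,
                                 peaks = peaks, promoter = prom,
                                 promoter_sam = prom_diff),
              expression = list(matrix = expr, sam = sam, fc = fc,
                                concordant = conc, clusters = clust,
                                mds = mds_xy),
              integration = list(cna_assoc = assoc_cna,
                                 meth_assoc = assoc_meth,
                                 inverse = inverse, stratified = strat),
              meta = list(results = meta, trend = trend),
              manifest = manifest)
  if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir)
  res
}

.check_config <- function(config) {
  known <- names(default_config())
  extra <- setdiff(names(config), known)
  if (length(extra)) {
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  }
  for (sec in setdiff(known, "seed")) {
    extra <- setdiff(names(config[[sec]]), names(default_config()[[sec]]))
    if (length(extra)) {
      stop("unknown config key(s) in '", sec, "': ",
           paste(extra, collapse = ", "))
    }
  }
  invisible(TRUE)
}

.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  segs <- do.call(rbind, lapply(res$cna$profiles, function(p) {
    if (nrow(p$calls) == 0L) return(NULL)
    data.frame(sample = p$sample_id,
               p$calls[, c("chrom", "start", "end", "mean_log2",
                           "n_markers", "state")],
               stringsAsFactors = FALSE)
  }))
  if (!is.null(segs)) write_seg(segs, file.path(out_dir, "cna_calls.seg"))
  if (nrow(res$methylation$dmrs)) {
    write_bed(res$methylation$dmrs, file.path(out_dir, "dmrs.bed"))
  }
  utils::write.table(res$expression$sam, file.path(out_dir, "sam.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix(res$expression$fc, file.path(out_dir, "fold_changes.tsv"),
               key = "gene")
  utils::write.table(res$integration$cna_assoc,
                     file.path(out_dir, "cna_expression_assoc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
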