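# Shared synthetic fixtures (used by the integration and acceptance
# suites): a 16-pair cohort with planted dosage and methylation-repressed
# genes at configurable expression noise.

make_dosage_fixture <- function(expr_noise_sd, seed = 77) {
  simulate_cohort(n_pairs = 16, seed = seed, n_chrom = 2,
                  chrom_length = 1e7, probe_spacing = 5000,
                  n_genes = 80, n_meth_genes = 4, n_de_genes = 0,
                  dmr_delta = 0.3, cna_noise_sd = 0,
                  meth_noise_sd = 0, expr_noise_sd = expr_noise_sd,
                  batch_shift = 0, n_shared = 3, n_acquired = 4,
                  n_lost = 1, gain_log2 = 0.5, loss_log2 = -0.5)
}

# planted dosage genes whose copy state actually differs between the two
# timepoints in at least one pair (the testable set: the rest have a
# constant zero delta across pairs)
evolving_dosage_genes <- function(co) {
  tr <- co$cna$truth[co$cna$truth$origin %in% c("acquired", "lost"), ]
  ann <- co$genome$genes
  hits <- unique(unlist(lapply(seq_len(nrow(tr)), function(i) {
    ann$gene[ann$chrom == tr$chrom[i] & ann$start >= tr$start[i] &
               ann$end <= tr$end[i]]
  })))
  intersect(hits, co$truth$dosage_genes)
}
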