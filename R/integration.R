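# Cross-platform association of paired changes: gene-level copy-number
# differences vs expression fold changes, promoter-methylation changes vs
# expression, DMR/DEG intersection, burden-stratified differential
# expression, pair-by-pair co-occurrence and a region-wise random-
# intercept association screen.

#' Gene-level copy-number change per pair
#'
#' For each gene and pair, the difference of the probe-weighted mean log2
#' ratio over the gene span between relapse and diagnosis. Genes whose
#' span contains no probe get NA.
#'
#' @param values copy-number probes x samples matrix.
#' @param probes probe data.frame (`chrom`, `pos`).
#' @param genes annotation (`gene`, `chrom`, `start`, `end`).
#' @param design a [cohort_design()].
#' @return genes x pairs matrix of log2-ratio differences.
#' @export
gene_cna_delta <- function(values, probes, genes, design) {
  p <- design$pairs
  win <- data.frame(gene = genes$gene, chrom = genes$chrom,
                    start = genes$start, end = genes$end,
                    stringsAsFactors = FALSE)
  gv <- .aggregate_probes(values, probes, win, "mean")
  delta <- gv[, p$relapse, drop = FALSE] - gv[, p$diagnosis, drop = FALSE]
  colnames(delta) <- p$pair_id
  delta
}

#' Correlate expression fold changes with a platform change across pairs
#'
#' Per gene, the Pearson correlation across pairs between the expression
#' log2 fold change and the platform change (copy-number delta or
#' methylation fold change), with two-sided p-values and Benjamini-
#' Hochberg FDR across the tested genes. Genes with a zero-variance
#' vector are skipped and flagged (`r` = NA). The reporting rule
#' |r| > `r_cutoff` AND FDR < `fdr_cutoff`, optionally restricted to one
#' correlation sign, is returned as a logical flag.
#'
#' @param expr_fc genes x pairs expression log2 fold-change matrix.
#' @param platform_delta genes x pairs platform-change matrix (same pair
#'   columns).
#' @param genes optional gene subset to test (default: common rownames).
#' @param sign_filter "any", "positive" or "negative".
#' @param r_cutoff reported-correlation threshold (default 0.8).
#' @param fdr_cutoff FDR threshold (default 0.05).
#' @return data.frame: `gene`, `r`, `p.value`, `fdr`, `significant`.
#' @export
correlate_fc <- function(expr_fc, platform_delta, genes = NULL,
                         sign_filter = c("any", "positive", "negative"),
                         r_cutoff = 0.8, fdr_cutoff = 0.05) {
  sign_filter <- match.arg(sign_filter)
  if (is.null(genes)) {
    genes <- intersect(rownames(expr_fc), rownames(platform_delta))
  }
  rows <- lapply(genes, function(g) {
    x <- expr_fc[g, ]
    y <- platform_delta[g, ]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L) {
      return(data.frame(gene = g, r = NA_real_, p.value = NA_real_,
                        stringsAsFactors = FALSE))
    }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(data.frame(gene = g, r = NA_real_, p.value = NA_real_,
                        stringsAsFactors = FALSE)) # zero variance: skipped
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(gene = g, r = unname(ct$estimate), p.value = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tested <- !is.na(out$p.value)
  out$fdr <- NA_real_
  out$fdr[tested] <- stats::p.adjust(out$p.value[tested], method = "BH")
  dir_ok <- switch(sign_filter,
                   any = rep(TRUE, nrow(out)),
                   positive = out$r > 0,
                   negative = out$r < 0)
  out$significant <- tested & dir_ok & abs(out$r) > r_cutoff &
    out$fdr < fdr_cutoff
  out$significant[is.na(out$significant)] <- FALSE
  rownames(out) <- NULL
  out
}

#' Inverse DMR/expression associations
#'
#' Genes with a hypermethylated DMR whose expression drops at least
#' `min_ratio_fc`-fold in at least `min_pairs` pairs, or a hypomethylated
#' DMR with the mirror-image expression increase.
#'
#' @param dmrs DMR data.frame from [detect_dmrs()] with a `gene` column
#'   (e.g. from [assign_region_to_gene()]).
#' @param fc genes x pairs expression log2 fold-change matrix.
#' @param min_ratio_fc ratio threshold (default 1.5).
#' @param min_pairs minimum supporting pairs (default 3).
#' @return data.frame of inverse associations: `gene`, `direction`,
#'   `n_pairs_expression`.
#' @export
dmr_deg_intersect <- function(dmrs, fc, min_ratio_fc = 1.5, min_pairs = 3L) {
  stopifnot("gene" %in% names(dmrs))
  t <- log2(min_ratio_fc)
  rows <- lapply(seq_len(nrow(dmrs)), function(i) {
    g <- dmrs$gene[i]
    if (is.na(g) || !(g %in% rownames(fc))) return(NULL)
    if (dmrs$direction[i] == "hyper") {
      k <- sum(fc[g, ] <= -t)
    } else {
      k <- sum(fc[g, ] >= t)
    }
    if (k < min_pairs) return(NULL)
    data.frame(gene = g, direction = dmrs$direction[i],
               n_pairs_expression = k, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(gene = character(), direction = character(),
                      n_pairs_expression = integer()))
  }
  out <- out[!duplicated(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Differential expression stratified by genomic burden
#'
#' Runs [sam_paired()] separately within the pairs whose relapse sample
#' carries "large" and "small" total DNA change; strata with fewer than 3
#' pairs are skipped with a note.
#'
#' @param x genes x samples expression matrix.
#' @param design a [cohort_design()].
#' @param burden named character vector of "small"/"large" per pair id.
#' @param q_cutoff DEG threshold on the SAM q-value (default 0.05).
#' @param ... passed to [sam_paired()].
#' @return list with per-stratum entries: `result` (SAM table or NULL),
#'   `n_pairs`, `n_deg`, `skipped`.
#' @export
burden_stratified_de <- function(x, design, burden, q_cutoff = 0.05, ...) {
  p <- design$pairs
  stopifnot(all(p$pair_id %in% names(burden)))
  out <- list()
  for (cls in c("small", "large")) {
    sel <- p[burden[p$pair_id] == cls, , drop = FALSE]
    if (nrow(sel) < 3L) {
      out[[cls]] <- list(result = NULL, n_pairs = nrow(sel), n_deg = NA,
                         skipped = TRUE)
      next
    }
    res <- sam_paired(x, sel, ...)
    out[[cls]] <- list(result = res, n_pairs = nrow(sel),
                       n_deg = sum(res$q < q_cutoff), skipped = FALSE)
  }
  out
}

#' Pair-by-pair co-occurrence of expression and platform changes
#'
#' Per gene, counts the pairs where the expression log2 fold change is at
#' least `expr_log2_cutoff` in magnitude AND the same pair's platform
#' change exceeds its threshold with the required sign relation
#' ("same" for copy-number dosage, "opposite" for methylation
#' repression). Genes supported by at least `min_supporting_pairs` pairs
#' are reported.
#'
#' @param expr_fc genes x pairs expression log2 fold-change matrix.
#' @param platform_delta genes x pairs platform-change matrix.
#' @param platform_cutoff magnitude threshold on the platform change
#'   (0.1 for copy-number log2 deltas, 0.05 for methylation fractions).
#' @param expr_log2_cutoff expression magnitude threshold (default 1,
#'   i.e. 2-fold).
#' @param sign_relation "same" or "opposite".
#' @param min_supporting_pairs report threshold (default 3).
#' @return data.frame: `gene`, `n_supporting`.
#' @export
pairwise_association <- function(expr_fc, platform_delta,
                                 platform_cutoff = 0.1,
                                 expr_log2_cutoff = 1,
                                 sign_relation = c("same", "opposite"),
                                 min_supporting_pairs = 3L) {
  sign_relation <- match.arg(sign_relation)
  genes <- intersect(rownames(expr_fc), rownames(platform_delta))
  counts <- vapply(genes, function(g) {
    x <- expr_fc[g, ]
    y <- platform_delta[g, ]
    ok <- is.finite(x) & is.finite(y) &
      abs(x) >= expr_log2_cutoff & abs(y) >= platform_cutoff
    rel <- if (sign_relation == "same") sign(x) == sign(y) else
      sign(x) == -sign(y)
    sum(ok & rel)
  }, numeric(1))
  out <- data.frame(gene = genes, n_supporting = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[out$n_supporting >= min_supporting_pairs, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Region-wise random-intercept association screen (SIM surrogate)
#'
#' A simplified surrogate for region-level integrated association
#' analysis: within each region (typically a chromosome), a pair-level
#' random intercept — the region-average expression fold change of each
#' pair, shrunk by a method-of-moments factor — is removed from the
#' expression fold changes before the per-gene Pearson association with
#' the platform change; FDR is computed across genes within each region.
#' Results are labelled "SIM-surrogate": this is not the published SIM
#' algorithm.
#'
#' @param expr_fc genes x pairs expression log2 fold-change matrix.
#' @param platform_delta genes x pairs platform-change matrix.
#' @param regions named character vector: region (e.g. chromosome) per
#'   gene.
#' @param min_genes minimum genes per region (default 3; smaller regions
#'   are skipped).
#' @return data.frame: `gene`, `region`, `r`, `p.value`, `fdr`,
#'   `method` = "SIM-surrogate".
#' @export
regionwise_random_effects <- function(expr_fc, platform_delta, regions,
                                      min_genes = 3L) {
  genes <- intersect(intersect(rownames(expr_fc), rownames(platform_delta)),
                     names(regions))
  out <- NULL
  for (rg in unique(regions[genes])) {
    gset <- genes[regions[genes] == rg]
    if (length(gset) < min_genes) next
    X <- expr_fc[gset, , drop = FALSE]
    # method-of-moments random intercept per pair: shrink the region-mean
    # fold change toward 0 by its estimated reliability
    b <- colMeans(X)
    sigma2_e <- mean(apply(sweep(X, 2, b), 1, stats::var))
    var_b <- stats::var(b)
    lambda <- if (var_b > 0) {
      max(0, 1 - (sigma2_e / length(gset)) / var_b)
    } else 0
    Xadj <- sweep(X, 2, lambda * b)
    rows <- lapply(gset, function(g) {
      y <- platform_delta[g, ]
      x <- Xadj[g, ]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3L || stats::sd(y[ok]) == 0 || stats::sd(x[ok]) == 0) {
        return(NULL) # constant within region: skipped
      }
      ct <- stats::cor.test(x[ok], y[ok])
      data.frame(gene = g, region = rg, r = unname(ct$estimate),
                 p.value = ct$p.value, stringsAsFactors = FALSE)
    })
    reg <- do.call(rbind, rows)
    if (is.null(reg)) next
    reg$fdr <- stats::p.adjust(reg$p.value, method = "BH")
    out <- rbind(out, reg)
  }
  if (is.null(out)) {
    return(data.frame(gene = character(), region = character(),
                      r = numeric(), p.value = numeric(), fdr = numeric(),
                      method = character()))
  }
  out$method <- "SIM-surrogate"
  rownames(out) <- NULL
  out
}
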