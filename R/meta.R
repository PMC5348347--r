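# Random-effects meta-analysis of gene expression across studies:
# Hedges' g standardized mean differences, Cochran's Q, I-squared,
# DerSimonian-Laird pooling with z-test and forest-plot tables.

#' Hedges' g standardized mean difference
#'
#' Bias-corrected standardized mean difference between two groups:
#' pooled SD `s_p = sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1+n2-2))`,
#' `d = (mean2 - mean1)/s_p`, small-sample correction
#' `J = 1 - 3/(4 (n1+n2-2) - 1)`, `g = J d`, sampling variance
#' `v = (n1+n2)/(n1 n2) + g^2 / (2 (n1+n2))`. Vectorized.
#'
#' @param n1,n2 group sizes (>= 2).
#' @param mean1,mean2 group means.
#' @param sd1,sd2 group standard deviations.
#' @return list with `g` and `v`.
#' @export
hedges_g <- function(n1, n2, mean1, mean2, sd1, sd2) {
  stopifnot(all(n1 >= 2), all(n2 >= 2), all(sd1 >= 0), all(sd2 >= 0))
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  if (any(sp == 0)) stop("hedges_g: pooled SD is zero, effect undefined")
  d <- (mean2 - mean1) / sp
  J <- 1 - 3 / (4 * df - 1)
  g <- J * d
  v <- (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2))
  list(g = g, v = v)
}

#' Cochran's Q heterogeneity test
#'
#' Fixed-effect weights `w_i = 1/v_i`, weighted mean effect, and
#' `Q = sum w_i (g_i - gbar)^2`, referred to a chi-square with k-1
#' degrees of freedom.
#'
#' @param g per-study effects.
#' @param v per-study variances (> 0).
#' @return list with `Q`, `df`, `p.value`.
#' @export
cochran_q <- function(g, v) {
  if (length(g) < 2L) stop("cochran_q: need at least 2 studies")
  if (any(v <= 0)) stop("cochran_q: variances must be positive")
  w <- 1 / v
  gbar <- sum(w * g) / sum(w)
  Q <- sum(w * (g - gbar)^2)
  df <- length(g) - 1L
  list(Q = Q, df = df, p.value = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' I-squared heterogeneity percentage
#'
#' `I2 = max(0, (Q - df)/Q) * 100`; 0 when Q is 0.
#'
#' @param Q Cochran's Q.
#' @param df degrees of freedom (k - 1, >= 1).
#' @return percentage in [0, 100].
#' @export
i_squared <- function(Q, df) {
  stopifnot(df >= 1)
  if (Q <= 0) return(0)
  max(0, (Q - df) / Q) * 100
}

#' DerSimonian-Laird random-effects pooling
#'
#' Method-of-moments between-study variance
#' `tau2 = max(0, (Q - df)/C)` with `C = sum(w) - sum(w^2)/sum(w)`,
#' `w = 1/v`; random-effects weights `w* = 1/(v + tau2)`; pooled effect,
#' its standard error `1/sqrt(sum w*)`, normal 95% CI, z statistic and
#' two-sided p-value. When the studies are homogeneous (Q <= df) the
#' result reduces exactly to fixed-effect inverse-variance pooling. The
#' heterogeneity flag follows the Q p < 0.05 AND I2 > 50% convention.
#'
#' @param g per-study effects.
#' @param v per-study variances.
#' @return list: `k`, `g`, `v`, `Q`, `df`, `Q_p`, `I2`, `tau2`,
#'   `weights` (normalized to sum 1), `pooled`, `se`, `ci_lower`,
#'   `ci_upper`, `z`, `p.value`, `heterogeneous`.
#' @export
dl_pool <- function(g, v) {
  qres <- cochran_q(g, v)
  w <- 1 / v
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (qres$Q - qres$df) / C)
  wstar <- 1 / (v + tau2)
  pooled <- sum(wstar * g) / sum(wstar)
  se <- 1 / sqrt(sum(wstar))
  I2 <- i_squared(qres$Q, qres$df)
  z <- pooled / se
  list(k = length(g), g = g, v = v, Q = qres$Q, df = qres$df,
       Q_p = qres$p.value, I2 = I2, tau2 = tau2,
       weights = wstar / sum(wstar), pooled = pooled, se = se,
       ci_lower = pooled - 1.96 * se, ci_upper = pooled + 1.96 * se,
       z = z, p.value = 2 * stats::pnorm(-abs(z)),
       heterogeneous = qres$p.value < 0.05 && I2 > 50)
}

#' Per-gene study summaries from an expression matrix
#'
#' Unpaired diagnosis-vs-relapse group summaries (n, mean, sd per group)
#' for each gene, the input to [hedges_g()].
#'
#' @param x genes x samples log2 matrix.
#' @param timepoint character vector per column: "diagnosis"/"relapse".
#' @param study study label stamped on the output.
#' @return data.frame: `study`, `gene`, `n1`, `mean1`, `sd1` (diagnosis),
#'   `n2`, `mean2`, `sd2` (relapse).
#' @export
study_summary <- function(x, timepoint, study = "study") {
  stopifnot(length(timepoint) == ncol(x),
            all(timepoint %in% c("diagnosis", "relapse")))
  d <- x[, timepoint == "diagnosis", drop = FALSE]
  r <- x[, timepoint == "relapse", drop = FALSE]
  data.frame(
    study = study, gene = rownames(x),
    n1 = ncol(d), mean1 = rowMeans(d), sd1 = apply(d, 1, stats::sd),
    n2 = ncol(r), mean2 = rowMeans(r), sd2 = apply(r, 1, stats::sd),
    stringsAsFactors = FALSE)
}

#' Random-effects meta-analysis of genes across studies
#'
#' Computes Hedges' g per study and gene, then DerSimonian-Laird pooling
#' per gene across studies.
#'
#' @param summaries list of [study_summary()] data.frames.
#' @param genes genes to analyze (default: those present in every study).
#' @return named list of [dl_pool()] results, one per gene.
#' @export
meta_analyze <- function(summaries, genes = NULL) {
  if (length(summaries) < 2L) stop("need at least 2 studies")
  if (is.null(genes)) {
    genes <- Reduce(intersect, lapply(summaries, function(s) s$gene))
  }
  labels <- vapply(summaries, function(s) s$study[1], character(1))
  out <- lapply(genes, function(gn) {
    eff <- lapply(summaries, function(s) {
      row <- s[s$gene == gn, , drop = FALSE]
      if (nrow(row) == 0L) return(NULL)
      hg <- hedges_g(row$n1, row$n2, row$mean1, row$mean2, row$sd1, row$sd2)
      c(g = hg$g, v = hg$v)
    })
    present <- !vapply(eff, is.null, logical(1))
    if (sum(present) < 2L) return(NULL) # not poolable across studies
    eff <- do.call(rbind, eff[present])
    res <- dl_pool(eff[, "g"], eff[, "v"])
    res$studies <- labels[present]
    res
  })
  names(out) <- genes
  dropped <- vapply(out, is.null, logical(1))
  if (any(dropped)) {
    warning(sum(dropped), " gene(s) present in fewer than 2 studies ",
            "were dropped")
  }
  out[!dropped]
}

#' Forest-plot table for one pooled gene
#'
#' Per-study rows with effect, 95% CI and percent weight (summing to 100
#' within rounding), plus the pooled random-effects row.
#'
#' @param pool a [dl_pool()] result.
#' @param study_labels optional study names.
#' @return data.frame: `study`, `g`, `ci_lower`, `ci_upper`,
#'   `weight_pct`.
#' @export
forest_table <- function(pool, study_labels = NULL) {
  k <- pool$k
  if (is.null(study_labels)) {
    study_labels <- if (!is.null(pool$studies)) pool$studies else
      paste0("study", seq_len(k))
  }
  se_i <- sqrt(pool$v)
  out <- data.frame(
    study = c(study_labels, "pooled"),
    g = c(pool$g, pool$pooled),
    ci_lower = c(pool$g - 1.96 * se_i, pool$ci_lower),
    ci_upper = c(pool$g + 1.96 * se_i, pool$ci_upper),
    weight_pct = c(100 * pool$weights, 100),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Genes with a pooled negative expression trend
#'
#' Flags genes whose pooled random-effects g is below zero with z-test
#' p < `alpha` (consistent underexpression in the second condition).
#'
#' @param results named list of [dl_pool()] results (see
#'   [meta_analyze()]).
#' @param alpha significance level (default 0.05).
#' @return data.frame: `gene`, `pooled_g`, `z`, `p.value`, `flagged`.
#' @export
negative_trend_check <- function(results, alpha = 0.05) {
  out <- data.frame(
    gene = names(results),
    pooled_g = vapply(results, function(r) r$pooled, numeric(1)),
    z = vapply(results, function(r) r$z, numeric(1)),
    p.value = vapply(results, function(r) r$p.value, numeric(1)),
    stringsAsFactors = FALSE)
  out$flagged <- out$pooled_g < 0 & out$p.value < alpha
  rownames(out) <- NULL
  out
}
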