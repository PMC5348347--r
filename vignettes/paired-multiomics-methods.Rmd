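---
title: "Methods: paired multi-omics analysis of two-timepoint tumor cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired multi-omics analysis of two-timepoint tumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairomics)
```

This vignette documents the statistical procedures implemented in
`pairomics`, the assumptions behind them, the parameters that matter, and
the design choices made where several reasonable options existed. The
setting throughout is a cohort of patients sampled at two timepoints
(called diagnosis and relapse here), profiled on copy-number,
DNA-methylation and gene-expression microarrays, with samples paired
within patients.

## Coordinates and formats

All internal coordinates are 0-based half-open, the BED convention.
SEG-format segment tables are 1-based inclusive on disk and converted on
read/write (`read_seg()`/`write_seg()`). This keeps interval lengths equal
to `end - start` everywhere internally and confines dialect differences to
the I/O layer.

## Copy number

**Winsorization.** Probe log2 ratios are clipped to
`median ± k · MAD` per chromosome, `k = 2.5` by default, with the MAD
scaled by 1.4826. When the MAD is zero there is no robust scale to clip
against and the vector is returned unchanged; this degenerate case arises
only in noise-free synthetic data.

**Segmentation.** We fit a piecewise-constant signal by exactly
minimizing `Σᵢ (xᵢ − μ_seg(i))² + λ · #breakpoints` with an O(n²) dynamic
program. An exact minimizer (rather than a heuristic changepoint search)
was chosen deliberately: it makes the segmentation testable against
exhaustive enumeration on small instances, and its single tuning constant
λ has a transparent meaning (the squared-error cost a breakpoint must
recoup). The default λ = 2 segments the zero-noise fixtures exactly and is
exposed in the pipeline config. For a typical chromosome of 2000 probes
the fit takes well under a second.

**CNA calling.** A segment is reported as a copy-number aberration when
all of: `mean log2 > 0.1` (gain) or `< −0.1` (loss); `≥ 25` markers;
`≥ 100 kb`; and `< 50%` of its length overlapping a known-CNV mask. All
four constants are exposed (`cna_call_params()`).

**Paired lesion evolution.** Within a pair, gains and losses are compared
separately. A relapse call is *acquired* when less than 50% of its length
is covered by same-state diagnosis calls, and symmetrically for *lost*
lesions; the 50% reciprocal-overlap rule is a package choice — visual
inspection of paired profiles does not yield a numeric rule — and is a
parameter of `compare_pair()`.

**Burden.** The total DNA changed per sample is the length of the union
of its call intervals (overlapping gained and lost intervals counted
once: the union, not the sum, is used, because a locus both gained and
lost across subclones is still one changed locus). Samples with more than
100 Mb changed are classed "large", the rest "small". The classification
is invariant to how calls are split or merged as long as their union is
unchanged.

**Count statistics.** Per-sample counts of imbalances, gains and losses
are compared between the diagnosis and relapse groups with a two-sided
Mann–Whitney U test; the exact null distribution is used when both groups
have ≤ 8 samples and there are no ties, the normal approximation with
continuity correction otherwise. Two-sided is the default because no
directional hypothesis is imposed a priori.

**Recurrent acquisition.** Per genomic bin and state, we count the pairs
whose acquired lesions overlap the bin. The null distribution preserves
each pair's acquired-lesion lengths and re-places them uniformly on the
genome (1000 permutations by default), and bins are corrected with
Benjamini–Hochberg. Length-preserving placement was chosen because
lesion length, not only count, drives how many bins a pair can hit.

## Methylation

Three workflows operate on probe-level values.

**Normalization and batch correction.** Quantile normalization forces
every sample onto the common reference distribution (the row-wise mean of
sorted columns), via `limma::normalizeQuantiles`. Batch correction is the
parametric empirical-Bayes location/scale adjustment (ComBat, via `sva`);
a per-batch mean-centering fallback that preserves the grand mean is used
when any batch has fewer than 2 samples. A batch perfectly confounded
with the biological condition triggers a warning, since correction would
then remove the signal. Both operate on the log2-ratio scale
`x = log2(m/(1−m))`, a bijection of the fraction scale on (0,1); region
thresholds are stated on the fraction ("percentage") scale.

**Peak counting.** Scanner-software peak scores are proprietary, so the
probe score is defined here as −log10 of the one-sided rank-sum
(normal-approximation) p-value of the probes within 750 bp of the probe
against the sample's global value distribution; the default cutoff 2
corresponds to p < 0.01. This is a documented stand-in with the same
interface (width 750 bp, ≥ 2 probes per peak, score ≥ 2) and is fully
configurable. Peaks are maximal runs of qualifying probes with
consecutive qualifying probes within the window width; disjoint peaks are
counted per sample and per chromosome, and relapse/diagnosis count ratios
are reported per pair. Counts are invariant to adding probes below the
cutoff.

**DMR detection.** The per-probe mean paired difference (relapse −
diagnosis, fraction scale) is smoothed by a centered running mean over 3
probes, with smoothing runs broken at inter-probe gaps over 1 kb.
Candidate regions are maximal same-sign runs with |smoothed difference| >
0.05 (5 percentage points). Because a running mean blurs sharp edges by
up to a window width, region flanks whose *raw* mean difference does not
itself exceed the cutoff are trimmed; at zero noise this recovers planted
region bounds exactly. Regions with fewer than 4 probes are removed.
Significance uses sign-flip permutations of the pair labels with the area
statistic (sum of smoothed differences over the region): all 2ⁿ flips for
n ≤ 10 pairs, 1000 random flips otherwise; regions with p < 0.05 are
reported. The smoothing here is a running mean rather than a loess fit;
the span/gap defaults are package choices, exposed as parameters.
The "> 5% average methylation difference" rule is interpreted as
|mean paired difference| > 0.05 on the fraction scale — the most
plausible reading of a percentage-unit threshold on paired arrays.

**Promoter windows.** The promoter is the 2000 bp upstream of the TSS
(strand-aware: `[tss−2000, tss)` on "+", `[tss, tss+2000)` on "−"); the
core promoter is ±250 bp around the TSS (symmetric, hence identical for
both strands). Gene-level values are the mean or the maximum over probes
in the window; genes with no probe in a window are excluded (NA). For
gene-level paired testing, the least-variable 50% of genes is removed
first, then the SAM paired statistic is applied; regions are assigned to
the gene with the nearest TSS (ties broken toward the smaller
coordinate, deterministically).

## Expression

**Filtering.** The low-expression filter retains genes above a floor in a
minimum number of samples. No numeric floor is canonical for this filter,
so the defaults derive from the data: the 25th percentile of the value
distribution, required in ≥ 25% of samples. The variance filter removes
the fraction (default half) of genes with the lowest variance, ties
broken by gene id for determinism.

**SAM two-class paired.** For gene g with per-pair differences
`z₁..zₙ`: `z̄ = mean(z)`, `s = sd(z)/√n`, and `d = z̄/(s + s₀)`. The fudge
factor s₀ is chosen from the percentile grid {0, 5, …, 100} of the s
values as the candidate minimizing the coefficient of variation of the
median |d| across s-quantile bins (the Tusher procedure); candidates of 0
are excluded when any gene has zero spread, so d is always defined. The
null distribution of d comes from sign-flip permutations of the pair
labels — all 2ⁿ when n ≤ 10, otherwise 1000 seeded random flips. The
q-value of gene g is the median across permutations of the count of null
|d| ≥ |d_g|, divided by the observed count of |d| ≥ |d_g|, clipped to
[0, 1] and monotonized in |d| rank. No π₀ estimate is applied; omitting
it biases q-values upward, i.e. the estimator is conservative. Under a
global null with 1000 genes and 10 pairs the mean number of genes at
q < 0.05 across 20 seeds is well below 1 (the calibration suite asserts
≤ 2), and planted 2-SD shifts are recovered with ≥ 80% power.

**Fold-change rules.** Fold changes are per-pair log2 differences; a
ratio threshold t means |log2 FC| ≥ log2 t. The concordance rule reports
genes changed ≥ 2-fold in the same direction in ≥ 5 pairs; candidate
selection for correlation screens uses |FC| ≥ 2 (copy-number screen) or
≥ 1.5 (methylation screen) in ≥ 3 pairs, in either direction. Raising any
threshold never enlarges a reported list.

**Unsupervised structure.** Euclidean distances between samples, UPGMA
(group-average) linkage, with flat clusters by height or count; classical
(Torgerson) MDS on double-centered squared distances, orientation fixed
by making each axis's first nonzero loading positive. The cluster-cut
height is always a parameter: absolute heights depend on the data scale,
so a fixed constant would not transfer across datasets.

**Over-representation.** One-sided hypergeometric test per gene set
against a supplied universe, BH-corrected across sets. This is a local
replacement for web-based enrichment tools, operating on user-supplied
sets only.

## Integration

The gene-level copy-number value is the probe-weighted mean log2 ratio
over the gene span, not the overlapping segment call, so partial overlaps
contribute continuously. Per gene, the expression fold-change vector
across pairs is correlated (Pearson) with the copy-number delta
(relapse − diagnosis of the span mean) or with the promoter methylation
change; two-sided p-values are BH-corrected across tested genes and the
headline reporting rule is |r| > 0.8 and FDR < 0.05, with an optional
sign restriction (positive for dosage, negative for methylation
repression). Zero-variance vectors are skipped and flagged rather than
given an arbitrary r.

The DMR/DEG intersection reports genes with a hypermethylated DMR and
expression down ≥ 1.5-fold in ≥ 3 pairs, or the mirrored hypomethylated
case — inverse associations only. Burden-stratified differential
expression runs the SAM paired test separately within the large- and
small-burden pairs (strata under 3 pairs are skipped). The pair-by-pair
screen counts, per gene, the pairs where |expression log2 FC| ≥ 1
co-occurs with a same-gene platform change (|copy-number delta| ≥ 0.1 or
|methylation Δfraction| ≥ 0.05) in the required sign relation.

The region-wise screen is a deliberately simplified surrogate for
region-level integrated association ("SIM-surrogate" in all outputs, to
avoid overclaiming): within each region (chromosome), a pair-level random
intercept — the region-average fold change per pair, shrunk by a
method-of-moments reliability factor — is removed before the per-gene
correlation, and FDR is computed within the region. Its purpose is to
absorb region-wide confounding shifts that inflate naive per-gene
correlations, which the test suite demonstrates on a planted-confounder
fixture.

## Meta-analysis

Per study and gene, group summaries (n, mean, SD per timepoint) yield
Hedges' g: pooled SD `s_p`, `d = Δmean/s_p`, small-sample factor
`J = 1 − 3/(4·df − 1)` (the standard approximation), `g = J·d`, variance
`v = (n₁+n₂)/(n₁n₂) + g²/(2(n₁+n₂))`. Cross-study pairing is not
available in practice, so summaries are unpaired group contrasts by
default. Heterogeneity: Cochran's Q with k−1 df and
`I² = max(0, (Q−df)/Q)·100`; studies are flagged heterogeneous when the
Q-test has p < 0.05 and I² > 50%. Pooling is DerSimonian–Laird:
`τ² = max(0, (Q−df)/C)`, `C = Σw − Σw²/Σw`, random-effects weights
`1/(v+τ²)`, normal 95% CI (1.96·SE; no Knapp–Hartung adjustment) and a
two-sided z-test. When Q ≤ df the result reduces exactly to fixed-effect
inverse-variance pooling. Genes present in fewer than two studies are
dropped with a warning. The whole chain is verified against an
independent step-by-step arithmetic recomputation and against
`metafor::rma(method = "DL")` in the test suite.

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code, not a fixture dump. It
emulates: per-pair shared, relapse-acquired and diagnosis-only (lost) CNA
segments with Gaussian probe noise; probe-level methylation fractions
with a Beta baseline, planted promoter DMRs and an additive batch shift;
and expression driven by baseline + copy-number dosage + promoter
methylation repression + direct relapse effects + noise. The methylation
probe set combines a background grid with dense tiles around every TSS
(as on promoter tiling arrays), so promoter windows contain enough probes
for the ≥ 4-probe DMR rule.

Defaults encode the study conditions the analyses are designed around:
17 pairs (the paired-expression cohort size); planted lesion means ±0.4
log2 (clearly callable at the ±0.1 thresholds; a precondition rejects
non-callable settings); copy-number probe noise SD 0.1, methylation
fraction noise SD 0.05, expression noise SD 0.3, batch shift 0.05 —
noise magnitudes for real arrays of this kind are not published, so these
were fixed once at values typical for the platforms and kept. The
dosage slope is 1 (expression tracks copy number one-to-one on the log2
scale) and the methylation slope −3 per unit promoter fraction, so the
default planted promoter change of +0.25 represses expression by 0.75
log2 — comfortably beyond the 1.5-fold inverse-association rule it must
be recoverable by. The direct relapse effect is −1.5 log2 in 5 genes.
When the copy-number probe table is supplied, the dosage term uses the
probe-weighted planted value over the gene span — the same summary the
downstream association step measures — so the zero-noise correlation of
a dosage gene is exactly 1 by construction.

What the generator does *not* emulate: raw scanner intensities,
allele-specific copy number, subclonal mixtures, probe-specific affinity
biases, and spatially correlated noise. Passing tests on synthetic data
therefore demonstrate correctness of the statistical machinery and
recoverability of planted signal under idealized noise, not performance
on raw array data.

Two generator details matter for exactness tests. First, methylation
fractions are clipped to [0, 1]; a planted hypomethylation delta on a
low baseline can clip at 0, shrinking the realized difference, so
exact-recovery fixtures plant hypermethylation on a mid-range Beta(10,30)
baseline. Second, planted segments shorter than `min_markers × probe
spacing` are not callable by construction; study-scale runs keep the
planted length range above that resolution.

## Problem sizes and determinism

The shipped configurations are sized for interactive use: the default
demo genome is 2 × 10 Mb with 4000 copy-number probes and ~5400
methylation probes, and the full pipeline runs in well under a minute on
one core; the acceptance script uses four 200-Mb chromosomes (8000
copy-number probes) and 17 pairs and completes in about a minute. All
randomness flows from a single integer seed (per-stage offsets keep the
platforms independent), and identical configurations reproduce outputs
byte-identically; the run manifest records the config, seed and stage
record counts.

## Known limitations

- The segmentation DP is O(n²) per chromosome; beyond ~10⁴ probes per
  chromosome a banded or pruned search would be needed.
- The SAM q-value estimator omits π₀ and is conservative; with very few
  pairs (n = 3–4) the sign-flip null is coarse (2ⁿ points) and q-values
  are quantized.
- ComBat requires ≥ 2 samples per batch; smaller batches silently fall
  back to mean-centering.
- The region-wise screen is a surrogate, not the published region-level
  association method, and is labelled as such in every output.
- Meta-analysis matches genes by identifier only; probe-set disparities
  between platforms must be resolved upstream.
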