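---
title: "Noise-floored differential expression for small bulk designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-floored differential expression for small bulk designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osmoseq)
```

# The analysis problem

osmoseq implements a classical bulk expression workflow for two-class
designs with very few biological replicates — the setting of transcriptome
studies of the hypothalamic supraoptic nucleus (SON) under chronic salt
loading, where three control and three treated animals per platform are
typical. The workflow's distinguishing feature is how it handles the
low-expression regime: rather than modelling mean–variance trends, it
locates the expression level at which the coefficient of variation (CV)
decouples from the mean — the *confidence criterion* — discards genes that
never exceed it, and floors the surviving values to it before testing.

The RNA-seq branch runs

1. read-pair counts → RPKM: `count * 1e9 / (length * library_total)`;
2. pedestalled log2: `log2(RPKM + 2)` (minimum attainable value 1);
3. removal of non-informative genes (no library above the pedestal floor,
   i.e. all raw RPKM zero);
4. quantile normalization across libraries;
5. per-class CV \~ mean curves, LOWESS-smoothed; confidence-criterion
   detection; removal of noise-biased genes and flooring;
6. per-gene Welch t-tests, Benjamini–Hochberg correction, signed linear
   fold changes, and selection at corrected p < 0.10 with |FC| ≥ 1.5.

The microarray branch enters at a post-RMA log2 matrix, replaces steps 1–4
by batch baseline subtraction against a common reference library, and
selects at corrected p < 0.05. QC projections (Tukey summaries, covariance
PCA, correlation heat-map data) run before and after selection.

# Statistical model and assumptions

The Welch-modified t-test is applied gene by gene to the post-floored
matrix, with Welch–Satterthwaite degrees of freedom and a two-sided p-value.
Its assumptions here are approximate normality of log-scale expression
within each class and independence across libraries. With n = 3 per class
the test is *conservative*: its true type-I rate at nominal 0.05 sits below
0.05, which is why the null-calibration check in the test suite asserts a
band (0.05 ± 0.02) rather than a point. Flooring further truncates the
low tail, so genes hovering at the criterion can become partially constant;
the implementation keeps such genes' statistics defined (see "Degenerate
inputs" below).

The signed linear fold change follows the reporting convention of
expression tables: `r = 2^(mean_treated − mean_control)`, reported as `r`
for increases and `−1/r` for decreases, so its magnitude is always ≥ 1 and
its sign is the direction of change. Selection is strict on p
(`p_bh < threshold`) and non-strict on fold change (`|fc| ≥ 1.5`).

# Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `pedestal` | 2 | RPKM | damps low-end variance before log2 |
| `lowess_frac` | 0.3 | fraction of points | LOWESS span of the CV curves |
| `elbow_gain` | 1.2 | SSE ratio | minimum broken-stick gain to accept an elbow |
| `criterion` | detected | log2 units | manual noise-floor override |
| `p_threshold` | 0.10 / 0.05 | probability | RNA-seq / microarray selection |
| `fc_threshold` | 1.5 | linear fold | selection magnitude |

The pedestal of 2 and both selection thresholds are the workflow's defining
constants. The LOWESS span and elbow gain are the only free parameters of
the noise-floor module; 0.3 is a conventional span for a single broad trend
over thousands of points, and 1.2 demands a 20% error reduction before a
two-segment description is accepted over a straight line, which rejects
elbow calls on flat curves.

# Automating the confidence criterion

In the original procedure the criterion was chosen by *visual inspection*
of the LOWESS fits. Reproducibility demands an algorithmic default, so
`detect_confidence_criterion()` fits a two-segment broken-stick model to
each class's smoothed curve, scanning every interior grid point as the
breakpoint and minimising total squared error; a class yields an elbow only
when the two-segment fit beats a single line by `elbow_gain`. "Grossly and
concordantly lost" is operationalised conservatively as the **maximum** of
the per-class breakpoints — nothing below the noise floor of either class
survives — with a warning when the classes disagree by more than 0.5 log2
units. Any visual choice remains reproducible through the `criterion`
override, and `run_pipeline(..., criterion =)` records the override in its
manifest. CV is computed on the normalized log2-scale values, i.e. the same
matrix the test sees.

# What the generators emulate — and what they do not

`simulate_counts()` emulates the study conditions the workflow was built
for: two classes × three libraries, log-normal gene abundances, a
mean-dependent CV with an elbow at low expression, a stated fraction of
truly differential genes at a stated fold change, and fixed sequencing
depth per library. Defaults, with their provenance:

- `n_per_class = 3` — the design of the emulated studies.
- `n_genes = 2000` — a desk-scale transcriptome; large enough for stable
  LOWESS fits and BH behaviour, small enough that multi-seed test batteries
  run in seconds per seed. All multi-seed checks in the test suite use this
  size (20 seeds for recovery properties, 50 for null calibration).
- `abundance_log2_mean = 2.6`, `abundance_log2_sd = 4.0` — chosen so that,
  after calibration of expected totals to `library_size`, roughly sixty
  percent of genes sit below the noise elbow. That matches the structure of
  deeply sequenced tissue transcriptomes, where most annotated genes are at
  or below the detection floor; an analysis that floors more than half of
  the detected genes is exactly the regime this workflow targets. Note the
  calibration pins the realized log2 location: the two defaults are
  mutually consistent rather than independent.
- `elbow_location = 3.0` log2(RPKM+2) units — a floor at RPKM ≈ 6, the
  scale on which published SON noise analyses place the cutoff.
- `cv_high = 0.02` — the within-class CV of log2 values above the elbow.
  Back-computed from the corrected p-values that published three-replicate
  SON tables report for their boundary fold changes (a 1.5× change at a
  mean of ~4.7 log2 units with corrected p ≈ 0.03 implies a per-library sd
  of ~0.08, i.e. CV ≈ 0.02).
- `cv_low_slope = 0.3` per log2 unit — a piecewise-linear CV inflation
  below the elbow, the simplest shape with a detectable breakpoint.
- `de_fraction = 0.057` — the fraction of reliably expressed genes that
  respond (552 of 9,709 in the emulated study).
- `de_log2fc = 1.0` — a two-fold planted effect, the median magnitude of
  published SON fold-change tables; split 50/50 up/down.
- `library_size = 1e6` read pairs — the emulated studies do not report
  mapped totals, so this is a desk-scale choice, not an inferred one.
- `gene_length_range = [500, 3000]` nt — typical mRNA lengths.

Two generator design choices deserve emphasis:

**Noise is drawn on the analysis scale.** Per-library values are drawn
Gaussian on the log2(RPKM+2) scale with sd = `cv(m) * m`, then converted
back to expected counts, rounded, and renormalised to the library total.
This targets the CV–mean profile directly — the behaviour the downstream
stages consume — instead of sampling counts from a negative-binomial
family, whose depth-dependent Poisson component would superimpose a second
elbow confounding the planted one. The cost is that count-level noise is
only quantisation; the benefit is that the planted elbow is exactly where
the configuration says it is.

**Differential truth is planted above the floor.** DE genes are drawn from
genes whose control abundance exceeds `elbow_location + de_log2fc`, so both
class means stay above the criterion. A down-shift landing below the floor
would be censored by flooring and unrecoverable *by construction*; planting
it would make "sensitivity against truth" measure the generator's cruelty
rather than the pipeline's behaviour. Published down-regulated tables show
the same structure: reported treated-class means sit above the criterion.

What the generators do **not** emulate: alignment ambiguity and positional
read placement, transcript isoforms, GC or length biases beyond the RPKM
length term, batch structure in the RNA-seq branch, outlier libraries, and
heavy-tailed (non-Gaussian) biological noise. Passing the recovery tests
therefore shows the pipeline correctly inverts the data-generating
mechanism it assumes — not that it is robust to everything real data can
do. The microarray generator adds per-probe offsets, a clamp at log2 = 2
(the typical RMA floor), additive batch offsets (scalar or gene-specific),
and a reference library drawn once and copied into every batch so the
offsets are recoverable exactly.

The qPCR generator plants `2^(−ΔΔCt)` structure directly: the calibrator Ct
is stable across groups and the target Ct shifts by `−log2(fold change)` in
the treated group before measurement noise.

# Numerical choices and degenerate inputs

- **Quantile-normalization ties** receive the mean of the reference values
  their ranks span. On tied data this intentionally departs from "all
  sorted columns identical": columns with different tie multiplicities
  (e.g. different numbers of pedestal-floor values) get different tie-block
  means. The sorted-columns identity is definitional only on tie-free
  input, and the test suite asserts each statement on its own domain.
- **Zero pooled SE** after flooring: equal class means give t = 0, p = 1;
  unequal constant classes have the zero SE replaced by 1e-8 (with a
  warning) so a real difference registers rather than producing NaN.
- **Keep rule** is strictly greater-than: a gene whose maximum equals the
  criterion exactly is removed.
- **Quartiles** are type-7 (linear interpolation); whisker ends sit on the
  most extreme point inside the 1.5×IQR fence. QC flags outliers but never
  removes samples — exclusion is a user decision.
- **PCA signs** follow a fixed convention (largest-magnitude loading
  positive) so runs are comparable.
- **Gene symbols** are compared case-insensitively with whitespace
  stripped at every cross-platform step, since reporting conventions mix
  capitalisations.
- **Multi-probe fold changes** collapse to the probe with maximum |FC|
  (alternatives `mean` and `first` are selectable); presence/DE status is
  "any probe".
- **Fisher enrichment** defaults to the two-sided exact test; pathway
  tools often use the right tail only, and `alternative = "greater"`
  reproduces that.
- **ΔΔCt significance** uses the plain Student t-test (equal variances) on
  per-sample ΔCt values, matching the convention of qPCR validation
  tables; the control group's reported relative expression is normalised
  to mean 1.

# Known limitations

- Welch at n = 3 is conservative (true type-I rate below nominal), and no
  variance moderation/shrinkage is applied — by design, since the point is
  to reproduce this workflow, not to improve on it.
- Flooring censors fold changes of genes near the criterion; a criterion
  overshoot in a noisy run shrinks observed fold changes of marginal genes
  below the selection threshold. This is inherent to the method.
- The broken-stick detector assumes one elbow; CV curves with multiple
  regime changes will yield the best single breakpoint and possibly a
  concordance warning.
- Batch correction assumes purely additive, library-independent batch
  effects measured by one reference library; with more than two batches,
  corrections chain against batch 1.
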