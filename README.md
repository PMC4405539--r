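# osmoseq

Noise-floored differential expression analysis for bulk RNA-seq and
microarray studies with few biological replicates.

## What problem this solves

Small two-class expression studies — three control versus three treated
animals is the classic design for transcriptome work on the hypothalamic
supraoptic nucleus under chronic salt loading — face two entangled
problems: most detected genes sit at or below the platform's noise floor,
and with n = 3 per class there is no room for elaborate variance modelling.
This package implements, end to end and reproducibly, the workflow built
for exactly that setting:

- **Preprocessing** (RNA-seq): paired-end FASTQ cleaning — 3' adapter
  clipping, a fixed 15 nt head / 1 nt tail trim, quality end-trimming at
  95% call accuracy, and discarding of pairs with a mate under 15 nt or
  with more than two ambiguous bases.
- **Normalization**: `RPKM = count · 10⁹ / (length · total)`, pedestalled
  log transform `log2(RPKM + 2)`, removal of genes with no library above
  the pedestal floor, and quantile normalization. Microarray data enter
  post-RMA and are batch-corrected by baseline subtraction against a
  common reference library.
- **Noise floor**: per class, the per-gene coefficient of variation is
  regressed on mean expression by LOWESS; the expression value where the
  CV decouples from the mean (located by a broken-stick fit, or set
  manually) becomes the *confidence criterion*. Genes never exceeding it
  are discarded; surviving sub-criterion values are floored to it.
- **Differential expression**: per-gene Welch t-tests with
  Benjamini–Hochberg correction; signed linear fold changes
  `2^(Δ log2)` reported as negative reciprocals for decreases; selection
  at corrected p < 0.10 (RNA-seq) or < 0.05 (microarray) with |FC| ≥ 1.5.
- **QC, comparison, validation**: Tukey summaries, covariance PCA and
  correlation heat-map data; symbol-level cross-platform Venn
  intersections and fold-change concordance; Fisher exact gene-set
  enrichment; ΔΔCt qPCR fold changes against a calibrator gene.
- **Synthetic data with ground truth** for every input — count matrices
  with a planted CV elbow and differential genes, batched microarrays with
  a common reference, paired FASTQ with per-pair filter truth, qPCR Ct
  tables — so the whole pipeline is testable without external data.

## Worked example

```r
library(osmoseq)

cfg <- sim_config(seed = 42)          # 2000 genes, 3 vs 3 libraries
sim <- simulate_counts(cfg)
sim$counts
#> count_matrix: 2000 genes x 6 libraries (read pairs)

res <- run_pipeline(sim$counts, sim$design, "example_run", platform = "rnaseq")
res$floor
#> noise_floor: criterion 3.111
#>   per-class breakpoints: control=2.999, salt_loaded=3.111

nrow(res$de); sum(res$de$selected)
#> [1] 1234
#> [1] 81

sel <- select_de_genes(res$de)
head(sel[, c("gene_id", "mean_control", "mean_treated", "signed_fc", "p_bh")], 5)
#>      gene_id mean_control mean_treated signed_fc   p_bh
#> 235 gene0371        10.92         9.70     -2.34 0.0447
#> 372 gene0584         6.31         7.49      2.28 0.0447
#> 789 gene1267        11.80        12.99      2.28 0.0177
#> 312 gene0492         5.66         6.82      2.23 0.0203
#> 346 gene0545         7.05         8.17      2.17 0.0636
```

Reading the output: the generator planted its noise elbow at 3.0
log2(RPKM+2) units, and the broken-stick detector recovered per-class
breakpoints of 2.999 and 3.111, taking the maximum (3.111) as the
consensus criterion. Of 2000 simulated genes, 1234 survived the
non-informative and noise-floor filters; 81 passed the selection rule
(corrected p < 0.10, |FC| ≥ 1.5). Comparing against the generator's truth:

```r
truth <- names(sim$truth$de_log2fc)
mean(truth %in% sel$gene_id)        # sensitivity
#> [1] 0.711
sum(!(sel$gene_id %in% truth))      # false discoveries among 81 selected
#> [1] 0
```

Fold changes recompute directly from class means in log2 units, e.g. a
gene with class means 4.16 (control) and 6.87 (salt-loaded):

```r
round(signed_fold_change(4.16, 6.87), 2)
#> [1] 6.54
```

Every run directory contains the normalized matrix, the noise model
(JSON + per-class CV curves), the floored matrix, full and selected DE
tables, QC summaries, and a manifest from which the run is reproducible.

## Package layout

- `R/` — implementation: generators (`sim_*`), `fastq_preprocess`,
  `io`, `normalize`, `qc`, `noisefloor`, `diffexpr`, `crossplatform`,
  `enrich_qpcr`, `pipeline`.
- `vignettes/noise-floored-de.Rmd` — the methods vignette: model,
  parameter provenance, generator design, numerical choices, limitations.
- `tests/testthat/` — unit, property and acceptance tests with
  independent brute-force oracles in `helper-oracles.R`.
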