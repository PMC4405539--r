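#' Configuration for the synthetic two-class expression generators
#'
#' Defaults describe the study design the generators emulate: two conditions
#' (control vs salt-loaded) with three biological replicate libraries each,
#' log-normally distributed gene abundances, a mean-dependent coefficient of
#' variation that is flat above a low-expression elbow and inflates linearly
#' below it, and a small fraction of genes planted as truly differential with
#' a symmetric two-fold effect. See the methods vignette for how each default
#' was chosen.
#'
#' @param n_genes number of genes.
#' @param n_per_class biological replicate libraries per condition.
#' @param class_labels length-2 character: control then treated label.
#' @param de_fraction proportion of genes planted as truly differential,
#'   in `[0, 1)`.
#' @param de_log2fc planted absolute log2 fold change (split 50/50 up/down).
#' @param abundance_log2_mean,abundance_log2_sd log-normal gene abundance
#'   parameters on the log2 RPKM scale. Expected abundances are rescaled so
#'   each library's expected read-pair total equals `library_size`, which
#'   pins the realized log2 location near `abundance_log2_mean` when the
#'   defaults are used together; the defaults place roughly sixty percent
#'   of genes below the noise elbow, the proportion a deeply sequenced
#'   tissue transcriptome shows (most annotated genes are at or below the
#'   detection floor in any one tissue).
#' @param elbow_location planted noise elbow, in log2(RPKM+2) units: below
#'   this mean expression the CV inflates.
#' @param cv_high baseline CV (sd/mean of log2-pedestalled values within a
#'   class) above the elbow.
#' @param cv_low_slope CV inflation per log2 unit below the elbow:
#'   `cv(m) = cv_high + cv_low_slope * max(0, elbow_location - m)`.
#' @param library_size expected mapped read pairs per library.
#' @param gene_length_range length-2 integer, transcript length bounds (nt).
#' @param seed integer seed; identical config + seed gives identical output.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_per_class = 3,
                       class_labels = c("control", "salt_loaded"),
                       de_fraction = 0.057,
                       de_log2fc = 1.0,
                       abundance_log2_mean = 2.6,
                       abundance_log2_sd = 4.0,
                       elbow_location = 3.0,
                       cv_high = 0.02,
                       cv_low_slope = 0.3,
                       library_size = 1e6,
                       gene_length_range = c(500L, 3000L),
                       seed = 1L) {
  assert_scalar_number(n_genes, "n_genes", positive = TRUE, integer = TRUE)
  assert_scalar_number(n_per_class, "n_per_class", positive = TRUE, integer = TRUE)
  if (length(class_labels) != 2 || anyDuplicated(class_labels))
    stopf("'class_labels' must be two distinct labels")
  assert_proportion(de_fraction, "de_fraction", open_right = TRUE)
  assert_scalar_number(de_log2fc, "de_log2fc")
  if (de_fraction > 0 && de_log2fc <= 0)
    stopf("de_log2fc must be > 0 when de_fraction > 0 (degenerate truth)")
  assert_scalar_number(abundance_log2_mean, "abundance_log2_mean")
  assert_scalar_number(abundance_log2_sd, "abundance_log2_sd", positive = TRUE)
  assert_scalar_number(elbow_location, "elbow_location")
  q <- abundance_log2_mean + c(-1, 1) * stats::qnorm(0.995) * abundance_log2_sd
  if (elbow_location < q[1] || elbow_location > q[2])
    stopf("elbow_location %.2f outside the central 99%% abundance range [%.2f, %.2f]",
          elbow_location, q[1], q[2])
  assert_scalar_number(cv_high, "cv_high", positive = TRUE)
  assert_scalar_number(cv_low_slope, "cv_low_slope", positive = TRUE)
  assert_scalar_number(library_size, "library_size", positive = TRUE)
  if (length(gene_length_range) != 2 || any(gene_length_range <= 0) ||
      gene_length_range[1] > gene_length_range[2])
    stopf("'gene_length_range' must be a positive increasing interval")
  assert_scalar_number(seed, "seed", integer = TRUE)
  structure(list(n_genes = as.integer(n_genes),
                 n_per_class = as.integer(n_per_class),
                 class_labels = as.character(class_labels),
                 de_fraction = de_fraction, de_log2fc = de_log2fc,
                 abundance_log2_mean = abundance_log2_mean,
                 abundance_log2_sd = abundance_log2_sd,
                 elbow_location = elbow_location,
                 cv_high = cv_high, cv_low_slope = cv_low_slope,
                 library_size = library_size,
                 gene_length_range = as.integer(gene_length_range),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Target CV at a given mean on the log2-pedestalled scale: flat above the
# elbow, piecewise-linear inflation below it.
target_cv <- function(cfg, m) {
  cfg$cv_high + cfg$cv_low_slope * pmax(0, cfg$elbow_location - m)
}
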