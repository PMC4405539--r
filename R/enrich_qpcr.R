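# Gene-set enrichment by Fisher's exact test over a declared gene universe,
# and delta-delta-Ct relative quantification for qPCR validation.

#' Fisher exact gene-set enrichment
#'
#' For each set, a 2x2 table of DE membership against set membership over
#' the universe (sets are intersected with the universe before counting) is
#' tested with Fisher's exact test. The default tail is two-sided; pathway
#' tools often use the right (over-representation) tail, selectable via
#' `alternative = "greater"`. A set is flagged enriched at uncorrected
#' p < `alpha`.
#'
#' @param de_genes differential gene ids (must all lie in `universe`).
#' @param universe all tested gene ids.
#' @param gene_sets named list of id vectors.
#' @param alternative Fisher tail, default `"two.sided"`.
#' @param alpha uncorrected enrichment threshold.
#' @return data.frame, one row per set: contingency counts, `odds_ratio`
#'   (conditional MLE; `NA` for degenerate margins), `p`, `enriched`.
#' @export
fisher_enrichment <- function(de_genes, universe, gene_sets,
                              alternative = c("two.sided", "greater", "less"),
                              alpha = 0.05) {
  alternative <- match.arg(alternative)
  de_genes <- unique(norm_symbol(de_genes))
  universe <- unique(norm_symbol(universe))
  outside <- setdiff(de_genes, universe)
  if (length(outside))
    stopf("DE gene(s) outside the universe: %s",
          paste(utils::head(outside, 10), collapse = ", "))
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(unique(norm_symbol(gene_sets[[nm]])), universe)
    de_in <- length(intersect(de_genes, s))
    de_out <- length(de_genes) - de_in
    bg_in <- length(s) - de_in
    bg_out <- length(universe) - length(s) - de_out
    tab <- matrix(c(de_in, de_out, bg_in, bg_out), 2)
    ft <- stats::fisher.test(tab, alternative = alternative)
    or <- unname(ft$estimate)
    data.frame(set = nm, de_in_set = de_in, de_not_in_set = de_out,
               bg_in_set = bg_in, bg_not_in_set = bg_out,
               odds_ratio = if (is.finite(or)) or else NA_real_,
               p = ft$p.value, enriched = ft$p.value < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Delta-delta-Ct fold change with a calibrator gene
#'
#' Per sample, `dCt = Ct_target - Ct_calibrator`; the group contrast
#' `ddCt = mean(dCt_treated) - mean(dCt_control)` gives the fold change
#' `2^(-ddCt)`. Significance is an unpaired Student t-test (equal
#' variances) on the per-sample dCt values. For reporting, per-sample
#' relative expression `2^(-dCt)` is normalised so the control group's mean
#' is 1. The statistic is invariant to adding a constant to all of a
#' sample's Ct values (that is what the calibrator is for).
#'
#' @param assay data.frame with columns `sample`, `group`, `target_ct`,
#'   `calibrator_ct` (as from [read_qpcr()] or [simulate_qpcr()]).
#' @param control,treated group labels (>= 2 samples each).
#' @return list with `fold_change`, `ddct`, `p`, and `relative` (per-sample
#'   control-normalised relative expression with group labels).
#' @export
ddct_fold_change <- function(assay, control = "control",
                             treated = "salt_loaded") {
  need <- c("sample", "group", "target_ct", "calibrator_ct")
  if (!all(need %in% names(assay)))
    stopf("assay must have columns: %s", paste(need, collapse = ", "))
  if (any(!is.finite(assay$target_ct)) || any(!is.finite(assay$calibrator_ct)))
    stopf("missing Ct measurement(s)")
  for (g in c(control, treated))
    if (sum(assay$group == g) < 2) stopf("group '%s' needs >= 2 samples", g)
  dct <- assay$target_ct - assay$calibrator_ct
  dc <- dct[assay$group == control]
  dt_ <- dct[assay$group == treated]
  ddct <- mean(dt_) - mean(dc)
  # simple Student t (equal variances); constant groups handled explicitly
  p <- if (stats::var(dc) == 0 && stats::var(dt_) == 0) {
    if (ddct == 0) 1 else 0
  } else {
    stats::t.test(dt_, dc, var.equal = TRUE)$p.value
  }
  rel <- 2^(-dct)
  rel <- rel / mean(rel[assay$group == control])  # control mean exactly 1
  list(fold_change = 2^(-ddct), ddct = ddct, p = p,
       relative = data.frame(sample = assay$sample, group = assay$group,
                             relative_expression = rel,
                             stringsAsFactors = FALSE))
}
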