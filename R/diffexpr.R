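# Gene-by-gene two-class testing on the floored matrix: Welch-modified t
# with Welch-Satterthwaite degrees of freedom, Benjamini-Hochberg FDR
# correction, signed linear fold change from the class means, and the
# selection rule (corrected p strictly below the platform threshold AND
# absolute fold change of at least 1.5).

#' Welch-modified two-sample t-test
#'
#' `t = (mean(b) - mean(a)) / sqrt(s_a^2/n_a + s_b^2/n_b)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p from the t
#' distribution. Flooring can leave both groups constant; such degenerate
#' genes must still yield defined statistics: equal constant groups give
#' `t = 0, p = 1`, while unequal constant groups have their zero standard
#' error replaced by 1e-8 (with a warning) so the difference registers as
#' maximally significant rather than undefined.
#'
#' @param a,b numeric vectors, >= 2 values each (group a = control,
#'   group b = treated).
#' @return list with `t`, `df`, `p`.
#' @export
welch_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stopf("each group needs >= 2 values")
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  d <- mean(b) - mean(a)
  if (se2 == 0) {
    if (d == 0) return(list(t = 0, df = na + nb - 2, p = 1))
    warnf("zero pooled SE with unequal means; SE set to 1e-8")
    return(list(t = d / 1e-8, df = na + nb - 2, p = 0))
  }
  t <- d / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR step-up rule (`q_(i) = min_{j>=i} m p_(j)/j`, capped at 1),
#' delegated to `stats::p.adjust(method = "BH")`, returned in input order.
#' Adjusted values preserve the ordering of the raw p-values. Do not apply
#' twice: the adjustment is not idempotent except in the single-value case.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted vector, same order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Signed linear fold change from log2 class means
#'
#' `r = 2^(mean_treated - mean_control)`; increases are reported as `r`
#' (>= 1), decreases as the negative reciprocal `-1/r` (<= -1), the usual
#' reporting convention for expression tables. Equal means give +1.
#'
#' @param mean_control,mean_treated class means in log2 units (vectorised).
#' @return signed linear fold change(s), full precision (round only for
#'   presentation).
#' @export
signed_fold_change <- function(mean_control, mean_treated) {
  r <- 2^(mean_treated - mean_control)
  ifelse(r >= 1, r, -1 / r)
}

#' Antilog presentation of a log2 expression value
#'
#' `2^value`, rounded to the nearest integer for reporting relative
#' expression in linear units.
#'
#' @param log2_value log2-scale value(s).
#' @return rounded linear value(s).
#' @export
linear_units <- function(log2_value) round(2^log2_value)

#' Differential-expression selection thresholds
#'
#' Defaults per platform: corrected p < 0.10 for RNA-seq, < 0.05 for
#' microarray; absolute fold change >= 1.5 for both. Note the asymmetry the
#' rule states: strict on p, non-strict on fold change.
#'
#' @param platform `"rnaseq"` or `"microarray"` (sets the p threshold).
#' @param p_threshold,fc_threshold explicit overrides.
#' @return list of class `selection_criteria`.
#' @export
selection_criteria <- function(platform = c("rnaseq", "microarray"),
                               p_threshold = NULL, fc_threshold = 1.5) {
  platform <- match.arg(platform)
  if (is.null(p_threshold))
    p_threshold <- if (platform == "rnaseq") 0.10 else 0.05
  assert_proportion(p_threshold, "p_threshold", open_right = TRUE)
  if (p_threshold <= 0) stopf("'p_threshold' must be in (0, 1)")
  assert_scalar_number(fc_threshold, "fc_threshold")
  if (fc_threshold < 1) stopf("'fc_threshold' must be >= 1")
  structure(list(platform = platform, p_threshold = p_threshold,
                 fc_threshold = fc_threshold),
            class = "selection_criteria")
}

#' Per-gene differential-expression table
#'
#' Applies the Welch test to every gene of a floored matrix, adjusts the
#' p-values by Benjamini-Hochberg over all tested genes, computes signed
#' linear fold changes from the class means, and flags the selected genes
#' (`p_bh < p_threshold` and `|signed_fc| >= fc_threshold`).
#'
#' @param em [expression_matrix()] on the `"floored"` scale (the same
#'   matrix feeds both the test and the fold change).
#' @param design `osmo_design` with exactly two classes.
#' @param control the control class label; the other class is treated.
#' @param criteria a [selection_criteria()].
#' @return data.frame: `gene_id`, `mean_control`, `mean_treated`, `t_stat`,
#'   `df`, `p_raw`, `p_bh`, `signed_fc`, `selected`.
#' @export
de_table <- function(em, design, control = "control",
                     criteria = selection_criteria("rnaseq")) {
  assert_scale(em, "floored", "de_table")
  idx <- match(colnames(em$values), design$library_id)
  if (any(is.na(idx)))
    stopf("libraries missing from design: %s",
          paste(colnames(em$values)[is.na(idx)], collapse = ", "))
  classes <- design$class[idx]
  if (length(unique(classes)) != 2) stopf("design must define exactly 2 classes")
  if (!control %in% classes) stopf("control class '%s' not in design", control)
  a <- em$values[, classes == control, drop = FALSE]
  b <- em$values[, classes != control, drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2) stopf("each class needs >= 2 libraries")

  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  d <- mb - ma
  degen <- se2 == 0
  if (any(degen & d != 0))
    warnf("%d gene(s) constant within both classes but with unequal means; SE set to 1e-8",
          sum(degen & d != 0))
  se2_adj <- ifelse(degen, 1e-16, se2)  # (1e-8)^2
  t <- ifelse(degen & d == 0, 0, d / sqrt(se2_adj))
  df <- ifelse(degen, na + nb - 2,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)))
  p <- ifelse(degen, ifelse(d == 0, 1, 0), 2 * stats::pt(-abs(t), df))
  p_bh <- bh_adjust(p)
  fc <- signed_fold_change(ma, mb)
  out <- data.frame(gene_id = rownames(em$values),
                    mean_control = ma, mean_treated = mb,
                    t_stat = t, df = df, p_raw = p, p_bh = p_bh,
                    signed_fc = fc,
                    selected = p_bh < criteria$p_threshold &
                               abs(fc) >= criteria$fc_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "criteria") <- criteria
  out
}

#' Apply the selection rule to a DE table
#'
#' Keep iff `p_bh < p_threshold` AND `|signed_fc| >= fc_threshold`.
#'
#' @param records a data.frame with `p_bh` and `signed_fc` columns.
#' @param criteria a [selection_criteria()].
#' @return the selected subset, ordered by decreasing `|signed_fc|`.
#' @export
select_de_genes <- function(records, criteria = selection_criteria("rnaseq")) {
  if (!all(c("p_bh", "signed_fc") %in% names(records)))
    stopf("records must carry p_bh and signed_fc")
  sel <- records[records$p_bh < criteria$p_threshold &
                   abs(records$signed_fc) >= criteria$fc_threshold, , drop = FALSE]
  sel[order(-abs(sel$signed_fc)), , drop = FALSE]
}

#' Cell-type marker panel report
#'
#' For each marker gene of a phenotype panel: class means in log2 and
#' antilog linear units, signed fold change (1 decimal for presentation),
#' and a significance flag taken from the DE table; the fold-change column
#' shows `"-"` for markers whose change is not significant. Markers absent
#' from the matrix are reported in a separate `missing` element rather than
#' failing the report.
#'
#' @param em [expression_matrix()] on the `"floored"` scale.
#' @param design `osmo_design`.
#' @param panel named character vector: `panel[gene_id] = phenotype label`.
#'   Matching against matrix rownames is case-insensitive.
#' @param control control class label.
#' @param de optional precomputed [de_table()] for the significance flag
#'   (computed from `em` when omitted).
#' @param criteria a [selection_criteria()].
#' @return list with `report` (data.frame: phenotype, gene, means with
#'   linear units, fold change string, significant flag) and `missing`.
#' @export
marker_panel_report <- function(em, design, panel, control = "control",
                                de = NULL,
                                criteria = selection_criteria("rnaseq")) {
  assert_scale(em, "floored", "marker_panel_report")
  if (is.null(names(panel))) stopf("'panel' must be named by gene id")
  if (is.null(de)) de <- de_table(em, design, control, criteria)
  rn <- rownames(em$values)
  hit <- match(toupper(names(panel)), toupper(rn))
  missing <- names(panel)[is.na(hit)]
  present <- which(!is.na(hit))
  rows <- lapply(present, function(i) {
    g <- rn[hit[i]]
    der <- de[match(toupper(g), toupper(de$gene_id)), ]
    fc <- round(der$signed_fc, 1)
    data.frame(phenotype = unname(panel[i]), gene = names(panel)[i],
               mean_control = der$mean_control,
               linear_control = linear_units(der$mean_control),
               mean_treated = der$mean_treated,
               linear_treated = linear_units(der$mean_treated),
               fold_change = if (der$selected) sprintf("%.1f", fc) else "-",
               fold_change_value = fc,
               significant = der$selected,
               stringsAsFactors = FALSE)
  })
  list(report = if (length(rows)) do.call(rbind, rows) else NULL,
       missing = missing)
}
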