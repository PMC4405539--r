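#' Run the full expression workflow and write every intermediate
#'
#' Orchestrates the stages in workflow order and writes each intermediate
#' artifact plus a manifest to `out_dir`, so a run is reproducible from its
#' manifest alone.
#'
#' RNA-seq: counts -> RPKM -> pedestalled log2 -> non-informative removal ->
#' quantile normalization -> QC -> CV/LOWESS noise model -> confidence
#' criterion -> floor filter -> Welch/BH/fold-change DE table -> post-DE QC.
#'
#' Microarray: post-RMA log2 matrix -> batch baseline subtraction -> QC ->
#' noise model -> floor filter -> DE table (p < 0.05 default) -> post-DE QC.
#'
#' @param x a [count_matrix()] (`platform = "rnaseq"`) or an
#'   [expression_matrix()] on the `"rma_log2"` scale
#'   (`platform = "microarray"`).
#' @param design an `osmo_design`.
#' @param out_dir output directory (created if needed).
#' @param platform `"rnaseq"` or `"microarray"`.
#' @param control control class label.
#' @param pedestal pedestal constant for the log2 transform.
#' @param lowess_frac LOWESS span for the noise curves.
#' @param elbow_gain minimum broken-stick SSE gain to accept an elbow.
#' @param criterion optional manual confidence criterion (overrides
#'   detection).
#' @param criteria a [selection_criteria()]; defaults to the platform's.
#' @return (invisibly) list with the final objects: `normalized`, `floor`,
#'   `floored`, `de`, `qc`, `artifacts` (paths), `manifest`.
#' @export
run_pipeline <- function(x, design, out_dir,
                         platform = c("rnaseq", "microarray"),
                         control = "control",
                         pedestal = 2,
                         lowess_frac = 0.3,
                         elbow_gain = 1.2,
                         criterion = NULL,
                         criteria = NULL) {
  platform <- match.arg(platform)
  if (is.null(criteria)) criteria <- selection_criteria(platform)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- list()
  put <- function(name, path) { art[[name]] <<- path; path }

  if (platform == "rnaseq") {
    if (!inherits(x, "count_matrix"))
      stopf("rnaseq pipeline starts from a count_matrix")
    em <- pedestal_log2(compute_rpkm(x), pedestal)
    dropped <- drop_noninformative(em)
    em <- quantile_normalize(dropped$expr)
    removed_noninf <- dropped$removed_ids
  } else {
    if (!inherits(x, "expression_matrix"))
      stopf("microarray pipeline starts from an expression_matrix")
    bc <- batch_baseline_subtract(x, design)
    em <- bc$expr
    design <- bc$design
    removed_noninf <- character(0)
  }
  write_expression(em, put("normalized", file.path(out_dir, "normalized.tsv")))

  qc_pre <- list(tukey = tukey_summary(em),
                 pca = pca_covariance(em),
                 correlation = correlation_heatmap(em, clustered = TRUE))
  jsonlite::write_json(
    list(pca_var_explained = qc_pre$pca$var_explained,
         correlation = qc_pre$correlation$r,
         leaf_order = qc_pre$correlation$order),
    put("qc", file.path(out_dir, "qc_summary.json")),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)

  curves <- lapply(cv_mean_by_class(em, design), fit_lowess, frac = lowess_frac)
  floor <- detect_confidence_criterion(curves, elbow_gain = elbow_gain,
                                       criterion = criterion)
  write_noise_floor(floor, put("noise_model", file.path(out_dir, "noise_model.json")),
                    curves = curves)

  floored <- apply_floor_filter(em, floor)
  write_expression(floored$expr,
                   put("floored", file.path(out_dir, "floored.tsv")))

  de <- de_table(floored$expr, design, control = control, criteria = criteria)
  write_de_table(select_de_genes(de, criteria),
                 put("de_selected", file.path(out_dir, "de_selected.tsv")))
  utils::write.table(de, put("de_full", file.path(out_dir, "de_full.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # post-selection grouping check on the DE genes only
  sel_ids <- de$gene_id[de$selected]
  qc_post <- if (length(sel_ids) >= 5 && sum(de$selected) >= 2) {
    sub <- expression_matrix(
      floored$expr$values[sel_ids, , drop = FALSE], "floored")
    list(pca = pca_covariance(sub),
         correlation = correlation_heatmap(sub, clustered = TRUE))
  } else NULL

  manifest <- list(
    package = "osmoseq",
    version = as.character(utils::packageVersion("osmoseq")),
    platform = platform, control = control,
    pedestal = pedestal, lowess_frac = lowess_frac,
    elbow_gain = elbow_gain,
    criterion = floor$criterion, criterion_manual = floor$manual,
    selection = list(p_threshold = criteria$p_threshold,
                     fc_threshold = criteria$fc_threshold),
    n_genes_in = if (platform == "rnaseq") nrow(x$counts) else nrow(x$values),
    n_removed_noninformative = length(removed_noninf),
    n_removed_noise = length(floored$removed_ids),
    n_tested = nrow(de),
    n_selected = sum(de$selected),
    artifacts = art)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  art$manifest <- file.path(out_dir, "manifest.json")

  invisible(list(normalized = em, floor = floor, floored = floored$expr,
                 de = de, qc = qc_pre, qc_post = qc_post,
                 artifacts = art, manifest = manifest))
}
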