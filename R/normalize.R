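# Normalization stages. RNA-seq branch: counts -> RPKM -> log2(RPKM+2)
# ("pedestalled" to damp low-end variance) -> non-informative gene removal
# -> quantile normalization. Microarray branch: post-RMA log2 values ->
# batch baseline subtraction against the common reference library.

#' Convert read-pair counts to RPKM
#'
#' `rpkm(g, l) = count(g, l) * 1e9 / (length(g) * total(l))` with `total(l)`
#' the column sum of gene-assigned read pairs (the only mapped-read total
#' available at this stage).
#'
#' @param cm a [count_matrix()].
#' @return [expression_matrix()] with scale `"rpkm"`.
#' @export
compute_rpkm <- function(cm) {
  if (!inherits(cm, "count_matrix")) stopf("'cm' must be a count_matrix")
  totals <- colSums(cm$counts)
  if (any(totals == 0))
    stopf("zero mapped-read total in library: %s",
          paste(colnames(cm$counts)[totals == 0], collapse = ", "))
  vals <- cm$counts * 1e9 /
    outer(cm$gene_lengths, totals)
  expression_matrix(vals, "rpkm")
}

#' Pedestalled log2 transform
#'
#' `log2(rpkm + c)` with pedestal constant `c = 2` by default; with that
#' constant the minimum attainable value is 1, and the transform promotes
#' normality while damping low-end variance.
#'
#' @param em [expression_matrix()] on the `"rpkm"` scale.
#' @param pedestal pedestal constant (> 0).
#' @return [expression_matrix()] with scale `"log2_pedestalled"`.
#' @export
pedestal_log2 <- function(em, pedestal = 2) {
  assert_scale(em, "rpkm", "pedestal_log2")
  assert_scalar_number(pedestal, "pedestal", positive = TRUE)
  if (any(em$values < 0)) stopf("negative RPKM value")
  out <- expression_matrix(log2(em$values + pedestal), "log2_pedestalled")
  attr(out, "pedestal") <- pedestal
  out
}

#' Remove non-informative genes
#'
#' A gene is kept iff at least one library has a transformed value above the
#' floor of the pedestalled scale (`> log2(pedestal)`, i.e. `> 1` with the
#' default pedestal of 2) — equivalently, iff any raw RPKM is nonzero.
#'
#' @param em [expression_matrix()] on the `"log2_pedestalled"` scale.
#' @return list with `expr` (kept genes, same scale) and `removed_ids`.
#' @export
drop_noninformative <- function(em) {
  assert_scale(em, "log2_pedestalled", "drop_noninformative")
  pedestal <- attr(em, "pedestal") %||% 2
  thr <- log2(pedestal)
  keep <- apply(em$values, 1, max) > thr
  out <- expression_matrix(em$values[keep, , drop = FALSE], "log2_pedestalled")
  attr(out, "pedestal") <- pedestal
  list(expr = out, removed_ids = rownames(em$values)[!keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantile normalization
#'
#' Forces every library onto the common distribution given by the
#' across-library mean of order statistics: after normalization each
#' column's sorted values are identical. Ties within a column receive the
#' mean of the reference values their ranks span. Rank order within each
#' column is preserved.
#'
#' @param em [expression_matrix()] on the `"log2_pedestalled"` scale (or
#'   `"rma_log2"` for microarray data normalised the same way).
#' @return [expression_matrix()] with scale `"quantile_normalized"`.
#' @export
quantile_normalize <- function(em) {
  assert_scale(em, c("log2_pedestalled", "rma_log2"), "quantile_normalize")
  x <- em$values
  if (ncol(x) < 2) stopf("quantile normalization needs >= 2 libraries")
  ref <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(col) {
    r <- rank(col, ties.method = "min")     # first rank of each tie block
    cnt <- table(r)                          # tie-block sizes keyed by first rank
    block_mean <- vapply(names(cnt), function(k) {
      k <- as.integer(k)
      mean(ref[k:(k + cnt[[as.character(k)]] - 1L)])
    }, numeric(1))
    unname(block_mean[as.character(r)])
  })
  dimnames(out) <- dimnames(x)
  expression_matrix(out, "quantile_normalized")
}

#' Batch baseline subtraction via a common reference library
#'
#' Corrects additive batch effects using the one library hybridised in every
#' batch: per gene, the difference between the reference's value in batch
#' *b* and in batch 1 is subtracted from every batch-*b* library. Batch-1
#' libraries pass through unchanged and the redundant reference copies are
#' dropped (the batch-1 copy is kept under its plain library id).
#'
#' Columns of `em` must correspond to design rows in order, with the
#' reference's copies named `<library_id>@<batch>`.
#'
#' @param em probe/gene x library [expression_matrix()] (`"rma_log2"`).
#' @param design an `osmo_design` with `batch` and `reference` columns;
#'   exactly one reference copy per batch.
#' @return list with `expr` (scale `"batch_corrected"`), `design` (reference
#'   copies collapsed to one row) and `offsets` (gene x batch matrix of the
#'   recovered corrections).
#' @export
batch_baseline_subtract <- function(em, design) {
  assert_scale(em, c("rma_log2", "log2_pedestalled"), "batch_baseline_subtract")
  if (!inherits(design, "osmo_design")) stopf("'design' must be an osmo_design")
  if (nrow(design) != ncol(em$values))
    stopf("design rows must match expression columns")
  batches <- unique(design$batch)
  if (length(batches) == 1L) {
    out <- expression_matrix(em$values, "batch_corrected")
    return(list(expr = out, design = design,
                offsets = matrix(0, nrow(em$values), 1,
                                 dimnames = list(rownames(em$values), batches))))
  }
  refs <- design$reference
  for (b in batches) {
    nb <- sum(refs & design$batch == b)
    if (nb != 1L)
      stopf("batch '%s' has %d reference copies (need exactly 1)", b, nb)
  }
  ref_id <- unique(design$library_id[refs])
  if (length(ref_id) != 1L)
    stopf("reference copies must come from one library, got: %s",
          paste(ref_id, collapse = ", "))
  b1 <- batches[1]
  ref_col <- function(b) which(refs & design$batch == b)
  vals <- em$values
  offsets <- matrix(0, nrow(vals), length(batches),
                    dimnames = list(rownames(vals), batches))
  for (b in batches[-1]) {
    delta <- vals[, ref_col(b)] - vals[, ref_col(b1)]
    offsets[, b] <- delta
    in_b <- design$batch == b
    vals[, in_b] <- vals[, in_b, drop = FALSE] - delta
  }
  # drop redundant reference copies, keep the batch-1 copy under its id
  drop <- refs & design$batch != b1
  vals <- vals[, !drop, drop = FALSE]
  design2 <- design[!drop, , drop = FALSE]
  colnames(vals)[design2$reference] <- ref_id
  list(expr = expression_matrix(vals, "batch_corrected"),
       design = design2, offsets = offsets)
}
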