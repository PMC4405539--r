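# Lightweight S3 containers for the pipeline's core data. These deliberately
# mirror what the workflow carries at each stage: integer read-pair counts
# with gene lengths on entry, real-valued expression with an explicit scale
# tag afterwards. The scale tag is what lets each stage refuse input produced
# out of order.

# Admissible scale-tag transitions. "rpkm" opens the RNA-seq branch,
# "rma_log2" the microarray branch (post-RMA log2 values).
.SCALES <- c("rpkm", "log2_pedestalled", "quantile_normalized",
             "rma_log2", "batch_corrected", "floored")

#' Construct a gene x library count matrix
#'
#' Entry point of the RNA-seq branch: integer read-pair counts per gene and
#' library plus per-gene transcript lengths in nucleotides.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   libraries in columns (colnames = library ids).
#' @param gene_lengths positive integer vector, one length per gene, either
#'   named by gene id or in row order of `counts`.
#' @return An object of class `count_matrix` with elements `counts` and
#'   `gene_lengths`.
#' @export
count_matrix <- function(counts, gene_lengths) {
  if (!is.matrix(counts)) stopf("'counts' must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("'counts' must carry gene ids as rownames and library ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicated gene id(s): %s",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stopf("duplicated library id(s): %s",
          paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be finite non-negative integers")
  storage.mode(counts) <- "integer"
  if (!is.null(names(gene_lengths))) {
    missing <- setdiff(rownames(counts), names(gene_lengths))
    if (length(missing))
      stopf("gene length missing for: %s", paste(utils::head(missing, 10), collapse = ", "))
    gene_lengths <- gene_lengths[rownames(counts)]
  } else if (length(gene_lengths) != nrow(counts)) {
    stopf("'gene_lengths' must be named or match nrow(counts)")
  }
  gene_lengths <- as.numeric(gene_lengths)
  if (any(!is.finite(gene_lengths)) || any(gene_lengths <= 0))
    stopf("gene lengths must be positive")
  names(gene_lengths) <- rownames(counts)
  structure(list(counts = counts, gene_lengths = gene_lengths),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d libraries (read pairs)\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Construct an expression matrix with an explicit scale tag
#'
#' @param values numeric matrix (genes x libraries) with dimnames.
#' @param scale one of `"rpkm"`, `"log2_pedestalled"`, `"quantile_normalized"`,
#'   `"rma_log2"`, `"batch_corrected"`, `"floored"`. The tag records where in
#'   the workflow the values stand; downstream operations refuse matrices
#'   carrying the wrong tag.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, scale) {
  if (!is.matrix(values) || !is.numeric(values)) stopf("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("'values' must carry gene ids as rownames and library ids as colnames")
  if (any(!is.finite(values))) stopf("expression values must be finite")
  scale <- match.arg(scale, .SCALES)
  structure(list(values = values, scale = scale), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s]: %d genes x %d libraries\n",
              x$scale, nrow(x$values), ncol(x$values)))
  invisible(x)
}

# Refuse matrices produced out of workflow order.
assert_scale <- function(em, allowed, op) {
  if (!inherits(em, "expression_matrix"))
    stopf("%s() expects an expression_matrix", op)
  if (!em$scale %in% allowed)
    stopf("%s() requires scale %s but got '%s' (stage-order violation)",
          op, paste(sprintf("'%s'", allowed), collapse = " or "), em$scale)
  invisible(em)
}

#' Construct a sample design table
#'
#' @param library_id character vector of library ids (unique).
#' @param class class label per library (two classes needed for testing).
#' @param batch optional batch label per library (microarray).
#' @param reference optional logical: the common reference library run in
#'   every batch (used by [batch_baseline_subtract()]).
#' @return data.frame of class `osmo_design`.
#' @export
design_table <- function(library_id, class, batch = NULL, reference = NULL) {
  library_id <- as.character(library_id)
  if (anyDuplicated(library_id)) {
    # the one sanctioned duplication is the reference library run in >1 batch
    dup <- unique(library_id[duplicated(library_id)])
    if (is.null(reference) || !all(dup %in% library_id[as.logical(reference)]))
      stopf("duplicated library id(s) without reference flag: %s",
            paste(dup, collapse = ", "))
  }
  n <- length(library_id)
  if (length(class) != n) stopf("'class' must match 'library_id' length")
  d <- data.frame(library_id = library_id, class = as.character(class),
                  stringsAsFactors = FALSE)
  d$batch <- if (is.null(batch)) rep("b1", n) else as.character(batch)
  d$reference <- if (is.null(reference)) rep(FALSE, n) else as.logical(reference)
  class(d) <- c("osmo_design", "data.frame")
  d
}
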