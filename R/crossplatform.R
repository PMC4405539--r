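# Cross-platform comparison: collapse probe-level results to gene symbols,
# intersect presence / differential sets between platforms, and measure
# fold-change concordance on the shared genes. Symbols are compared
# case-insensitively with surrounding whitespace stripped, since reporting
# conventions mix capitalisations.

norm_symbol <- function(x) toupper(trimws(as.character(x)))

#' Collapse a probe-level table to gene symbols
#'
#' A symbol is present (or differentially expressed) iff at least one of its
#' probes is; the symbol-level fold change is taken from the probe with the
#' largest `|signed_fc|` (configurable: `"max_abs"`, `"mean"` of signed
#' values, or `"first"` in probe order). Probes without a mapping are
#' excluded and reported.
#'
#' @param probe_table data.frame with a `probe_id` column and, as available,
#'   `signed_fc` and `selected` columns.
#' @param map named character vector probe_id -> symbol ([probe_map()]).
#' @param mode `"presence"` (every probe row counts) or `"de"` (only rows
#'   with `selected == TRUE` make a symbol differential).
#' @param fc_rule how multi-probe fold changes are summarised to one value.
#' @return list with `table` (one row per unique symbol: `symbol`,
#'   `signed_fc`, `n_probes`, and for mode "de" a `selected` flag) and
#'   `unmapped` (excluded probe ids).
#' @export
collapse_probes <- function(probe_table, map,
                            mode = c("presence", "de"),
                            fc_rule = c("max_abs", "mean", "first")) {
  mode <- match.arg(mode)
  fc_rule <- match.arg(fc_rule)
  if (!length(map)) stopf("empty probe map")
  if (!"probe_id" %in% names(probe_table)) stopf("probe_table needs a probe_id column")
  pid <- as.character(probe_table$probe_id)
  mapped <- pid %in% names(map)
  unmapped <- pid[!mapped]
  tab <- probe_table[mapped, , drop = FALSE]
  sym <- norm_symbol(map[as.character(tab$probe_id)])
  fc <- if ("signed_fc" %in% names(tab)) tab$signed_fc else rep(NA_real_, nrow(tab))
  sel <- if ("selected" %in% names(tab)) tab$selected else rep(TRUE, nrow(tab))
  rows <- lapply(split(seq_len(nrow(tab)), sym), function(ii) {
    f <- fc[ii]
    rep_fc <- switch(fc_rule,
      max_abs = if (all(is.na(f))) NA_real_ else f[order(-abs(f), ii)][1],
      mean = mean(f),
      first = f[1])
    data.frame(signed_fc = rep_fc, n_probes = length(ii),
               selected = any(sel[ii]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- data.frame(symbol = names(rows), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (mode == "de") out <- out[out$selected, , drop = FALSE]
  list(table = out, unmapped = unmapped)
}

#' Two-set Venn partition
#'
#' Exact partition of two id sets (normalised case-insensitively) into
#' exclusive and shared members; the three parts are pairwise disjoint and
#' their counts reconcile additively with the input set sizes.
#'
#' @param a,b character vectors of ids.
#' @return object of class `venn_result`: `only_a`, `both`, `only_b`, and
#'   `counts` (named integer vector including `size_a`, `size_b`).
#' @export
venn_sets <- function(a, b) {
  a <- unique(norm_symbol(a)); b <- unique(norm_symbol(b))
  both <- intersect(a, b)
  only_a <- setdiff(a, b); only_b <- setdiff(b, a)
  structure(list(only_a = only_a, both = both, only_b = only_b,
                 counts = c(only_a = length(only_a), both = length(both),
                            only_b = length(only_b),
                            size_a = length(a), size_b = length(b))),
            class = "venn_result")
}

#' @export
print.venn_result <- function(x, ...) {
  cat(sprintf("venn: |A|=%d (%d only), |A&B|=%d, |B|=%d (%d only)\n",
              x$counts["size_a"], x$counts["only_a"], x$counts["both"],
              x$counts["size_b"], x$counts["only_b"]))
  invisible(x)
}

#' Fold-change concordance between platforms
#'
#' Signed linear fold changes from two platforms on shared symbols are
#' converted to signed log2 (log2 of the magnitude carrying the sign of the
#' change) and their Pearson correlation computed, with the paired table
#' returned for plotting.
#'
#' @param shared data.frame with columns `symbol`, `fc_a`, `fc_b` (signed
#'   linear fold changes; >= 3 rows).
#' @return list with `table` (adds `log2fc_a`, `log2fc_b`) and `r`.
#' @export
concordance <- function(shared) {
  need <- c("symbol", "fc_a", "fc_b")
  if (!all(need %in% names(shared)))
    stopf("'shared' must have columns: %s", paste(need, collapse = ", "))
  if (nrow(shared) < 3) stopf("need >= 3 shared symbols")
  slog2 <- function(f) sign(f) * log2(abs(f))
  tab <- shared
  tab$log2fc_a <- slog2(shared$fc_a)
  tab$log2fc_b <- slog2(shared$fc_b)
  list(table = tab, r = stats::cor(tab$log2fc_a, tab$log2fc_b))
}
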