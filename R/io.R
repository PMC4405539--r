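# Readers and writers for the pipeline's tabular formats. Dialect is fixed:
# tab-separated, '.' decimal, no quoting, first column the identifier,
# header row of library ids. Readers validate and reject rather than coerce.

read_tsv_strict <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read a gene x library count matrix with gene lengths
#'
#' @param path TSV of integer read-pair counts: first column gene id, one
#'   column per library.
#' @param lengths_path gene-length annotation: a two-column TSV
#'   (`gene_id`, `length`), or a GTF/BED file (see [gene_lengths_from_annotation()]);
#'   format sniffed from the file extension.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, lengths_path) {
  tab <- read_tsv_strict(path)
  if (ncol(tab) < 2) stopf("count table needs an id column plus >=1 library")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stopf("duplicated gene id(s) in %s: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stopf("non-numeric count cell(s) in %s", path)
  if (any(m != round(m))) stopf("non-integer count cell(s) in %s", path)
  rownames(m) <- ids
  lens <- gene_lengths_from_annotation(lengths_path)
  missing <- setdiff(ids, names(lens))
  if (length(missing))
    stopf("gene length missing for: %s", paste(utils::head(missing, 10), collapse = ", "))
  count_matrix(m, lens[ids])
}

#' @rdname read_counts
#' @param cm a [count_matrix()] to write.
#' @param lengths_path for `write_counts`, where to write the two-column
#'   gene-length table accompanying the counts.
#' @export
write_counts <- function(cm, path, lengths_path) {
  if (!inherits(cm, "count_matrix")) stopf("'cm' must be a count_matrix")
  tab <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = names(cm$gene_lengths), length = cm$gene_lengths),
    lengths_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene lengths from a TSV, GTF or BED annotation
#'
#' For GTF (1-based inclusive) and BED (0-based half-open) the per-gene
#' length is the plain sum of exon feature lengths carrying that gene id;
#' parsing is done by `rtracklayer::import`, which normalises both
#' conventions to 1-based closed ranges, so `width` is the feature length in
#' either case. For BED the `name` column is taken as the gene id.
#'
#' @param path annotation file (.tsv/.txt, .gtf/.gff, or .bed).
#' @param format override the extension-based format guess.
#' @return named numeric vector of lengths (nt) per gene id.
#' @export
gene_lengths_from_annotation <- function(path,
                                         format = c("auto", "tsv", "gtf", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gtf = "gtf", gff = "gtf", gff3 = "gtf",
                     bed = "bed", "tsv")
  }
  if (format == "tsv") {
    tab <- read_tsv_strict(path)
    if (ncol(tab) < 2) stopf("length table needs id and length columns")
    lens <- as.numeric(tab[[2]])
    if (any(!is.finite(lens)) || any(lens <= 0))
      stopf("non-positive or missing gene length in %s", path)
    ids <- as.character(tab[[1]])
    if (anyDuplicated(ids)) stopf("duplicated gene id in length table")
    names(lens) <- ids
    return(lens)
  }
  gr <- rtracklayer::import(path, format = format)
  df <- as.data.frame(gr)
  id <- if (format == "gtf") {
    if (is.null(df$gene_id)) stopf("GTF lacks gene_id attribute")
    exon <- if (!is.null(df$type)) df$type == "exon" else rep(TRUE, nrow(df))
    df <- df[exon, , drop = FALSE]
    df$gene_id
  } else {
    if (is.null(df$name)) stopf("BED lacks a name column for gene ids")
    df$name
  }
  sums <- tapply(df$width, id, sum)
  stats::setNames(as.numeric(sums[unique(id)]), unique(id))
}

#' Write / read an expression matrix as TSV
#'
#' The scale tag is preserved in a `# scale: <tag>` comment line above the
#' header so round-trips restore the workflow position.
#'
#' @param em an [expression_matrix()].
#' @param path output file.
#' @return `write_expression` returns `path` invisibly; `read_expression`
#'   returns an [expression_matrix()].
#' @export
write_expression <- function(em, path) {
  if (!inherits(em, "expression_matrix")) stopf("'em' must be an expression_matrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scale: %s", em$scale), con)
  writeLines(paste(c("gene_id", colnames(em$values)), collapse = "\t"), con)
  utils::write.table(format(em$values, trim = TRUE, digits = 15, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  first <- readLines(path, n = 1)
  scale <- sub("^# scale: *", "", first)
  if (identical(scale, first)) stopf("missing '# scale:' header line in %s", path)
  tab <- read_tsv_strict(path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  expression_matrix(m, scale)
}

#' Read a design table (library_id, class, batch, reference)
#'
#' @param path TSV with columns `library_id` and `class`; optional `batch`
#'   and logical `reference`.
#' @return an `osmo_design` data.frame.
#' @export
read_design <- function(path) {
  tab <- read_tsv_strict(path)
  need <- c("library_id", "class")
  if (!all(need %in% names(tab)))
    stopf("design table must have columns: %s", paste(need, collapse = ", "))
  design_table(tab$library_id, tab$class, batch = tab$batch,
               reference = if (!is.null(tab$reference)) as.logical(tab$reference))
}

#' Read a probe-to-gene-symbol map
#'
#' Every probe must map to exactly one non-empty symbol; many probes per
#' symbol are allowed.
#'
#' @param path TSV with columns `probe_id`, `symbol`.
#' @return named character vector: `map[probe_id] == symbol`.
#' @export
read_probe_map <- function(path) {
  tab <- read_tsv_strict(path)
  if (!all(c("probe_id", "symbol") %in% names(tab)))
    stopf("probe map must have columns probe_id, symbol")
  probe_map(tab$probe_id, tab$symbol)
}

#' @rdname read_probe_map
#' @param probe_id,symbol vectors defining the mapping directly.
#' @export
probe_map <- function(probe_id, symbol) {
  probe_id <- as.character(probe_id); symbol <- as.character(symbol)
  if (anyDuplicated(probe_id))
    stopf("probe(s) mapped more than once: %s",
          paste(unique(probe_id[duplicated(probe_id)]), collapse = ", "))
  if (any(is.na(symbol) | !nzchar(trimws(symbol)))) stopf("empty gene symbol in probe map")
  stats::setNames(symbol, probe_id)
}

#' Write a differential-expression table in the report layout
#'
#' Columns `Gene Symbol / Mean Control / Mean SL / Fold Change / Corrected P`;
#' means and fold change printed to 2 decimals (presentation rounding only —
#' the in-memory table keeps full precision).
#'
#' @param de a data.frame as returned by [de_table()] (needs columns
#'   `gene_id`, `mean_control`, `mean_treated`, `signed_fc`, `p_bh`).
#' @param path output TSV.
#' @export
write_de_table <- function(de, path) {
  need <- c("gene_id", "mean_control", "mean_treated", "signed_fc", "p_bh")
  if (!all(need %in% names(de)))
    stopf("DE table must have columns: %s", paste(need, collapse = ", "))
  out <- data.frame(
    `Gene Symbol`  = de$gene_id,
    `Mean Control` = sprintf("%.2f", de$mean_control),
    `Mean SL`      = sprintf("%.2f", de$mean_treated),
    `Fold Change`  = sprintf("%.2f", de$signed_fc),
    `Corrected P`  = sprintf("%.3f", de$p_bh),
    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) {
  tab <- read_tsv_strict(path)
  data.frame(gene_id = as.character(tab[["Gene Symbol"]]),
             mean_control = as.numeric(tab[["Mean Control"]]),
             mean_treated = as.numeric(tab[["Mean SL"]]),
             signed_fc = as.numeric(tab[["Fold Change"]]),
             p_bh = as.numeric(tab[["Corrected P"]]),
             stringsAsFactors = FALSE)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member ids, tab-separated.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("malformed GMT line: %s", substr(l, 1, 40))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Read a qPCR Ct table
#'
#' @param path TSV with columns `sample`, `group`, `target_ct`, `calibrator_ct`.
#' @return data.frame suitable for [ddct_fold_change()].
#' @export
read_qpcr <- function(path) {
  tab <- read_tsv_strict(path)
  need <- c("sample", "group", "target_ct", "calibrator_ct")
  if (!all(need %in% names(tab)))
    stopf("qPCR table must have columns: %s", paste(need, collapse = ", "))
  if (any(!is.finite(tab$target_ct)) || any(!is.finite(tab$calibrator_ct)))
    stopf("missing Ct measurement(s) in %s", path)
  tab
}

#' RNA-yield report for a two-class sample table
#'
#' Summarises per-sample RNA yields by condition and reports the ratio of
#' class-average yields (treated over control). Published sample tables often
#' print an average that is a given constant rather than the arithmetic mean
#' of the printed rows; pass such printed averages via `printed_averages` to
#' have the ratio computed from them (the recomputed row means are still
#' reported alongside).
#'
#' @param samples data.frame with columns `condition`, `sample`, `yield`
#'   (and optionally `rin`).
#' @param control,treated the two condition labels.
#' @param printed_averages optional named numeric, e.g.
#'   `c(Normosmotic = 335, `Salt-Loaded` = 652)`: class averages to take as
#'   given when computing the ratio.
#' @return list with per-class `mean_yield` (recomputed), `average_used`,
#'   and `ratio` (treated/control, rounded to 2 decimals).
#' @export
sample_yield_report <- function(samples, control, treated,
                                printed_averages = NULL) {
  need <- c("condition", "sample", "yield")
  if (!all(need %in% names(samples)))
    stopf("sample table must have columns: %s", paste(need, collapse = ", "))
  for (cl in c(control, treated))
    if (!cl %in% samples$condition) stopf("condition '%s' absent from table", cl)
  recomputed <- tapply(samples$yield, samples$condition, mean)
  used <- recomputed[c(control, treated)]
  if (!is.null(printed_averages)) {
    if (!all(c(control, treated) %in% names(printed_averages)))
      stopf("'printed_averages' must name both conditions")
    used <- printed_averages[c(control, treated)]
  }
  list(mean_yield = recomputed,
       average_used = used,
       ratio = round(unname(used[treated] / used[control]), 2))
}
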