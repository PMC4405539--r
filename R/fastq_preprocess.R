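# Paired-end read cleaning: 3' adapter clipping, fixed head/tail trimming,
# quality-based end trimming, and pair-level ambiguity/length filtering.
# Rule values default to the workflow this package implements: 15 nt head
# trim, 1 nt tail trim, 95% minimum call accuracy (Phred <= 13 fails on the
# offset-33 scale), at most 2 ambiguous bases per read, 15 nt minimum length.

#' Read-pair cleaning rules
#'
#' @param adapter 3' adapter sequence to clip (DNA string, >= `min_overlap` nt).
#' @param head_trim bases removed unconditionally from the 5' end.
#' @param tail_trim bases removed unconditionally from the 3' end.
#' @param min_call_accuracy terminal bases whose call accuracy
#'   (`1 - 10^(-Q/10)`) falls below this are trimmed from the ends inward.
#' @param max_ambiguities maximum non-ACGT bases tolerated per read.
#' @param min_length pairs with any mate shorter than this are discarded.
#' @param min_overlap minimum 3'-end suffix/adapter-prefix overlap for a
#'   partial adapter match.
#' @return validated list of class `preprocess_rules`.
#' @export
preprocess_rules <- function(adapter = "AGATCGGAAGAGC",
                             head_trim = 15L, tail_trim = 1L,
                             min_call_accuracy = 0.95,
                             max_ambiguities = 2L,
                             min_length = 15L,
                             min_overlap = 5L) {
  assert_scalar_number(head_trim, "head_trim", integer = TRUE)
  assert_scalar_number(tail_trim, "tail_trim", integer = TRUE)
  if (head_trim < 0 || tail_trim < 0) stopf("trims must be >= 0")
  assert_scalar_number(min_call_accuracy, "min_call_accuracy")
  if (min_call_accuracy <= 0 || min_call_accuracy >= 1)
    stopf("'min_call_accuracy' must lie in (0, 1)")
  assert_scalar_number(max_ambiguities, "max_ambiguities", integer = TRUE)
  assert_scalar_number(min_length, "min_length", positive = TRUE, integer = TRUE)
  assert_scalar_number(min_overlap, "min_overlap", positive = TRUE, integer = TRUE)
  if (nchar(adapter) < min_overlap)
    stopf("adapter shorter than min_overlap (%d nt)", min_overlap)
  if (grepl("[^ACGT]", adapter)) stopf("adapter must be an ACGT string")
  structure(list(adapter = adapter, head_trim = as.integer(head_trim),
                 tail_trim = as.integer(tail_trim),
                 min_call_accuracy = min_call_accuracy,
                 max_ambiguities = as.integer(max_ambiguities),
                 min_length = as.integer(min_length),
                 min_overlap = as.integer(min_overlap)),
            class = "preprocess_rules")
}

#' A set of FASTQ records held in memory
#'
#' Vectorised container: parallel character vectors of ids, sequences and
#' offset-33 quality strings.
#'
#' @param id,seq,qual character vectors of equal length; `nchar(seq)` must
#'   equal `nchar(qual)` record by record.
#' @return object of class `fastq_reads`.
#' @export
fastq_reads <- function(id, seq, qual) {
  id <- as.character(id); seq <- as.character(seq); qual <- as.character(qual)
  if (length(seq) != length(id) || length(qual) != length(id))
    stopf("id, seq and qual must have equal length")
  if (any(nchar(seq) != nchar(qual)))
    stopf("sequence/quality length mismatch in record(s): %s",
          paste(utils::head(id[nchar(seq) != nchar(qual)], 5), collapse = ", "))
  structure(list(id = id, seq = seq, qual = qual), class = "fastq_reads")
}

#' @export
length.fastq_reads <- function(x) length(x$id)

#' @export
`[.fastq_reads` <- function(x, i) fastq_reads(x$id[i], x$seq[i], x$qual[i])

#' @export
print.fastq_reads <- function(x, ...) {
  cat(sprintf("fastq_reads: %d records\n", length(x$id)))
  invisible(x)
}

phred <- function(qual_string) utf8ToInt(qual_string) - 33L

# Highest integer Phred score still failing the accuracy rule.
phred_fail_max <- function(min_call_accuracy)
  as.integer(floor(-10 * log10(1 - min_call_accuracy) - 1e-9))

#' Clip a 3' adapter from reads
#'
#' The earliest full occurrence of the adapter, or failing that the longest
#' 3'-end suffix of the read matching a prefix of the adapter with at least
#' `min_overlap` bases (exact match, no mismatches), truncates sequence and
#' qualities at the match start. Reads without a match are unchanged.
#'
#' @param reads a [fastq_reads()].
#' @param adapter adapter sequence.
#' @param min_overlap minimum partial-overlap length.
#' @return clipped [fastq_reads()].
#' @export
clip_adapter <- function(reads, adapter, min_overlap = 5L) {
  if (!inherits(reads, "fastq_reads")) stopf("'reads' must be fastq_reads")
  if (nchar(adapter) < min_overlap) stopf("adapter shorter than min_overlap")
  cut_at <- vapply(reads$seq, function(s) {
    p <- regexpr(adapter, s, fixed = TRUE)
    if (p > 0) return(as.integer(p))
    n <- nchar(s)
    for (k in seq(min(nchar(adapter) - 1L, n), min_overlap)) {
      if (substr(s, n - k + 1L, n) == substr(adapter, 1L, k))
        return(n - k + 1L)
    }
    0L
  }, integer(1), USE.NAMES = FALSE)
  keep_to <- ifelse(cut_at > 0, cut_at - 1L, nchar(reads$seq))
  fastq_reads(reads$id,
              substr(reads$seq, 1L, keep_to),
              substr(reads$qual, 1L, keep_to))
}

#' Trim reads: fixed head/tail removal plus quality end-trimming
#'
#' Removes `head_trim` bases from the 5' end and `tail_trim` from the 3'
#' end, then trims further from both ends inward while the terminal base's
#' call accuracy is below `min_call_accuracy`. Qualities stay aligned with
#' the sequence. Reads may come back empty; short reads are handled by the
#' pair filter, not here.
#'
#' @param reads a [fastq_reads()].
#' @param rules a [preprocess_rules()].
#' @return trimmed [fastq_reads()].
#' @export
trim_read <- function(reads, rules) {
  if (!inherits(rules, "preprocess_rules")) stopf("'rules' must be preprocess_rules")
  qfail <- phred_fail_max(rules$min_call_accuracy)
  n <- nchar(reads$seq)
  from <- pmin(rules$head_trim + 1L, n + 1L)
  to <- pmax(n - rules$tail_trim, from - 1L)
  seqs <- substr(reads$seq, from, to)
  quals <- substr(reads$qual, from, to)
  for (i in seq_along(seqs)) {
    q <- if (nchar(quals[i])) phred(quals[i]) else integer(0)
    lo <- 1L; hi <- length(q)
    while (lo <= hi && q[lo] <= qfail) lo <- lo + 1L
    while (hi >= lo && q[hi] <= qfail) hi <- hi - 1L
    if (lo > hi) { seqs[i] <- ""; quals[i] <- "" }
    else { seqs[i] <- substr(seqs[i], lo, hi); quals[i] <- substr(quals[i], lo, hi) }
  }
  fastq_reads(reads$id, seqs, quals)
}

count_ambiguities <- function(seq) nchar(gsub("[ACGT]", "", seq))

#' Filter synchronized read pairs on length and ambiguity
#'
#' A pair survives iff both mates are at least `min_length` long and neither
#' mate carries more than `max_ambiguities` non-ACGT bases. The first
#' matching discard reason wins, checked in the order length, ambiguity.
#'
#' @param r1,r2 trimmed mates as [fastq_reads()], same ids in the same order
#'   (a trailing `/1`, `/2` or ` 1:`-style tag may differ).
#' @param rules a [preprocess_rules()].
#' @return list with `r1`, `r2` (kept pairs), `keep` (logical per input
#'   pair), and `stats` (input/kept/discard-reason counts).
#' @export
filter_pairs <- function(r1, r2, rules) {
  if (length(r1) != length(r2)) stopf("mate files differ in record count")
  base_id <- function(id) sub("[/ ].*$", "", id)
  b1 <- base_id(r1$id); b2 <- base_id(r2$id)
  bad <- which(b1 != b2)
  if (length(bad))
    stopf("desynchronized mates at record %d: '%s' vs '%s'",
          bad[1], r1$id[bad[1]], r2$id[bad[1]])
  len_ok <- nchar(r1$seq) >= rules$min_length & nchar(r2$seq) >= rules$min_length
  amb_ok <- count_ambiguities(r1$seq) <= rules$max_ambiguities &
            count_ambiguities(r2$seq) <= rules$max_ambiguities
  keep <- len_ok & amb_ok
  reason <- ifelse(keep, "kept", ifelse(!len_ok, "length", "ambiguity"))
  list(r1 = r1[keep], r2 = r2[keep], keep = keep,
       stats = list(input = length(keep),
                    kept = sum(keep),
                    discarded_length = sum(reason == "length"),
                    discarded_ambiguity = sum(reason == "ambiguity")))
}

#' Full pair-cleaning pipeline on in-memory reads
#'
#' Clips the adapter from both mates, trims them, then applies the pair
#' filter.
#'
#' @inheritParams filter_pairs
#' @return as [filter_pairs()].
#' @export
preprocess_pairs <- function(r1, r2, rules = preprocess_rules()) {
  r1 <- trim_read(clip_adapter(r1, rules$adapter, rules$min_overlap), rules)
  r2 <- trim_read(clip_adapter(r2, rules$adapter, rules$min_overlap), rules)
  filter_pairs(r1, r2, rules)
}

#' Read / write FASTQ files
#'
#' Thin wrappers over Biostrings with offset-33 qualities.
#'
#' @param path FASTQ file (optionally gzip-compressed on read).
#' @param reads a [fastq_reads()].
#' @return `read_fastq` returns a [fastq_reads()]; `write_fastq` returns
#'   `path` invisibly.
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping (empty) metadata columns while pairing
  # sequences with qualities; that is expected here, not a data problem
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  fastq_reads(names(x), as.character(x),
              as.character(Biostrings::quality(x)))
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Preprocess a pair of FASTQ files on disk
#'
#' @param in1,in2 input mate files.
#' @param out1,out2 output mate files for kept pairs.
#' @param rules a [preprocess_rules()].
#' @param stats_path optional path for the filter statistics as JSON.
#' @return the filter statistics list, invisibly.
#' @export
preprocess_fastq_files <- function(in1, in2, out1, out2,
                                   rules = preprocess_rules(),
                                   stats_path = NULL) {
  res <- preprocess_pairs(read_fastq(in1), read_fastq(in2), rules)
  write_fastq(res$r1, out1)
  write_fastq(res$r2, out2)
  if (!is.null(stats_path))
    jsonlite::write_json(res$stats, stats_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(res$stats)
}
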