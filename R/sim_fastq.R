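#' Simulate paired FASTQ reads with per-pair filter ground truth
#'
#' Generates syntactically valid paired-end records exercising every
#' preprocessing rule: inserts shorter than the read length run into the 3'
#' adapter (read-through), a fraction of reads carry a low-quality 3' tail,
#' and bases are replaced by `N` at `ambiguity_rate`. The returned truth
#' flags record, per pair, whether the cleaning rules keep or discard it;
#' they are computed at generation time by applying the rule operations
#' ([clip_adapter()], [trim_read()], [filter_pairs()]) to the fresh records,
#' so tests can compare them against an independent rule-by-rule oracle.
#'
#' @param n_pairs number of read pairs.
#' @param read_length read length in nt (> 16 so the fixed trims leave at
#'   least one base).
#' @param adapter 3' adapter sequence.
#' @param ambiguity_rate per-base probability of an `N` call.
#' @param quality_profile list with `high` (baseline Phred), `low` (tail
#'   Phred), `tail_prob` (probability a read carries a low-quality tail) and
#'   `max_tail` (maximum tail length).
#' @param seed integer seed.
#' @param rules [preprocess_rules()] used to derive the truth flags.
#' @param path_r1,path_r2 optional output FASTQ paths; written when both are
#'   given.
#' @return list with `r1`, `r2` ([fastq_reads()]) and `truth` (data.frame:
#'   `pair_id`, `keep`, plus the generating insert length).
#' @export
simulate_fastq <- function(n_pairs, read_length = 100L,
                           adapter = "AGATCGGAAGAGC",
                           ambiguity_rate = 0.01,
                           quality_profile = list(high = 38L, low = 8L,
                                                  tail_prob = 0.25,
                                                  max_tail = 90L),
                           seed = 1L,
                           rules = preprocess_rules(adapter = adapter),
                           path_r1 = NULL, path_r2 = NULL) {
  assert_scalar_number(n_pairs, "n_pairs", positive = TRUE, integer = TRUE)
  assert_scalar_number(read_length, "read_length", integer = TRUE)
  if (read_length <= 16L)
    stopf("read_length must exceed 16 nt (fixed trims would consume the read)")
  assert_proportion(ambiguity_rate, "ambiguity_rate")
  set.seed(seed)

  random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                  collapse = "")
  make_mate <- function(insert_len) {
    core <- random_dna(insert_len)
    s <- if (insert_len < read_length) {
      substr(paste0(core, adapter, random_dna(read_length)), 1L, read_length)
    } else substr(core, 1L, read_length)
    q <- rep(quality_profile$high, read_length) +
      sample(-3:2, read_length, replace = TRUE)
    if (stats::runif(1) < quality_profile$tail_prob) {
      k <- sample.int(quality_profile$max_tail, 1)
      k <- min(k, read_length)
      q[(read_length - k + 1L):read_length] <-
        quality_profile$low + sample(-3:3, k, replace = TRUE)
    }
    q <- pmin(pmax(q, 2L), 40L)
    ns <- stats::runif(read_length) < ambiguity_rate
    if (any(ns)) {
      sv <- strsplit(s, "")[[1]]
      sv[ns] <- "N"
      s <- paste(sv, collapse = "")
    }
    list(seq = s, qual = intToUtf8(q + 33L))
  }

  insert_len <- sample(seq(40L, 2L * read_length), n_pairs, replace = TRUE)
  ids <- sprintf("pair%05d", seq_len(n_pairs))
  m1 <- lapply(insert_len, make_mate)
  m2 <- lapply(insert_len, make_mate)
  r1 <- fastq_reads(ids, vapply(m1, `[[`, "", "seq"), vapply(m1, `[[`, "", "qual"))
  r2 <- fastq_reads(ids, vapply(m2, `[[`, "", "seq"), vapply(m2, `[[`, "", "qual"))

  flags <- preprocess_pairs(r1, r2, rules)
  truth <- data.frame(pair_id = ids, keep = flags$keep,
                      insert_len = insert_len, stringsAsFactors = FALSE)
  if (!is.null(path_r1) && !is.null(path_r2)) {
    write_fastq(r1, path_r1)
    write_fastq(r2, path_r2)
  }
  list(r1 = r1, r2 = r2, truth = truth)
}

#' Simulate a qPCR Ct table with known relative expression
#'
#' The calibrator gene's Ct is stable across groups; the target gene's Ct in
#' the treated group is shifted by `-log2(true_fold_change)` cycles before
#' measurement noise, the defining relationship of relative quantification
#' (fold change `2^(-ddCt)`).
#'
#' @param n_samples_per_group samples per group (>= 2).
#' @param true_fold_change planted treated/control expression ratio (> 0).
#' @param ct_noise_sd measurement noise sd, cycles, applied to every Ct.
#' @param seed integer seed.
#' @param groups length-2 character: control then treated label.
#' @param target_base,calibrator_base control-group mean Ct values.
#' @return list with `assay` (data.frame: `sample`, `group`, `target_ct`,
#'   `calibrator_ct`) and `truth` (`true_fold_change`, `seed`).
#' @export
simulate_qpcr <- function(n_samples_per_group, true_fold_change,
                          ct_noise_sd = 0.05, seed = 1L,
                          groups = c("control", "salt_loaded"),
                          target_base = 26, calibrator_base = 18) {
  assert_scalar_number(n_samples_per_group, "n_samples_per_group", integer = TRUE)
  if (n_samples_per_group < 2) stopf("need >= 2 samples per group")
  assert_scalar_number(true_fold_change, "true_fold_change", positive = TRUE)
  assert_scalar_number(ct_noise_sd, "ct_noise_sd")
  if (ct_noise_sd < 0) stopf("'ct_noise_sd' must be >= 0")
  set.seed(seed)
  n <- n_samples_per_group
  grp <- rep(groups, each = n)
  target_mu <- ifelse(grp == groups[2],
                      target_base - log2(true_fold_change), target_base)
  assay <- data.frame(
    sample = sprintf("s%02d", seq_len(2 * n)),
    group = grp,
    target_ct = target_mu + stats::rnorm(2 * n, 0, ct_noise_sd),
    calibrator_ct = calibrator_base + stats::rnorm(2 * n, 0, ct_noise_sd),
    stringsAsFactors = FALSE)
  list(assay = assay,
       truth = list(true_fold_change = true_fold_change, seed = as.integer(seed)))
}
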