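rules <- preprocess_rules()

test_that("adapter clipping matches a naive search oracle", {
  # no occurrence: unchanged
  r <- fastq_reads("a", "ACGTACGTACGT", strrep("I", 12))
  expect_identical(clip_adapter(r, rules$adapter)$seq, "ACGTACGTACGT")

  # insert + full adapter: exactly the insert comes back
  insert <- "TTTTGGGGCCCCAAAA"
  r <- fastq_reads("b", paste0(insert, rules$adapter),
                   strrep("I", nchar(insert) + nchar(rules$adapter)))
  expect_identical(clip_adapter(r, rules$adapter)$seq, insert)

  # randomized reads with the adapter (or a 3' fragment of it) planted at
  # known positions: clip point equals the brute-force oracle's
  set.seed(42)
  for (i in 1:100) {
    ins_len <- sample(20:80, 1)
    ins <- paste(sample(c("A", "C", "G", "T"), ins_len, replace = TRUE),
                 collapse = "")
    keep_ad <- sample(nchar(rules$adapter), 1)
    s <- paste0(ins, substr(rules$adapter, 1, keep_ad))
    r <- fastq_reads("x", s, strrep("I", nchar(s)))
    got <- clip_adapter(r, rules$adapter, rules$min_overlap)$seq
    want <- oracle_clean_fixed(s, strrep("I", nchar(s)),
                               preprocess_rules(adapter = rules$adapter,
                                                head_trim = 0L, tail_trim = 0L))
    expect_identical(got, want$seq)
  }
})

test_that("trimming removes fixed ends then low-quality termini maximally", {
  # 100 nt, uniformly high quality: 15 + 1 = 16 bases removed
  r <- fastq_reads("a", strrep("A", 100), strrep("I", 100))
  out <- trim_read(r, rules)
  expect_identical(nchar(out$seq), 84L)
  expect_identical(nchar(out$qual), 84L)

  # a 16 nt read is consumed entirely
  r16 <- fastq_reads("b", strrep("A", 16), strrep("I", 16))
  expect_identical(trim_read(r16, rules)$seq, "")

  # random low-quality ends: equals the exhaustive end-trim oracle
  set.seed(7)
  qmax <- 13L  # accuracy 0.95 on the offset-33 scale
  for (i in 1:100) {
    n <- sample(30:120, 1)
    q <- sample(c(2:12, 30:40), n, replace = TRUE)
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    qual <- intToUtf8(q + 33L)
    got <- trim_read(fastq_reads("x", s, qual), rules)
    # fixed trims by hand, then the exhaustive end-trim oracle
    fixed <- if (n <= 16) list(seq = "", qual = "") else
      list(seq = substr(s, 16, n - 1), qual = substr(qual, 16, n - 1))
    want <- oracle_end_trim(fixed$seq, fixed$qual, qmax)
    expect_identical(got$seq, want$seq)
    expect_identical(got$qual, want$qual)
  }
})

test_that("trimming is idempotent once fixed trims are disabled", {
  notrim <- preprocess_rules(head_trim = 0L, tail_trim = 0L)
  set.seed(9)
  n <- 80
  q <- sample(c(2:12, 30:40), n, replace = TRUE)
  r <- fastq_reads("a",
                   paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""),
                   intToUtf8(q + 33L))
  once <- trim_read(r, notrim)
  twice <- trim_read(once, notrim)
  expect_identical(once$seq, twice$seq)
  expect_identical(once$qual, twice$qual)
})

test_that("pair filter applies length and ambiguity rules at the boundary", {
  mk <- function(seq) fastq_reads("p1", seq, strrep("I", nchar(seq)))
  # both mates exactly 15 nt, no Ns: kept (the rule is "< 15 nt" discards)
  res <- filter_pairs(mk(strrep("A", 15)), mk(strrep("C", 15)), rules)
  expect_true(res$keep)

  # one mate with 3 Ns: discarded ("more than two ambiguities")
  res <- filter_pairs(mk(paste0("NNN", strrep("A", 20))), mk(strrep("C", 20)), rules)
  expect_false(res$keep)
  expect_identical(res$stats$discarded_ambiguity, 1L)

  # exactly 2 Ns: kept
  res <- filter_pairs(mk(paste0("NN", strrep("A", 20))), mk(strrep("C", 20)), rules)
  expect_true(res$keep)

  # 14 nt mate: discarded for length, and length wins over ambiguity
  res <- filter_pairs(mk(paste0("NNN", strrep("A", 5))), mk(strrep("C", 20)), rules)
  expect_false(res$keep)
  expect_identical(res$stats$discarded_length, 1L)

  expect_error(
    filter_pairs(fastq_reads("a", "ACGT", "IIII"),
                 fastq_reads("b", "ACGT", "IIII"), rules),
    "desynchronized")
})

test_that("full cleaning agrees with generator truth and the rule oracle", {
  sf <- simulate_fastq(500, seed = 3)
  res <- preprocess_pairs(sf$r1, sf$r2)
  expect_identical(res$keep, sf$truth$keep)
  # conservation: kept + discarded = input
  expect_identical(res$stats$kept + res$stats$discarded_length +
                     res$stats$discarded_ambiguity, 500L)
  # independent rule-by-rule oracle
  oracle_keep <- vapply(seq_len(500), function(i) {
    oracle_pair_keep(sf$r1$seq[i], sf$r1$qual[i],
                     sf$r2$seq[i], sf$r2$qual[i], rules)
  }, logical(1))
  expect_identical(res$keep, oracle_keep)
  # every emitted record keeps sequence and quality aligned
  expect_true(all(nchar(res$r1$seq) == nchar(res$r1$qual)))
  expect_true(all(nchar(res$r2$seq) == nchar(res$r2$qual)))
  # both discard reasons actually occur under the default profile
  expect_gt(res$stats$discarded_length, 0L)
  expect_gt(res$stats$discarded_ambiguity, 0L)
})

test_that("FASTQ files round-trip through Biostrings", {
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "r1.fastq")
  p2 <- file.path(dir, "r2.fastq")
  sf <- simulate_fastq(50, seed = 5, path_r1 = p1, path_r2 = p2)
  back <- read_fastq(p1)
  expect_identical(back$seq, sf$r1$seq)
  expect_identical(back$qual, sf$r1$qual)
  expect_identical(back$id, sf$r1$id)

  out1 <- file.path(dir, "k1.fastq"); out2 <- file.path(dir, "k2.fastq")
  stats <- preprocess_fastq_files(p1, p2, out1, out2,
                                  stats_path = file.path(dir, "stats.json"))
  expect_identical(stats$kept, sum(sf$truth$keep))
  kept <- read_fastq(out1)
  expect_identical(length(kept), sum(sf$truth$keep))
  expect_true(file.exists(file.path(dir, "stats.json")))
})
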