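toy_cm <- function(counts, lengths) {
  rownames(counts) <- sprintf("g%d", seq_len(nrow(counts)))
  colnames(counts) <- sprintf("L%d", seq_len(ncol(counts)))
  count_matrix(counts, lengths)
}

test_that("RPKM follows the per-cell formula", {
  # count 100, length 2000 nt, library total 1e6 -> RPKM 50; count 0 -> 0
  cm <- toy_cm(matrix(c(100, 999900, 0, 1e6), 2, 2), c(2000, 50000))
  em <- compute_rpkm(cm)
  expect_equal(em$values["g1", "L1"], 50)
  expect_equal(em$values["g1", "L2"], 0)
  expect_identical(em$scale, "rpkm")

  # random matrix equals the naive loop oracle
  set.seed(3)
  counts <- matrix(rpois(300, 40), 50, 6)
  lens <- sample(500:3000, 50)
  cm <- toy_cm(counts, lens)
  expect_equal(compute_rpkm(cm)$values, oracle_rpkm(cm$counts, cm$gene_lengths),
               tolerance = 1e-12)

  # scale equivariance: doubling one library's counts leaves its RPKM column
  counts2 <- counts; counts2[, 3] <- counts2[, 3] * 2L
  cm2 <- toy_cm(counts2, lens)
  expect_equal(compute_rpkm(cm2)$values[, 3], compute_rpkm(cm)$values[, 3],
               tolerance = 1e-12)

  # zero column total names the library
  cm0 <- toy_cm(matrix(c(1, 2, 0, 0), 2, 2), c(1000, 1000))
  expect_error(compute_rpkm(cm0), "L2")
})

test_that("pedestalled log2 hits its fixed points and guards its domain", {
  cm <- toy_cm(matrix(c(10L, 5L), 1, 2), 1000)
  em <- compute_rpkm(cm)
  em$values[1, ] <- c(0, 2)
  out <- pedestal_log2(em)
  expect_equal(unname(out$values[1, ]), c(1, 2))
  em$values[1, 1] <- 6
  expect_equal(unname(pedestal_log2(em)$values[1, 1]), 3)
  expect_identical(out$scale, "log2_pedestalled")

  em$values[1, 1] <- -1
  expect_error(pedestal_log2(em), "negative")
  # stage-order enforcement
  expect_error(pedestal_log2(out), "stage-order")
})

test_that("non-informative removal equals the raw-RPKM>0 rule", {
  set.seed(5)
  counts <- matrix(rpois(200, 1.5), 40, 5)
  counts[3, ] <- 0L  # an all-zero gene
  cm <- toy_cm(counts, sample(500:2000, 40))
  rpkm <- compute_rpkm(cm)
  res <- drop_noninformative(pedestal_log2(rpkm))
  expect_true("g3" %in% res$removed_ids)
  # equivalence oracle: kept iff any raw RPKM > 0
  kept_oracle <- rownames(rpkm$values)[apply(rpkm$values > 0, 1, any)]
  expect_setequal(rownames(res$expr$values), kept_oracle)

  # one count in one library is enough to keep a gene
  counts[3, 2] <- 1L
  res2 <- drop_noninformative(pedestal_log2(compute_rpkm(toy_cm(counts, cm$gene_lengths))))
  expect_false("g3" %in% res2$removed_ids)
})

test_that("quantile normalization equalizes column distributions", {
  mk_em <- function(m) {
    dimnames(m) <- list(sprintf("g%d", seq_len(nrow(m))),
                        sprintf("L%d", seq_len(ncol(m))))
    expression_matrix(m, "log2_pedestalled")
  }
  # hand-computed mean of order statistics
  em <- mk_em(cbind(c(1, 2, 3), c(2, 4, 6)))
  out <- quantile_normalize(em)
  expect_equal(unname(out$values[, 1]), c(1.5, 3, 4.5))
  expect_equal(unname(out$values[, 2]), c(1.5, 3, 4.5))

  # already-identical columns are unchanged
  same <- mk_em(cbind(c(5, 1, 3), c(5, 1, 3)))
  expect_equal(quantile_normalize(same)$values, same$values)

  # definitional property: all sorted columns identical afterwards
  set.seed(8)
  r <- mk_em(matrix(rnorm(600, 6, 2), 100, 6))
  qn <- quantile_normalize(r)
  sorted <- apply(qn$values, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
  # rank order preserved within each column
  for (j in 1:6)
    expect_identical(order(qn$values[, j]), order(r$values[, j]))

  # ties receive the mean of the reference values their ranks span
  tied <- mk_em(cbind(c(2, 2, 7), c(1, 5, 9)))
  ref <- rowMeans(cbind(sort(c(2, 2, 7)), sort(c(1, 5, 9))))
  out_t <- quantile_normalize(tied)
  expect_equal(unname(out_t$values[1:2, 1]), rep(mean(ref[1:2]), 2))

  # independent oracle: limma agrees on tie-free input
  skip_if_not_installed("limma")
  expect_equal(unname(quantile_normalize(r)$values),
               unname(limma::normalizeQuantiles(r$values)),
               tolerance = 1e-10)

  expect_error(quantile_normalize(mk_em(matrix(1:3, 3, 1))), ">= 2")
})

test_that("batch baseline subtraction corrects against the reference copies", {
  cfg <- sim_config(n_genes = 200, seed = 9)
  # single batch: identity
  ma1 <- simulate_microarray(cfg, n_batches = 1)
  out1 <- batch_baseline_subtract(ma1$expr, ma1$design)
  expect_equal(out1$expr$values, ma1$expr$values)
  expect_identical(out1$expr$scale, "batch_corrected")

  # uniform +0.8 offset: reference copies agree post-correction to 1e-9
  ma <- simulate_microarray(cfg, n_batches = 2, batch_offsets = c(0, 0.8))
  out <- batch_baseline_subtract(ma$expr, ma$design)
  expect_true(all(abs(out$offsets[, "b2"] - 0.8) < 1e-9))
  # batch-1 libraries pass through unchanged
  b1_libs <- ma$design$library_id[ma$design$batch == "b1" & !ma$design$reference]
  expect_equal(out$expr$values[, b1_libs], ma$expr$values[, b1_libs])
  # redundant reference copy dropped; kept copy under its plain id
  expect_identical(ncol(out$expr$values), ncol(ma$expr$values) - 1L)
  expect_true(ma$design$library_id[ma$design$reference][1] %in%
                colnames(out$expr$values))

  # missing reference flags are an error
  d_bad <- ma$design
  d_bad$reference <- FALSE
  expect_error(batch_baseline_subtract(ma$expr, d_bad), "reference")
})
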