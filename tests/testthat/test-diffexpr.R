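test_that("Welch test matches the closed form and handles degeneracy", {
  # identical groups
  w0 <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)

  # textbook oracle via stats::t.test
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  w <- welch_test(a, b)
  tt <- t.test(b, a)
  expect_equal(w$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(w$df, unname(tt$parameter), tolerance = 1e-10)
  expect_equal(w$p, tt$p.value, tolerance = 1e-10)

  # random instances against the oracle
  set.seed(14)
  for (i in 1:25) {
    x <- rnorm(sample(2:6, 1)); y <- rnorm(sample(2:6, 1), 1)
    w <- welch_test(x, y)
    tt <- t.test(y, x)
    expect_equal(w$p, tt$p.value, tolerance = 1e-10)
  }

  # equal variances and sizes: Welch df is exactly 2n-2
  expect_equal(welch_test(c(1, 2, 3), c(5, 6, 7))$df, 4)

  # degenerate zero-SE cases per the documented contract
  expect_silent(wz <- welch_test(c(2, 2, 2), c(2, 2, 2)))
  expect_equal(wz$p, 1)
  expect_warning(wu <- welch_test(c(2, 2, 2), c(3, 3, 3)), "zero pooled SE")
  expect_equal(wu$p, 0)

  expect_error(welch_test(1, c(1, 2)), ">= 2")
})

test_that("BH adjustment equals the hand-applied step-up rule", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # a vector needing the running minimum: hand computation
  p <- c(0.005, 0.009, 0.05, 0.5)
  expect_equal(bh_adjust(p), c(0.018, 0.018, 2/30, 0.5))
  # input order is preserved and monotonicity holds
  set.seed(2)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p - 1e-15))
  # adjusted values preserve the ordering of the raw p-values
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("signed fold change follows the reporting convention", {
  expect_equal(round(signed_fold_change(4.16, 6.87), 2), 6.54)
  expect_equal(round(signed_fold_change(4.41, 3.43), 2), -1.97)
  expect_equal(signed_fold_change(5, 5), 1)
  # antisymmetry for unequal means
  expect_equal(signed_fold_change(3, 5), -signed_fold_change(5, 3))
  # |fc| >= 1 always
  set.seed(3)
  m1 <- runif(50, 1, 12); m2 <- runif(50, 1, 12)
  expect_true(all(abs(signed_fold_change(m1, m2)) >= 1))
})

test_that("linear units are the rounded antilog", {
  expect_equal(linear_units(10.97), 2006)
  expect_equal(linear_units(9.02), 519)
  expect_equal(linear_units(1.0), 2)
})

test_that("selection is strict on p and non-strict on fold change", {
  crit <- selection_criteria("rnaseq")
  rec <- data.frame(gene_id = c("a", "b", "c", "d"),
                    p_bh = c(0.09, 0.10, 0.09, 0.2),
                    signed_fc = c(1.50, 3.0, 1.49, 5))
  sel <- select_de_genes(rec, crit)
  expect_identical(sel$gene_id, "a")
  # microarray default is stricter on p
  expect_equal(selection_criteria("microarray")$p_threshold, 0.05)
})

test_that("the DE table agrees with per-gene Welch tests and flags truth", {
  st <- run_rnaseq_stages(sim_config(n_genes = 600, seed = 8))
  de <- st$de
  d <- st$sim$design
  v <- st$floored$expr$values
  ctl <- d$library_id[d$class == "control"]
  trt <- d$library_id[d$class == "salt_loaded"]
  set.seed(99)
  idx <- sample(nrow(de), 20)
  for (i in idx) {
    w <- suppressWarnings(welch_test(v[de$gene_id[i], ctl], v[de$gene_id[i], trt]))
    expect_equal(de$p_raw[i], w$p, tolerance = 1e-12)
    expect_equal(de$t_stat[i], w$t, tolerance = 1e-12)
  }
  expect_equal(de$p_bh, bh_adjust(de$p_raw))
  expect_true(all(de$p_bh >= de$p_raw - 1e-15))
  expect_true(all(abs(de$signed_fc) >= 1))
  # sign of fc matches sign of the mean difference
  up <- de$mean_treated > de$mean_control
  expect_true(all(de$signed_fc[up] > 1 - 1e-12))
  expect_true(all(de$signed_fc[!up] <= 1))
})

test_that("marker panel reports means, linear units and panel fold changes", {
  # floored matrix built so class means equal the printed marker values
  means <- c(TH = 5.36, GFAP = 8.29, AVP = 14.79)
  sl <- c(TH = 8.55, GFAP = 7.18, AVP = 14.79)
  vals <- rbind(cbind(matrix(rep(means, 3), 3), matrix(rep(sl, 3), 3)),
                matrix(rep(c(4, 4.3), each = 3 * 10), 10, 6, byrow = TRUE) +
                  matrix(rnorm(60, 0, 0.05), 10, 6))
  dimnames(vals) <- list(c(names(means), sprintf("f%02d", 1:10)),
                         sprintf("L%d", 1:6))
  em <- expression_matrix(vals, "floored")
  d <- design_table(colnames(vals), rep(c("control", "salt_loaded"), each = 3))
  panel <- c(TH = "MCN", GFAP = "Astrocyte", AVP = "MCN", Missing1 = "None")
  rep <- suppressWarnings(marker_panel_report(em, d, panel))
  th <- rep$report[rep$report$gene == "TH", ]
  expect_equal(th$fold_change_value, 9.1)
  # antilogs of the (rounded) printed log2 means
  expect_equal(th$linear_control, 41)
  expect_equal(th$linear_treated, 375)
  expect_identical(rep$missing, "Missing1")
  avp <- rep$report[rep$report$gene == "AVP", ]
  expect_identical(avp$fold_change, "-")   # equal means: not significant
  expect_equal(avp$fold_change_value, 1)
})
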