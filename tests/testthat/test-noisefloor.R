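mk_qn <- function(m) {
  dimnames(m) <- list(sprintf("g%d", seq_len(nrow(m))),
                      sprintf("L%d", seq_len(ncol(m))))
  expression_matrix(m, "quantile_normalized")
}
mk_design <- function(classes) design_table(sprintf("L%d", seq_along(classes)), classes)

test_that("per-class CV and mean follow the n-1 definition", {
  em <- mk_qn(rbind(c(2, 4, 6, 5, 5, 5),
                    c(3, 3, 3, 7, 7, 7)))
  d <- mk_design(rep(c("control", "salt_loaded"), each = 3))
  curves <- cv_mean_by_class(em, d)
  # class values 2,4,6: mean 4, sample sd 2, cv 0.5
  expect_equal(curves$control$points["g1", "mean"], 4)
  expect_equal(curves$control$points["g1", "cv"], 0.5)
  # identical values: cv 0
  expect_equal(curves$control$points["g2", "cv"], 0)
  expect_equal(curves$salt_loaded$points["g2", "mean"], 7)

  # permutation invariance within a class
  em_perm <- mk_qn(em$values[, c(3, 1, 2, 5, 6, 4)])
  colnames(em_perm$values) <- colnames(em$values)[c(3, 1, 2, 5, 6, 4)]
  curves_perm <- cv_mean_by_class(em_perm, d)
  expect_equal(curves_perm$control$points, curves$control$points)

  expect_error(cv_mean_by_class(em, mk_design(c("a", "a", "a", "a", "a", "b"))),
               "< 2")
})

test_that("LOWESS smoothing is exact on linear data and deterministic", {
  x <- seq(1, 10, length.out = 60)
  cu <- structure(list(class = "c",
                       points = data.frame(mean = x, cv = 0.5 - 0.03 * x,
                                           row.names = sprintf("g%d", 1:60))),
                  class = "noise_curve")
  sm <- fit_lowess(cu)
  expect_equal(sm$smoothed, 0.5 - 0.03 * sm$grid, tolerance = 1e-6)
  sm2 <- fit_lowess(cu)
  expect_identical(sm$smoothed, sm2$smoothed)

  # planted piecewise curve + noise recovered within a 2-sd envelope
  set.seed(12)
  xx <- runif(400, 1, 10)
  truth <- 0.05 + 0.3 * pmax(0, 3 - xx)
  cu2 <- structure(list(class = "c",
                        points = data.frame(mean = xx,
                                            cv = truth + rnorm(400, 0, 0.02),
                                            row.names = sprintf("g%d", 1:400))),
                   class = "noise_curve")
  sm3 <- fit_lowess(cu2, frac = 0.2)
  truth_grid <- 0.05 + 0.3 * pmax(0, 3 - sm3$grid)
  # boundary and kink neighbourhoods carry smoothing bias; the 2-sd
  # envelope applies to the smooth parts, a looser one at the kink
  inner <- sm3$grid > 1.3 & sm3$grid < 9.7 & abs(sm3$grid - 3) > 0.4
  expect_lt(max(abs(sm3$smoothed - truth_grid)[inner]), 0.04)
  expect_lt(max(abs(sm3$smoothed - truth_grid)), 0.08)

  expect_error(fit_lowess(structure(list(class = "c",
    points = data.frame(mean = 1:5, cv = 1:5)), class = "noise_curve")),
    ">= 20")
})

test_that("criterion detection takes the max of concordant breakpoints", {
  hinge_curve <- function(bp, label) {
    g <- seq(1, 10, length.out = 100)
    structure(list(class = label, grid = g,
                   smoothed = 0.05 + 0.4 * pmax(0, bp - g), frac = 0.3),
              class = "noise_curve")
  }
  fl <- detect_confidence_criterion(list(hinge_curve(2.8, "a"),
                                         hinge_curve(3.1, "b")))
  expect_equal(fl$criterion, 3.1, tolerance = 0.1)
  expect_equal(unname(fl$breakpoints["a"]), 2.8, tolerance = 0.1)
  expect_lt(fl$concordance_gap, 0.5)

  # flat curve: no elbow, explicit failure asking for a manual criterion
  flat <- structure(list(class = "a", grid = seq(1, 10, length.out = 100),
                         smoothed = rep(0.05, 100), frac = 0.3),
                    class = "noise_curve")
  expect_error(suppressWarnings(detect_confidence_criterion(list(flat))),
               "manually")

  # manual override bypasses detection entirely
  manual <- detect_confidence_criterion(list(flat), criterion = 3)
  expect_identical(manual$criterion, 3)
  expect_true(manual$manual)

  # discordant breakpoints warn
  expect_warning(detect_confidence_criterion(list(hinge_curve(2, "a"),
                                                  hinge_curve(4, "b"))),
                 "disagree")
})

test_that("floor filter keeps max>criterion genes and floors the rest", {
  em <- mk_qn(rbind(c(1.0, 1.2, 1.1, 1.0, 1.3, 1.2),   # entirely below
                    c(2.0, 3.5, 2.8, 3.2, 3.9, 2.2),   # kept, partially floored
                    c(5.0, 5.5, 5.2, 6.0, 6.1, 5.9)))  # untouched
  res <- apply_floor_filter(em, 3.0)
  expect_identical(res$removed_ids, "g1")
  expect_equal(unname(res$expr$values["g2", ]), c(3, 3.5, 3, 3.2, 3.9, 3))
  expect_equal(res$expr$values["g3", ], em$values["g3", ])
  expect_identical(res$expr$scale, "floored")

  # boundary: a gene whose max equals the criterion exactly is removed
  em_eq <- mk_qn(rbind(c(1, 2, 3, 1, 2, 3), c(1, 2, 4, 1, 2, 3)))
  expect_identical(apply_floor_filter(em_eq, 3)$removed_ids, "g1")

  # random matrix equals the naive loop oracle; flooring is monotone
  set.seed(21)
  r <- mk_qn(matrix(runif(600, 1, 8), 100, 6))
  got <- apply_floor_filter(r, 3.0)
  want <- oracle_floor(r$values, 3.0)
  expect_equal(got$expr$values, want$values)
  expect_identical(got$removed_ids, want$removed)
  expect_true(all(got$expr$values >= 3.0))
  untouched <- r$values[rownames(got$expr$values), ] > 3.0
  expect_equal(got$expr$values[untouched],
               r$values[rownames(got$expr$values), ][untouched])

  # filter-then-floor commutes with column permutation
  perm <- c(4, 2, 6, 1, 3, 5)
  r_perm <- expression_matrix(r$values[, perm], "quantile_normalized")
  got_perm <- apply_floor_filter(r_perm, 3.0)
  expect_equal(got_perm$expr$values, got$expr$values[, perm])
})

test_that("detected criterion recovers the planted elbow on default data", {
  errs <- vapply(1:5, function(s) {
    st <- run_rnaseq_stages(sim_config(seed = s))
    abs(st$floor$criterion - 3.0)
  }, numeric(1))
  expect_lte(stats::median(errs), 0.5)
})
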