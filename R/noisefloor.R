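# Noise-floor detection. Bulk expression noise (CV) is roughly flat in the
# mean at useful signal levels but inflates sharply below some expression
# value where measurement noise dominates. The workflow locates that value
# per class — the "confidence criterion" — from a LOWESS fit of CV against
# mean expression, discards genes never exceeding it, and floors remaining
# sub-criterion values to it. The original procedure located the elbow by
# eye; here a two-segment broken-stick fit makes the choice algorithmic and
# reproducible, with a manual override to reproduce any visual call.

#' Per-class CV and mean of normalized expression
#'
#' For every gene and class: mean = arithmetic mean over the class's
#' libraries, CV = sample standard deviation (n-1) / mean, both on the
#' normalized scale the matrix carries.
#'
#' @param em [expression_matrix()] on the `"quantile_normalized"` or
#'   `"batch_corrected"` scale.
#' @param design `osmo_design`; every class needs >= 2 libraries.
#' @return named list of `noise_curve` objects (one per class), each with
#'   `points` (data.frame `mean`, `cv`) and the class label.
#' @export
cv_mean_by_class <- function(em, design) {
  assert_scale(em, c("quantile_normalized", "batch_corrected"), "cv_mean_by_class")
  if (!inherits(design, "osmo_design")) stopf("'design' must be an osmo_design")
  idx <- match(colnames(em$values), design$library_id)
  if (any(is.na(idx)))
    stopf("libraries missing from design: %s",
          paste(colnames(em$values)[is.na(idx)], collapse = ", "))
  classes <- design$class[idx]
  curves <- lapply(unique(classes), function(cl) {
    x <- em$values[, classes == cl, drop = FALSE]
    if (ncol(x) < 2) stopf("class '%s' has < 2 libraries", cl)
    m <- rowMeans(x)
    if (any(m <= 0))
      stopf("non-positive gene mean in class '%s'; CV is undefined there", cl)
    s <- sqrt(rowSums((x - m)^2) / (ncol(x) - 1))
    structure(list(class = cl,
                   points = data.frame(mean = m, cv = s / m,
                                       row.names = rownames(x))),
              class = "noise_curve")
  })
  stats::setNames(curves, unique(classes))
}

#' LOWESS fit of a CV-mean curve
#'
#' Locally weighted linear regression (`stats::lowess`, 3 robustness
#' iterations) of CV on mean expression, resampled onto a fixed equally
#' spaced grid over the observed mean range. Deterministic for a given
#' input.
#'
#' @param curve a `noise_curve` from [cv_mean_by_class()] (>= 20 points).
#' @param frac LOWESS span (fraction of points in each local fit).
#' @param grid_n number of grid points for the resampled smooth.
#' @return the curve with `grid`, `smoothed` and `frac` filled in.
#' @export
fit_lowess <- function(curve, frac = 0.3, grid_n = 100L) {
  if (!inherits(curve, "noise_curve")) stopf("'curve' must be a noise_curve")
  if (nrow(curve$points) < 20) stopf("need >= 20 points for a LOWESS fit")
  assert_proportion(frac, "frac")
  lo <- stats::lowess(curve$points$mean, curve$points$cv, f = frac, iter = 3)
  grid <- seq(min(curve$points$mean), max(curve$points$mean), length.out = grid_n)
  curve$grid <- grid
  curve$smoothed <- stats::approx(lo$x, lo$y, xout = grid, rule = 2, ties = mean)$y
  curve$frac <- frac
  curve
}

# Least-squares SSE of a single line through (x, y).
line_sse <- function(x, y) {
  if (length(x) < 2) return(0)
  fit <- stats::lm.fit(cbind(1, x), y)
  sum(fit$residuals^2)
}

# Broken-stick scan: best two-segment fit with the breakpoint at a grid
# point (shared by both segments). Returns breakpoint, SSE and the gain of
# the two-segment fit over a single line.
broken_stick <- function(x, y) {
  n <- length(x)
  sse1 <- line_sse(x, y)
  best <- list(i = NA_integer_, sse = Inf)
  for (i in 2:(n - 1)) {
    sse <- line_sse(x[1:i], y[1:i]) + line_sse(x[i:n], y[i:n])
    if (sse < best$sse) best <- list(i = i, sse = sse)
  }
  list(breakpoint = x[best$i], sse2 = best$sse, sse1 = sse1,
       gain = if (best$sse > 0) sse1 / best$sse else Inf)
}

#' Detect the confidence criterion from smoothed noise curves
#'
#' Fits a two-segment broken-stick model to each class's smoothed CV curve,
#' scanning every interior grid point as the candidate breakpoint and
#' minimising total squared error. A class yields an elbow only when the
#' two-segment fit beats a single line by at least `elbow_gain` in SSE;
#' otherwise the class reports "no elbow". The consensus criterion is the
#' maximum of the per-class breakpoints — the conservative reading of
#' "concordantly lost": nothing sub-noise in any class survives. A warning
#' is issued when the per-class breakpoints disagree by more than 0.5.
#'
#' @param curves list of smoothed `noise_curve` objects ([fit_lowess()]).
#' @param elbow_gain minimum SSE ratio (single line / broken stick) for an
#'   elbow to be accepted.
#' @param criterion manual override: skip detection and use this value.
#' @return object of class `noise_floor`: `breakpoints` (per class, `NA` if
#'   none), `criterion`, `concordance_gap`, `elbow_gain`, `manual`.
#' @export
detect_confidence_criterion <- function(curves, elbow_gain = 1.2,
                                        criterion = NULL) {
  if (inherits(curves, "noise_curve")) curves <- list(curves)
  if (!is.null(criterion)) {
    assert_scalar_number(criterion, "criterion")
    return(structure(list(breakpoints = NULL, criterion = criterion,
                          concordance_gap = NA_real_,
                          elbow_gain = elbow_gain, manual = TRUE),
                     class = "noise_floor"))
  }
  if (length(curves) < 2)
    warnf("only one noise curve supplied; consensus is a single class")
  bps <- vapply(curves, function(cu) {
    if (is.null(cu$smoothed)) stopf("curves must be smoothed with fit_lowess()")
    bs <- broken_stick(cu$grid, cu$smoothed)
    if (is.finite(bs$gain) && bs$gain < elbow_gain) NA_real_ else bs$breakpoint
  }, numeric(1))
  names(bps) <- vapply(curves, `[[`, "", "class")
  if (all(is.na(bps)))
    stopf(paste("no elbow detected in any class; the CV-mean relationship",
                "looks flat. Set the criterion manually via 'criterion='."))
  gap <- if (sum(!is.na(bps)) > 1) diff(range(bps, na.rm = TRUE)) else 0
  if (is.finite(gap) && gap > 0.5)
    warnf("per-class breakpoints disagree by %.2f (> 0.5): inspect the curves", gap)
  structure(list(breakpoints = bps,
                 criterion = max(bps, na.rm = TRUE),
                 concordance_gap = gap,
                 elbow_gain = elbow_gain, manual = FALSE),
            class = "noise_floor")
}

#' @export
print.noise_floor <- function(x, ...) {
  cat(sprintf("noise_floor: criterion %.3f%s\n", x$criterion,
              if (isTRUE(x$manual)) " (manual)" else ""))
  if (!is.null(x$breakpoints))
    cat("  per-class breakpoints:",
        paste(sprintf("%s=%.3f", names(x$breakpoints), x$breakpoints),
              collapse = ", "), "\n")
  invisible(x)
}

#' Remove noise-biased genes and floor the survivors
#'
#' A gene is kept iff at least one library exceeds the confidence criterion
#' (strict inequality); kept genes' values below the criterion are raised to
#' it. Values above the criterion are untouched.
#'
#' @param em [expression_matrix()] on the `"quantile_normalized"` or
#'   `"batch_corrected"` scale.
#' @param floor a `noise_floor` (or a single number taken as the criterion).
#' @return list with `expr` (scale `"floored"`) and `removed_ids`.
#' @export
apply_floor_filter <- function(em, floor) {
  assert_scale(em, c("quantile_normalized", "batch_corrected"), "apply_floor_filter")
  crit <- if (inherits(floor, "noise_floor")) floor$criterion else floor
  assert_scalar_number(crit, "criterion")
  keep <- apply(em$values, 1, max) > crit
  vals <- em$values[keep, , drop = FALSE]
  vals[vals < crit] <- crit
  list(expr = expression_matrix(vals, "floored"),
       removed_ids = rownames(em$values)[!keep])
}

#' Serialize a noise model to JSON / TSV diagnostics
#'
#' Writes the floor parameters as JSON and, when curves are supplied, a
#' per-class TSV of (mean, cv, smoothed cv) suitable for re-plotting the
#' noise analysis.
#'
#' @param floor a `noise_floor`.
#' @param path JSON output path.
#' @param curves optional smoothed curves; written next to `path` as
#'   `<path>_curves.tsv`.
#' @export
write_noise_floor <- function(floor, path, curves = NULL) {
  jsonlite::write_json(
    list(criterion = floor$criterion,
         breakpoints = as.list(floor$breakpoints),
         concordance_gap = floor$concordance_gap,
         elbow_gain = floor$elbow_gain, manual = floor$manual),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(curves)) {
    tab <- do.call(rbind, lapply(curves, function(cu) {
      sm <- stats::approx(cu$grid, cu$smoothed, xout = cu$points$mean,
                          rule = 2, ties = mean)$y
      data.frame(class = cu$class, gene_id = rownames(cu$points),
                 mean = cu$points$mean, cv = cu$points$cv, smoothed_cv = sm)
    }))
    utils::write.table(tab, paste0(tools::file_path_sans_ext(path), "_curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
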