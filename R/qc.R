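# Outlier screening: Tukey five-number summaries, covariance-based PCA and
# Pearson correlation with optional average-linkage clustering. These
# operations emit data for inspection; they flag, never remove — sample
# exclusion is a user decision.

#' Tukey box-plot summaries per library
#'
#' Five-number summary with linear-interpolation (type-7) quartiles and
#' 1.5 x IQR whiskers; whisker ends sit on the most extreme data point still
#' inside the fence, and values beyond the whiskers are flagged as outliers.
#'
#' @param em an [expression_matrix()] (any scale; >= 5 values per library).
#' @return named list per library: `min`, `q1`, `median`, `q3`, `max`,
#'   `whisker_low`, `whisker_high`, `outliers`.
#' @export
tukey_summary <- function(em) {
  if (!inherits(em, "expression_matrix")) stopf("'em' must be an expression_matrix")
  if (nrow(em$values) < 5) stopf("need >= 5 values per library")
  apply(em$values, 2, function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - 1.5 * iqr
    hi_fence <- q[3] + 1.5 * iqr
    inside <- x[x >= lo_fence & x <= hi_fence]
    list(min = min(x), q1 = q[1], median = q[2], q3 = q[3], max = max(x),
         whisker_low = min(inside), whisker_high = max(inside),
         outliers = sort(x[x < lo_fence | x > hi_fence]))
  }, simplify = FALSE)
}

#' Covariance-based PCA of samples
#'
#' Genes are centered but not scaled (covariance, not correlation, PCA);
#' sample scores come from the eigenstructure of the sample-space
#' covariance. Component signs follow a deterministic convention: the
#' largest-magnitude gene loading of each component is positive.
#'
#' @param em an [expression_matrix()] with >= 2 samples.
#' @return list with `scores` (sample x component), `loadings`
#'   (gene x component) and `var_explained` (fractions, decreasing).
#' @export
pca_covariance <- function(em) {
  if (!inherits(em, "expression_matrix")) stopf("'em' must be an expression_matrix")
  if (ncol(em$values) < 2) stopf("PCA needs >= 2 samples")
  pr <- stats::prcomp(t(em$values), center = TRUE, scale. = FALSE)
  for (k in seq_len(ncol(pr$rotation))) {
    j <- which.max(abs(pr$rotation[, k]))
    if (pr$rotation[j, k] < 0) {
      pr$rotation[, k] <- -pr$rotation[, k]
      pr$x[, k] <- -pr$x[, k]
    }
  }
  list(scores = pr$x,
       loadings = pr$rotation,
       var_explained = pr$sdev^2 / sum(pr$sdev^2))
}

#' Pearson correlation across samples, optionally clustered
#'
#' @param em an [expression_matrix()] with >= 2 samples, each with nonzero
#'   variance.
#' @param clustered if `TRUE`, average-linkage hierarchical clustering on
#'   the distance `1 - r` is performed and the leaf order returned.
#' @return list with `r` (sample correlation matrix) and, when clustered,
#'   `order` (leaf order labels) and `hclust` (the tree).
#' @export
correlation_heatmap <- function(em, clustered = FALSE) {
  if (!inherits(em, "expression_matrix")) stopf("'em' must be an expression_matrix")
  if (ncol(em$values) < 2) stopf("need >= 2 samples")
  sds <- apply(em$values, 2, stats::sd)
  if (any(sds == 0))
    stopf("zero-variance sample(s): %s",
          paste(colnames(em$values)[sds == 0], collapse = ", "))
  r <- stats::cor(em$values)
  out <- list(r = r)
  if (clustered) {
    hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
    out$order <- colnames(r)[hc$order]
    out$hclust <- hc
  }
  out
}
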