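# Independent brute-force oracles used across test files. These deliberately
# avoid the package's code paths: plain loops, naive searches, exhaustive
# enumeration.

# Naive per-cell RPKM loop.
oracle_rpkm <- function(counts, lengths) {
  out <- counts * NA_real_
  totals <- colSums(counts)
  for (g in seq_len(nrow(counts)))
    for (l in seq_len(ncol(counts)))
      out[g, l] <- counts[g, l] * 1e9 / (lengths[g] * totals[l])
  out
}

# Naive keep/floor loop.
oracle_floor <- function(values, criterion) {
  keep <- logical(nrow(values))
  out <- values
  for (g in seq_len(nrow(values))) {
    keep[g] <- max(values[g, ]) > criterion
    for (l in seq_len(ncol(values)))
      if (out[g, l] < criterion) out[g, l] <- criterion
  }
  list(values = out[keep, , drop = FALSE], removed = rownames(values)[!keep])
}

# Naive O(n*m) leftmost substring search; returns 0 when absent.
oracle_find <- function(s, pat) {
  n <- nchar(s); m <- nchar(pat)
  if (m > n) return(0L)
  for (i in seq_len(n - m + 1L))
    if (substr(s, i, i + m - 1L) == pat) return(i)
  0L
}

# Independent rule-by-rule re-implementation of the read-pair cleaning,
# split into: clip + fixed trims (naive search), maximal end-quality trim
# (walk in from both ends), and the pair filter.
oracle_end_trim <- function(seq, qual, qmax) {
  if (nchar(seq) == 0) return(list(seq = "", qual = ""))
  q <- utf8ToInt(qual) - 33L
  i <- 1L; j <- length(q)
  while (i <= j && q[i] <= qmax) i <- i + 1L
  while (j >= i && q[j] <= qmax) j <- j - 1L
  if (i > j) list(seq = "", qual = "") else
    list(seq = substr(seq, i, j), qual = substr(qual, i, j))
}

oracle_pair_keep <- function(s1, q1, s2, q2, rules) {
  qmax <- floor(-10 * log10(1 - rules$min_call_accuracy) - 1e-9)
  clean1 <- oracle_clean_fixed(s1, q1, rules)
  clean1 <- oracle_end_trim(clean1$seq, clean1$qual, qmax)
  clean2 <- oracle_clean_fixed(s2, q2, rules)
  clean2 <- oracle_end_trim(clean2$seq, clean2$qual, qmax)
  n_amb <- function(s) sum(strsplit(s, "")[[1]] %in% c("A", "C", "G", "T") == FALSE)
  nchar(clean1$seq) >= rules$min_length && nchar(clean2$seq) >= rules$min_length &&
    n_amb(clean1$seq) <= rules$max_ambiguities &&
    n_amb(clean2$seq) <= rules$max_ambiguities
}

# clip + fixed trims only
oracle_clean_fixed <- function(seq, qual, rules) {
  p <- oracle_find(seq, rules$adapter)
  if (p == 0L) {
    n <- nchar(seq)
    ks <- seq(min(nchar(rules$adapter) - 1L, n), rules$min_overlap)
    for (k in ks) {
      if (substr(seq, n - k + 1L, n) == substr(rules$adapter, 1L, k)) {
        p <- n - k + 1L
        break
      }
    }
  }
  if (p > 0L) {
    seq <- substr(seq, 1L, p - 1L)
    qual <- substr(qual, 1L, p - 1L)
  }
  n <- nchar(seq)
  from <- rules$head_trim + 1L
  to <- n - rules$tail_trim
  if (from > to) list(seq = "", qual = "") else
    list(seq = substr(seq, from, to), qual = substr(qual, from, to))
}

# Two-segment hinge scan over binned medians — independent elbow locator.
oracle_elbow_binned <- function(mean, cv, bin = 0.25) {
  brk <- seq(floor(min(mean)), ceiling(max(mean)), by = bin)
  mid <- (brk[-1] + brk[-length(brk)]) / 2
  med <- tapply(cv, cut(mean, brk), stats::median)
  ok <- !is.na(med)
  x <- mid[ok]; y <- as.numeric(med[ok])
  n <- length(x)
  sse <- function(xx, yy) {
    if (length(xx) < 2) return(0)
    r <- stats::lm.fit(cbind(1, xx), yy)$residuals
    sum(r^2)
  }
  best_i <- NA; best <- Inf
  for (i in 2:(n - 1)) {
    s <- sse(x[1:i], y[1:i]) + sse(x[i:n], y[i:n])
    if (s < best) { best <- s; best_i <- i }
  }
  x[best_i]
}

# Exhaustive hypergeometric enumeration for a two-sided Fisher test on a
# 2x2 table with fixed margins.
oracle_fisher_two_sided <- function(de_in, de_out, bg_in, bg_out) {
  m <- de_in + bg_in          # set size
  n <- de_out + bg_out        # outside set
  k <- de_in + de_out         # DE draws
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(de_in, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Default-generator run through the RNA-seq stages, returning what the
# acceptance properties need. Kept here so several test files share it.
run_rnaseq_stages <- function(cfg) {
  sim <- simulate_counts(cfg)
  em <- quantile_normalize(
    drop_noninformative(pedestal_log2(compute_rpkm(sim$counts)))$expr)
  curves <- lapply(cv_mean_by_class(em, sim$design), fit_lowess)
  floor <- suppressWarnings(detect_confidence_criterion(curves))
  fl <- apply_floor_filter(em, floor)
  de <- suppressWarnings(de_table(fl$expr, sim$design,
                                  control = cfg$class_labels[1]))
  list(sim = sim, em = em, floor = floor, floored = fl, de = de)
}
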