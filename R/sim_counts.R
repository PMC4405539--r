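#' Simulate a two-class read-pair count matrix with planted ground truth
#'
#' Draws per-gene expected RPKM abundances log-normally, calibrates them so
#' each library's expected total equals `library_size`, plants differential
#' genes by shifting the treated class by `+/- de_log2fc`, then draws noisy
#' per-library values on the log2(RPKM+2) analysis scale with a standard
#' deviation chosen so the within-class CV follows the configured mean-CV
#' profile (flat at `cv_high` above the planted elbow, linearly inflating
#' below it). Noisy abundances are converted back to expected read-pair
#' counts and each library is renormalised to `library_size` total pairs.
#'
#' The noise is injected directly on the scale on which the downstream CV is
#' measured, so the planted elbow is recoverable by the noise-floor stage;
#' count discretisation adds only sub-dominant quantisation noise.
#'
#' @param config a [sim_config()].
#' @return list with elements `counts` (a [count_matrix()]), `truth` (class
#'   `sim_truth`: named `de_log2fc` vector over the planted genes,
#'   `planted_elbow`, `seed`) and `design` (an `osmo_design`).
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config")) stopf("'config' must be a sim_config")
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_genes
  npc <- cfg$n_per_class
  genes <- sprintf("gene%04d", seq_len(n))
  libs <- c(paste0(cfg$class_labels[1], "_", seq_len(npc)),
            paste0(cfg$class_labels[2], "_", seq_len(npc)))
  classes <- rep(cfg$class_labels, each = npc)

  lens <- sample(seq(cfg$gene_length_range[1], cfg$gene_length_range[2]),
                 n, replace = TRUE)

  # expected RPKM, calibrated so sum(rpkm * length) = 1e9, i.e. expected
  # per-library read-pair total equals library_size
  log2_rpkm <- stats::rnorm(n, cfg$abundance_log2_mean, cfg$abundance_log2_sd)
  rpkm <- 2^log2_rpkm
  rpkm <- rpkm * 1e9 / sum(rpkm * lens)

  # planted DE genes: drawn by seeded shuffle from genes far enough above
  # the noise elbow that both class means stay above it after the shift —
  # differential expression planted below the floor would be censored by
  # flooring and unrecoverable by construction. Signs alternate for a
  # 50/50 up/down split.
  n_de <- round(cfg$de_fraction * n)
  eligible <- which(log2(rpkm + 2) > cfg$elbow_location + cfg$de_log2fc)
  if (n_de > length(eligible))
    stopf("de_fraction %.3f asks for %d DE genes but only %d genes lie above the elbow",
          cfg$de_fraction, n_de, length(eligible))
  de_idx <- if (n_de > 0) sample(eligible, n_de) else integer(0)
  lfc <- numeric(n)
  if (n_de > 0) lfc[de_idx] <- rep_len(c(1, -1), n_de) * cfg$de_log2fc

  rpkm_class <- cbind(rpkm, rpkm * 2^lfc)  # control, treated expectations
  counts <- matrix(0L, n, 2 * npc, dimnames = list(genes, libs))
  for (j in seq_along(libs)) {
    mu <- rpkm_class[, if (classes[j] == cfg$class_labels[1]) 1 else 2]
    m <- log2(mu + 2)                       # pedestalled analysis scale
    y <- stats::rnorm(n, m, target_cv(cfg, m) * m)
    noisy_rpkm <- pmax(2^y - 2, 0)
    w <- noisy_rpkm * lens
    counts[, j] <- as.integer(round(cfg$library_size * w / sum(w)))
  }

  truth <- structure(list(
    de_log2fc = stats::setNames(lfc[de_idx], genes[de_idx]),
    planted_elbow = cfg$elbow_location,
    seed = cfg$seed), class = "sim_truth")
  list(counts = count_matrix(counts, stats::setNames(lens, genes)),
       truth = truth,
       design = design_table(libs, classes))
}
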