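#' Simulate a probe-level microarray study with batches and a common reference
#'
#' Emulates a two-batch microarray design in which one reference library is
#' hybridised in every batch so that batch differences are recoverable by
#' baseline subtraction. Gene abundances, planted differential genes and the
#' mean-dependent CV profile follow the same model as [simulate_counts()],
#' but values are emitted on a post-RMA log2 scale at probe level: each gene
#' carries one to three probes with a fixed per-probe offset, and every
#' library in batch `b` receives that batch's additive offset (scalar or
#' gene-specific). The reference library's values are drawn once and copied
#' into every batch, so comparing its copies recovers the planted offsets
#' exactly.
#'
#' @param config a [sim_config()].
#' @param n_batches number of batches (>= 1).
#' @param batch_offsets `NULL` for the default scalar offsets
#'   `0.8 * (batch - 1)`; or a numeric vector of length `n_batches`; or an
#'   `n_genes x n_batches` matrix of gene-specific offsets. Batch 1 offsets
#'   must be zero (it is the baseline).
#' @param probe_sd standard deviation of the fixed per-probe log2 offset.
#' @return list with `expr` (probe x library [expression_matrix()], scale
#'   `"rma_log2"`), `truth` (planted DE, per-gene batch offset matrix,
#'   elbow, seed), `design` (with batch and reference columns; the reference
#'   library appears once per batch) and `map` (probe id -> gene symbol).
#' @export
simulate_microarray <- function(config, n_batches = 2, batch_offsets = NULL,
                                probe_sd = 0.25) {
  if (!inherits(config, "sim_config")) stopf("'config' must be a sim_config")
  assert_scalar_number(n_batches, "n_batches", integer = TRUE)
  if (n_batches < 1) stopf("'n_batches' must be >= 1")
  cfg <- config
  set.seed(cfg$seed + 1L)  # decoupled from the count generator's stream
  n <- cfg$n_genes
  npc <- cfg$n_per_class
  genes <- sprintf("gene%04d", seq_len(n))

  offsets <- matrix(0, n, n_batches)  # gene x batch
  if (is.null(batch_offsets)) {
    offsets <- outer(rep(1, n), 0.8 * (seq_len(n_batches) - 1))
  } else if (is.matrix(batch_offsets)) {
    if (!all(dim(batch_offsets) == c(n, n_batches)))
      stopf("'batch_offsets' matrix must be n_genes x n_batches")
    offsets <- batch_offsets
  } else {
    if (length(batch_offsets) != n_batches)
      stopf("'batch_offsets' must have one entry per batch")
    offsets <- outer(rep(1, n), as.numeric(batch_offsets))
  }
  if (any(offsets[, 1] != 0)) stopf("batch 1 is the baseline; its offsets must be 0")

  # post-RMA log2 values never fall much below ~2 on real arrays: the lower
  # abundance tail is clamped there, mimicking the array detection floor
  e <- pmax(stats::rnorm(n, cfg$abundance_log2_mean, cfg$abundance_log2_sd), 2)
  n_de <- round(cfg$de_fraction * n)
  eligible <- which(e > cfg$elbow_location + cfg$de_log2fc)
  if (n_de > length(eligible))
    stopf("de_fraction %.3f asks for %d DE genes but only %d genes lie above the elbow",
          cfg$de_fraction, n_de, length(eligible))
  de_idx <- if (n_de > 0) sample(eligible, n_de) else integer(0)
  lfc <- numeric(n)
  if (n_de > 0) lfc[de_idx] <- rep_len(c(1, -1), n_de) * cfg$de_log2fc
  gene_mean <- cbind(e, e + lfc)  # control, treated class means (log2)

  n_probes <- sample(1:3, n, replace = TRUE, prob = c(0.7, 0.2, 0.1))
  gene_of_probe <- rep(seq_len(n), n_probes)
  probes <- unlist(lapply(seq_len(n), function(g)
    sprintf("%s_at%d", genes[g], seq_len(n_probes[g]))))
  probe_eff <- stats::rnorm(length(probes), 0, probe_sd)

  # libraries: npc per class; the first control library doubles as the
  # batch reference and is copied into every batch
  lib_ids <- c(paste0(cfg$class_labels[1], "_", seq_len(npc)),
               paste0(cfg$class_labels[2], "_", seq_len(npc)))
  lib_class <- rep(cfg$class_labels, each = npc)
  ref <- lib_ids[1]
  nonref <- setdiff(lib_ids, ref)
  batch_of <- stats::setNames(
    rep_len(seq_len(n_batches), length(nonref)), nonref)

  draw_library <- function(class_idx) {
    m <- gene_mean[gene_of_probe, class_idx] + probe_eff
    sdv <- target_cv(cfg, m) * pmax(m, 1)
    stats::rnorm(length(m), m, sdv)
  }

  ref_values <- draw_library(1L)  # drawn once, reused in each batch
  cols <- list(); col_lib <- character(0); col_batch <- integer(0); col_ref <- logical(0)
  for (b in seq_len(n_batches)) {
    cols[[paste0(ref, "@b", b)]] <- ref_values + offsets[gene_of_probe, b]
    col_lib <- c(col_lib, ref); col_batch <- c(col_batch, b); col_ref <- c(col_ref, TRUE)
  }
  for (lib in nonref) {
    b <- batch_of[[lib]]
    ci <- if (lib_class[match(lib, lib_ids)] == cfg$class_labels[1]) 1L else 2L
    cols[[lib]] <- draw_library(ci) + offsets[gene_of_probe, b]
    col_lib <- c(col_lib, lib); col_batch <- c(col_batch, b); col_ref <- c(col_ref, FALSE)
  }
  values <- do.call(cbind, cols)
  rownames(values) <- probes

  design <- design_table(col_lib,
                         lib_class[match(col_lib, lib_ids)],
                         batch = paste0("b", col_batch),
                         reference = col_ref)
  truth <- structure(list(
    de_log2fc = stats::setNames(lfc[de_idx], genes[de_idx]),
    batch_offsets = `dimnames<-`(offsets, list(genes, paste0("b", seq_len(n_batches)))),
    planted_elbow = cfg$elbow_location,
    seed = cfg$seed), class = "sim_truth")
  list(expr = expression_matrix(values, "rma_log2"),
       truth = truth, design = design,
       map = probe_map(probes, genes[gene_of_probe]))
}
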