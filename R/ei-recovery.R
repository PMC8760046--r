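#' Genotype session profiles with planted population E/I ratios
#'
#' Session configurations emulating the three genotypes of the emulated
#' experiments, with true cell-odor label ratios p_excited / p_inhibited of
#' 2.0 (control), 5.0 (SHANK2A-overexpressing, "SH-WT") and 1.4 (truncated
#' variant, "SH-RX"), strong response gains, and equal unit counts. These are
#' the conditions used by the parameter-recovery checks: the question is
#' whether the analysis chain recovers the planted E/I ordering, not the
#' biological fractions themselves (response probabilities are enriched
#' relative to cortex to give desk-scale power).
#'
#' @param n_units Units per genotype session.
#' @param seed Optional seed stored in each config (offset per genotype).
#' @return Named list of [session_config()]s: `control`, `sh_wt`, `sh_rx`.
#' @export
ei_genotype_profiles <- function(n_units = 220, seed = NULL) {
  p <- list(control = c(0.35, 0.175), # E/I 2.0
            sh_wt = c(0.40, 0.08),    # E/I 5.0
            sh_rx = c(0.245, 0.175))  # E/I 1.4
  out <- lapply(seq_along(p), function(i) {
    session_config(n_units = n_units,
                   p_excited = p[[i]][1], p_inhibited = p[[i]][2],
                   balanced_labels = TRUE,
                   seed = if (is.null(seed)) NULL else seed + i - 1L)
  })
  names(out) <- names(p)
  out
}

#' Estimated E/I ratio of one simulated session
#'
#' Runs the full analysis chain on a generated session: unit QC and
#' inclusion, per-pair z-score classification, session summary.
#'
#' @param config A [session_config()].
#' @param qc Apply the unit inclusion criteria before classification.
#' @param ... Passed to [classify_session()].
#' @return The [summarize_session()] list, with the generating truth attached
#'   as attribute `truth`.
#' @export
estimate_session_ei <- function(config, qc = TRUE, ...) {
  ses <- generate_session(config)
  units <- seq_along(ses$spikes)
  if (qc && length(units)) {
    qcr <- unit_qc(ses$spikes, ses$trials, ses$span_s)
    units <- qcr$unit[qcr$included]
  }
  pairs <- classify_session(ses$spikes, ses$trials, units = units, ...)
  out <- summarize_session(pairs)
  attr(out, "truth") <- ses$truth
  out
}

#' E/I rank-order recovery across simulated genotype triplets
#'
#' Simulates `n_triplets` independent (control, SH-WT, SH-RX) session
#' triplets from [ei_genotype_profiles()] and scores how often the estimated
#' E/I ratios recover the planted rank order (SH-WT above control above
#' SH-RX).
#'
#' @param n_triplets Number of triplets.
#' @param n_units Units per session.
#' @param seed Seed for the whole experiment.
#' @param ... Passed to [estimate_session_ei()].
#' @return List with `rank_correct` (fraction of triplets in correct order)
#'   and `ei` (n_triplets x 3 matrix of estimated ratios).
#' @export
ei_rank_recovery <- function(n_triplets = 100, n_units = 220, seed = NULL,
                             ...) {
  if (!is.null(seed)) set.seed(seed)
  profiles <- ei_genotype_profiles(n_units = n_units, seed = NULL)
  ei <- matrix(NA_real_, n_triplets, 3,
               dimnames = list(NULL, names(profiles)))
  for (t in seq_len(n_triplets)) {
    for (g in seq_along(profiles)) {
      ei[t, g] <- estimate_session_ei(profiles[[g]], ...)$ei_ratio
    }
  }
  ok <- !is.na(ei[, "sh_wt"]) & !is.na(ei[, "control"]) & !is.na(ei[, "sh_rx"])
  correct <- ok & ei[, "sh_wt"] > ei[, "control"] & ei[, "control"] > ei[, "sh_rx"]
  list(rank_correct = mean(correct), ei = ei)
}
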