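#' Session firing-rate stability of a unit
#'
#' The session is divided into `n_blocks` equal blocks. The end-to-end change
#' is the absolute rate difference between last and first block relative to
#' the first block; the intermittent fluctuation is the largest absolute block
#' deviation from the session mean rate, relative to that mean.
#'
#' @param times Spike times (s).
#' @param span_s Session duration (s).
#' @param n_blocks Number of equal blocks (default 10).
#' @return List with `end_to_end_change`, `max_intermittent_fluctuation`,
#'   `block_rates_hz`. A silent first block (or silent unit) yields `Inf`, so
#'   the unit fails the stability criteria rather than dividing by zero.
#' @export
session_stability <- function(times, span_s, n_blocks = 10) {
  stopifnot(span_s > 0, n_blocks >= 2)
  breaks <- seq(0, span_s, length.out = n_blocks + 1)
  counts <- tabulate(findInterval(times, breaks, rightmost.closed = TRUE),
                     nbins = n_blocks)
  rates <- counts / (span_s / n_blocks)
  mean_rate <- mean(rates)
  end_change <- if (rates[1] == 0) Inf else
    abs(rates[n_blocks] - rates[1]) / rates[1]
  fluct <- if (mean_rate == 0) Inf else
    max(abs(rates - mean_rate)) / mean_rate
  list(end_to_end_change = end_change,
       max_intermittent_fluctuation = fluct,
       block_rates_hz = rates)
}

#' Refractory-period contamination
#'
#' Fraction of inter-spike intervals strictly below the refractory period
#' (default 5 ms); a cluster-quality metric for putative single units.
#'
#' @param times Spike times (s).
#' @param refractory_s Refractory period (s).
#' @return Fraction in `[0, 1]`; 0 for fewer than two spikes.
#' @export
refractory_contamination <- function(times, refractory_s = 0.005) {
  if (length(times) < 2) return(0)
  mean(diff(sort(times)) < refractory_s)
}

#' Baseline firing rate over pre-odor windows
#'
#' Mean firing rate across the pre-odor baseline windows (default 2 s before
#' each odor onset); the rate entering the minimum-rate inclusion criterion.
#'
#' @param times Spike times (s).
#' @param trials Trial table with an `onset_s` column.
#' @param baseline_window_s Baseline window length (s).
#' @return Rate in Hz.
#' @export
baseline_rate <- function(times, trials, baseline_window_s = 2) {
  stopifnot(baseline_window_s > 0, nrow(trials) >= 1)
  ons <- trials$onset_s
  edges <- as.vector(rbind(ons - baseline_window_s, ons))
  idx <- findInterval(times, edges)
  n_in <- sum(idx %% 2L == 1L)
  n_in / (length(ons) * baseline_window_s)
}

#' Per-unit quality-control report
#'
#' Computes, for every unit, the baseline rate, session-stability metrics and
#' refractory contamination, and applies the inclusion criteria via
#' [apply_inclusion()].
#'
#' @param spikes List of spike-time vectors.
#' @param trials Trial table (`onset_s` column).
#' @param span_s Session duration (s).
#' @param n_blocks Stability blocks.
#' @param baseline_window_s Baseline window (s).
#' @param ... Criteria passed on to [apply_inclusion()].
#' @return Data.frame with one row per unit: metrics, `included`, `reasons`.
#' @export
unit_qc <- function(spikes, trials, span_s, n_blocks = 10,
                    baseline_window_s = 2, ...) {
  rows <- lapply(seq_along(spikes), function(u) {
    st <- session_stability(spikes[[u]], span_s, n_blocks)
    data.frame(unit = u,
               baseline_rate_hz = baseline_rate(spikes[[u]], trials,
                                                baseline_window_s),
               end_to_end_change = st$end_to_end_change,
               max_intermittent_fluctuation = st$max_intermittent_fluctuation,
               refractory_fraction = refractory_contamination(spikes[[u]]))
  })
  qc <- if (length(rows)) do.call(rbind, rows) else
    data.frame(unit = integer(0), baseline_rate_hz = numeric(0),
               end_to_end_change = numeric(0),
               max_intermittent_fluctuation = numeric(0),
               refractory_fraction = numeric(0))
  apply_inclusion(qc, ...)
}

#' Apply unit inclusion criteria
#'
#' A unit is kept iff its baseline firing rate is at least `min_rate_hz`
#' (default 0.5 Hz), the end-to-end change in baseline firing rate is below
#' `max_end_change` (default 10%), and the maximum intermittent block
#' fluctuation is below `max_fluctuation` (default 20%). Exclusion reasons
#' are recorded per unit.
#'
#' @param qc Data.frame with columns `baseline_rate_hz`, `end_to_end_change`,
#'   `max_intermittent_fluctuation` (e.g. from [unit_qc()]).
#' @param min_rate_hz,max_end_change,max_fluctuation Criteria.
#' @return `qc` with logical `included` and a `reasons` string column
#'   (`""` for included units).
#' @export
apply_inclusion <- function(qc, min_rate_hz = 0.5, max_end_change = 0.10,
                            max_fluctuation = 0.20) {
  fail_rate <- qc$baseline_rate_hz < min_rate_hz
  fail_drift <- !(qc$end_to_end_change < max_end_change)
  fail_fluct <- !(qc$max_intermittent_fluctuation < max_fluctuation)
  qc$included <- !(fail_rate | fail_drift | fail_fluct)
  qc$reasons <- vapply(seq_len(nrow(qc)), function(i) {
    paste(c(if (fail_rate[i]) "low_baseline_rate",
            if (fail_drift[i]) "end_to_end_drift",
            if (fail_fluct[i]) "intermittent_fluctuation"),
          collapse = ";")
  }, character(1))
  qc
}
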