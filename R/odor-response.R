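#' Peristimulus time histogram for one cell-odor pair
#'
#' Bins a unit's spikes in 100 ms bins over a window around each onset of one
#' odor and averages across trials.
#'
#' @param times Spike times (s), sorted.
#' @param trials Trial table (`odor`, `onset_s`).
#' @param odor Odor id to align to.
#' @param bin_s Bin width (s), default 0.1.
#' @param window Window around onset (s), default `c(-2, 4)`; must contain
#'   the onset.
#' @return A `psth`: list with `counts` (trials x bins), `mean_rate_hz`,
#'   `edges` (bin edges relative to onset), `bin_s`, `n_trials`, `unit_odor`.
#' @export
build_psth <- function(times, trials, odor, bin_s = 0.1, window = c(-2, 4)) {
  stopifnot(bin_s > 0, length(window) == 2, window[1] < window[2])
  if (window[1] > 0 || window[2] <= 0) {
    stop("`window` must contain the odor onset (window[1] <= 0 < window[2])")
  }
  ons <- trials$onset_s[trials$odor == odor]
  if (length(ons) == 0) stop("no trials for odor ", odor)
  edges <- seq(window[1], window[2], by = bin_s)
  n_bins <- length(edges) - 1L
  abs_edges <- outer(edges, ons, "+") # (n_bins+1) x n_trials
  cum <- matrix(findInterval(abs_edges, times), nrow = n_bins + 1L)
  counts <- t(cum[-1L, , drop = FALSE] - cum[-(n_bins + 1L), , drop = FALSE])
  structure(list(counts = counts, mean_rate_hz = colMeans(counts) / bin_s,
                 edges = edges, bin_s = bin_s, n_trials = length(ons),
                 odor = odor),
            class = "psth")
}

#' Z-score a PSTH against its pre-odor baseline
#'
#' The baseline mean `mu_b` is the across-trial mean rate in the baseline
#' window (default 2 s before onset). The scale `sigma_b` depends on
#' `sd_mode`:
#' * `"sem"` (default): across-trial SD of single-trial baseline bin rates,
#'   pooled over baseline bins, divided by `sqrt(n_trials)` - the standard
#'   error of a trial-averaged bin rate, so that under stationary firing the
#'   per-bin z is calibrated and `|z| > 1.96` is a 5%-level test;
#' * `"trial"`: across-trial SD of the per-trial baseline-window rate;
#' * `"bins"`: SD across baseline bins of the trial-averaged PSTH.
#'
#' Each bin's z is `(mean rate - mu_b) / sigma_b`. A zero `sigma_b` (e.g. a
#' silent baseline) makes the pair unclassifiable (`z` all `NA`).
#'
#' @param psth A [build_psth()] result.
#' @param baseline_window Baseline window (s) relative to onset.
#' @param sd_mode Baseline-SD definition (see above).
#' @return A `zscored_psth`: the PSTH plus `mu_b_hz`, `sigma_b_hz`, `z`,
#'   `classifiable`.
#' @export
zscore_psth <- function(psth, baseline_window = c(-2, 0),
                        sd_mode = c("sem", "trial", "bins")) {
  sd_mode <- match.arg(sd_mode)
  stopifnot(inherits(psth, "psth"))
  e <- psth$edges
  nb <- length(e) - 1L
  in_base <- which(e[-length(e)] >= baseline_window[1] - 1e-9 &
                     e[-1] <= baseline_window[2] + 1e-9)
  if (length(in_base) < 1) stop("baseline window contains no bins")
  base_counts <- psth$counts[, in_base, drop = FALSE]
  blen <- length(in_base) * psth$bin_s
  per_trial_rate <- rowSums(base_counts) / blen
  mu_b <- mean(per_trial_rate)
  sigma_b <- switch(sd_mode,
    sem = sd(as.vector(base_counts) / psth$bin_s) / sqrt(psth$n_trials),
    trial = sd(per_trial_rate),
    bins = sd(psth$mean_rate_hz[in_base]))
  classifiable <- is.finite(sigma_b) && sigma_b > 0
  z <- if (classifiable) (psth$mean_rate_hz - mu_b) / sigma_b else
    rep(NA_real_, nb)
  out <- psth
  out$mu_b_hz <- mu_b
  out$sigma_b_hz <- sigma_b
  out$z <- z
  out$classifiable <- classifiable
  out$sd_mode <- sd_mode
  class(out) <- c("zscored_psth", "psth")
  out
}

#' Classify a cell-odor pair as excited, inhibited or non-responsive
#'
#' A pair is excited if any response-window bin has `z > threshold`, else
#' inhibited if any has `z < -threshold`, else not responsive. When both
#' thresholds are exceeded the larger `|z|` decides. Unclassifiable pairs
#' (zero baseline SD) get label `NA`.
#'
#' @param zpsth A [zscore_psth()] result.
#' @param response_window Window after onset (s) searched for significant
#'   bins.
#' @param threshold Z threshold (default 1.96).
#' @return List with `label` (`"excited"`, `"inhibited"`, `"none"` or `NA`),
#'   `peak_z` (extremal response-window z, the default signal-to-noise
#'   measure), `mean_z` (mean response-window z, the alternative
#'   signal-to-noise variant), `peak_bin` (index into the PSTH bins).
#' @export
classify_response <- function(zpsth, response_window = c(0, 2),
                              threshold = 1.96) {
  stopifnot(inherits(zpsth, "zscored_psth"), threshold > 0)
  if (!isTRUE(zpsth$classifiable)) {
    return(list(label = NA_character_, peak_z = NA_real_, mean_z = NA_real_,
                peak_bin = NA_integer_))
  }
  e <- zpsth$edges
  in_resp <- which(e[-length(e)] >= response_window[1] - 1e-9 &
                     e[-1] <= response_window[2] + 1e-9)
  if (length(in_resp) < 1) stop("response window contains no bins")
  zr <- zpsth$z[in_resp]
  zmax <- max(zr); zmin <- min(zr)
  exc <- zmax > threshold
  inh <- zmin < -threshold
  if (exc && inh) {
    if (abs(zmin) > zmax) exc <- FALSE else inh <- FALSE
  }
  mz <- mean(zr)
  if (exc) {
    i <- in_resp[which.max(zr)]
    list(label = "excited", peak_z = zmax, mean_z = mz, peak_bin = i)
  } else if (inh) {
    i <- in_resp[which.min(zr)]
    list(label = "inhibited", peak_z = zmin, mean_z = mz, peak_bin = i)
  } else {
    i <- in_resp[which.max(abs(zr))]
    list(label = "none", peak_z = zr[which.max(abs(zr))], mean_z = mz,
         peak_bin = i)
  }
}

#' Peak response and width of a baseline-subtracted PSTH
#'
#' Subtracts the mean rate of the subtraction window (default 1 s before
#' onset) from the whole PSTH, then reports the extremum in the response
#' window (maximum for excited, minimum for inhibited pairs) and its full
#' width at half extremum, measured on the unsmoothed PSTH with linear
#' interpolation between bin centers.
#'
#' @param psth A [build_psth()] result.
#' @param label `"excited"` or `"inhibited"` (direction of the extremum);
#'   `"none"` uses the largest absolute deviation.
#' @param subtract_window Baseline-subtraction window (s).
#' @param response_window Search window (s).
#' @return List with `peak_hz` (baseline-subtracted extremum) and `width_s`
#'   (full width at half extremum; `NA` if the half level is never crossed or
#'   the PSTH is flat).
#' @export
peak_metrics <- function(psth, label = "excited", subtract_window = c(-1, 0),
                         response_window = c(0, 2)) {
  stopifnot(inherits(psth, "psth"))
  e <- psth$edges
  centers <- e[-length(e)] + psth$bin_s / 2
  in_sub <- which(e[-length(e)] >= subtract_window[1] - 1e-9 &
                    e[-1] <= subtract_window[2] + 1e-9)
  if (length(in_sub) < 1) stop("subtraction window contains no bins")
  curve <- psth$mean_rate_hz - mean(psth$mean_rate_hz[in_sub])
  in_resp <- which(e[-length(e)] >= response_window[1] - 1e-9 &
                     e[-1] <= response_window[2] + 1e-9)
  seg <- curve[in_resp]
  sgn <- switch(label,
                excited = 1,
                inhibited = -1,
                if (max(abs(seg)) == 0) 1 else sign(seg[which.max(abs(seg))]))
  peak_rel <- max(sgn * seg)
  peak_idx <- in_resp[which.max(sgn * seg)]
  peak <- sgn * peak_rel
  if (peak_rel <= 0) {
    return(list(peak_hz = peak, width_s = NA_real_))
  }
  half <- peak_rel / 2
  y <- sgn * curve # peak is a positive maximum of y
  # walk left / right from peak bin to the half-height crossings
  left <- NA_real_
  for (i in seq(peak_idx, 2)) {
    if (y[i - 1] <= half && y[i] > half) {
      f <- (half - y[i - 1]) / (y[i] - y[i - 1])
      left <- centers[i - 1] + f * psth$bin_s
      break
    }
  }
  right <- NA_real_
  for (i in seq(peak_idx, length(y) - 1)) {
    if (y[i + 1] <= half && y[i] > half) {
      f <- (y[i] - half) / (y[i] - y[i + 1])
      right <- centers[i] + f * psth$bin_s
      break
    }
  }
  width <- if (is.na(left) || is.na(right)) NA_real_ else right - left
  list(peak_hz = peak, width_s = width)
}

#' Classify every cell-odor pair of a session
#'
#' Runs [build_psth()], [zscore_psth()], [classify_response()] and
#' [peak_metrics()] for all unit x odor combinations.
#'
#' @param spikes List of spike-time vectors (one per unit); names or indices
#'   identify units.
#' @param trials Trial table (`odor`, `onset_s`).
#' @param units Optional subset of unit indices (e.g. QC-included units).
#' @param bin_s,window,baseline_window,sd_mode,response_window,threshold,subtract_window
#'   Passed to the underlying steps.
#' @return Data.frame with one row per cell-odor pair: `unit`, `odor`,
#'   `label`, `peak_z`, `peak_hz`, `width_s`, `baseline_hz` (the pair's
#'   `mu_b`).
#' @export
classify_session <- function(spikes, trials, units = seq_along(spikes),
                             bin_s = 0.1, window = c(-2, 4),
                             baseline_window = c(-2, 0), sd_mode = "sem",
                             response_window = c(0, 2), threshold = 1.96,
                             subtract_window = c(-1, 0)) {
  odors <- sort(unique(trials$odor))
  rows <- vector("list", length(units) * length(odors))
  k <- 0L
  for (u in units) {
    for (o in odors) {
      p <- build_psth(spikes[[u]], trials, o, bin_s, window)
      zp <- zscore_psth(p, baseline_window, sd_mode)
      cl <- classify_response(zp, response_window, threshold)
      pm <- if (is.na(cl$label) || cl$label == "none") {
        list(peak_hz = NA_real_, width_s = NA_real_)
      } else {
        peak_metrics(p, cl$label, subtract_window, response_window)
      }
      k <- k + 1L
      rows[[k]] <- data.frame(unit = u, odor = o, label = cl$label,
                              peak_z = cl$peak_z, mean_z = cl$mean_z,
                              peak_hz = pm$peak_hz, width_s = pm$width_s,
                              baseline_hz = zp$mu_b_hz)
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

#' Session-level response summary and E/I ratio
#'
#' Aggregates per-pair labels into the session summary: fraction of
#' responsive units (at least one significant odor), tuning broadness
#' (significant odors per unit), counts of excited and inhibited pairs, their
#' E/I ratio, and mean baseline firing over all units and over excited units.
#'
#' @param pairs Data.frame from [classify_session()].
#' @return List with `n_units`, `fraction_responsive`, `broadness` (named
#'   per-unit counts), `n_excited`, `n_inhibited`, `ei_ratio` (`NA` when no
#'   inhibited pairs), `mean_baseline_hz_all`, `mean_baseline_hz_excited`.
#' @export
summarize_session <- function(pairs) {
  ok <- !is.na(pairs$label)
  n_exc <- sum(pairs$label[ok] == "excited")
  n_inh <- sum(pairs$label[ok] == "inhibited")
  sig <- ok & pairs$label != "none"
  broadness <- c(tapply(sig, pairs$unit, sum))
  unit_base <- c(tapply(pairs$baseline_hz, pairs$unit, mean))
  excited_units <- names(which(tapply(ok & pairs$label == "excited",
                                      pairs$unit, any)))
  list(n_units = length(unique(pairs$unit)),
       fraction_responsive = mean(broadness > 0),
       broadness = broadness,
       n_excited = n_exc,
       n_inhibited = n_inh,
       ei_ratio = if (n_inh > 0) n_exc / n_inh else NA_real_,
       mean_baseline_hz_all = mean(unit_base),
       mean_baseline_hz_excited = if (length(excited_units)) {
         mean(unit_base[excited_units])
       } else NA_real_)
}
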