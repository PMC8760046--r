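#' Common-median referencing and band-pass filtering
#'
#' Subtracts the per-sample median across all channels from each channel
#' (common-median reference, removing shared artifacts), then applies a
#' zero-phase Butterworth band-pass (forward-backward filtering; appropriate
#' for offline analysis).
#'
#' @param rec A `voltage_recording` (see [render_traces()], [read_traces()]).
#' @param config A [detection_config()].
#' @param reference Apply the common-median reference (default `TRUE`;
#'   requires at least 2 channels).
#' @return The recording with filtered `traces` (same dimensions).
#' @export
reference_and_filter <- function(rec, config = detection_config(),
                                 reference = TRUE) {
  stopifnot(inherits(config, "detection_config"))
  x <- rec$traces
  fs <- rec$sampling_rate_hz
  if (fs <= 2 * config$band_high_hz) {
    stop("sampling rate must exceed twice the upper band edge")
  }
  if (reference) {
    if (ncol(x) < 2) stop("common-median referencing needs >= 2 channels")
    x <- x - apply(x, 1, median)
  }
  bf <- signal::butter(config$filter_order,
                       c(config$band_low_hz, config$band_high_hz) / (fs / 2),
                       type = "pass")
  for (ch in seq_len(ncol(x))) {
    x[, ch] <- signal::filtfilt(bf, x[, ch])
  }
  rec$traces <- x
  rec
}

#' MAD-multiple spike threshold
#'
#' Threshold = `k` times the median absolute deviation of the filtered trace.
#' The MAD is used raw (median of absolute deviations from the median), not
#' rescaled to a Gaussian SD estimate, unless `scaled = TRUE` divides it by
#' 0.6745.
#'
#' @param x Filtered single-channel trace.
#' @param k Threshold multiplier.
#' @param scaled Use the 0.6745-scaled (SD-calibrated) variant.
#' @return Threshold in the units of `x`.
#' @export
compute_threshold <- function(x, k = 7.5, scaled = FALSE) {
  stopifnot(k > 0)
  m <- median(x)
  mad_raw <- median(abs(x - m))
  if (mad_raw == 0) {
    stop("degenerate input: MAD of the trace is zero (constant trace)")
  }
  k * if (scaled) mad_raw / 0.6745 else mad_raw
}

# local maxima of y strictly above thr (plateau-safe: left-strict rise)
find_peaks <- function(y, thr) {
  n <- length(y)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  cand <- i[y[i] > y[i - 1] & y[i] >= y[i + 1] & y[i] > thr]
  cand
}

#' Detect spike events on a filtered recording
#'
#' Per channel, local maxima of the inverted (polarity `"negative"`) or
#' rectified (`"absolute"`) trace above that channel's threshold are taken as
#' candidate peaks. Candidates of all channels of a tetrode are pooled and
#' pruned by height to the minimum separation: accepting peaks in decreasing
#' amplitude order, any candidate within `min_separation_s` of an accepted
#' event is discarded. This both removes multiple detections of one
#' multiphasic spike and merges cross-channel detections, keeping the
#' timestamp of the highest peak. Waveforms are extracted
#' `-waveform_pre..+waveform_post` samples around the peak on all channels of
#' the tetrode; events too close to the trace edges are discarded.
#'
#' @param rec Filtered `voltage_recording` (see [reference_and_filter()]).
#' @param thresholds Per-channel thresholds; default computed with
#'   [compute_threshold()] from the config's `threshold_k`.
#' @param config A [detection_config()].
#' @return List with `events` (data.frame: `timestamp_s`, `sample`, `tetrode`,
#'   `peak_channel`, `amplitude_uv`) and `waveforms` (list of
#'   samples x 4 matrices, one per event).
#' @export
detect_events <- function(rec, config = detection_config(),
                          thresholds = NULL) {
  stopifnot(inherits(config, "detection_config"))
  x <- rec$traces
  fs <- rec$sampling_rate_hz
  if (is.null(thresholds)) {
    thresholds <- vapply(seq_len(ncol(x)), function(ch) {
      compute_threshold(x[, ch], config$threshold_k, config$mad_scaled)
    }, numeric(1))
  }
  stopifnot(length(thresholds) == ncol(x))
  y <- if (config$polarity == "negative") -x else abs(x)
  min_sep <- round(config$min_separation_s * fs)
  pre <- config$waveform_pre
  post <- config$waveform_post

  ev_list <- list()
  wf_list <- list()
  for (tet in unique(rec$tetrode)) {
    chans <- which(rec$tetrode == tet)
    cand_s <- integer(0); cand_ch <- integer(0); cand_a <- numeric(0)
    for (ch in chans) {
      p <- find_peaks(y[, ch], thresholds[ch])
      cand_s <- c(cand_s, p)
      cand_ch <- c(cand_ch, rep(ch, length(p)))
      cand_a <- c(cand_a, y[p, ch])
    }
    if (length(cand_s) == 0) next
    o <- order(cand_a, decreasing = TRUE)
    cand_s <- cand_s[o]; cand_ch <- cand_ch[o]; cand_a <- cand_a[o]
    kept_s <- integer(0); kept_ch <- integer(0); kept_a <- numeric(0)
    for (i in seq_along(cand_s)) {
      if (length(kept_s) == 0 || all(abs(kept_s - cand_s[i]) >= min_sep)) {
        kept_s <- c(kept_s, cand_s[i])
        kept_ch <- c(kept_ch, cand_ch[i])
        kept_a <- c(kept_a, cand_a[i])
      }
    }
    ok <- kept_s - pre >= 1 & kept_s + post <= nrow(x)
    kept_s <- kept_s[ok]; kept_ch <- kept_ch[ok]; kept_a <- kept_a[ok]
    if (length(kept_s) == 0) next
    ev_list[[length(ev_list) + 1L]] <- data.frame(
      timestamp_s = (kept_s - 1) / fs, sample = kept_s, tetrode = tet,
      peak_channel = kept_ch, amplitude_uv = kept_a)
    wf_list <- c(wf_list, lapply(kept_s, function(s0) {
      x[(s0 - pre):(s0 + post), chans, drop = FALSE]
    }))
  }
  if (length(ev_list) == 0) {
    return(list(events = data.frame(timestamp_s = numeric(0),
                                    sample = integer(0), tetrode = integer(0),
                                    peak_channel = integer(0),
                                    amplitude_uv = numeric(0)),
                waveforms = list()))
  }
  events <- do.call(rbind, ev_list)
  o <- order(events$timestamp_s)
  list(events = events[o, , drop = FALSE], waveforms = wf_list[o])
}

#' Match detected events against ground-truth spike times
#'
#' One-to-one greedy matching within a tolerance, used to score recall and
#' precision of the detection chain on rendered synthetic traces.
#'
#' @param detected_s,truth_s Sorted (or unsorted) time vectors (s).
#' @param tol_s Matching tolerance (s).
#' @return List with `n_matched`, `recall`, `precision`.
#' @export
match_spike_times <- function(detected_s, truth_s, tol_s = 0.001) {
  detected_s <- sort(detected_s)
  truth_s <- sort(truth_s)
  i <- 1L; j <- 1L; m <- 0L
  while (i <= length(detected_s) && j <= length(truth_s)) {
    d <- detected_s[i] - truth_s[j]
    if (abs(d) <= tol_s) {
      m <- m + 1L; i <- i + 1L; j <- j + 1L
    } else if (d < 0) i <- i + 1L else j <- j + 1L
  }
  list(n_matched = m,
       recall = if (length(truth_s)) m / length(truth_s) else NA_real_,
       precision = if (length(detected_s)) m / length(detected_s) else NA_real_)
}
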