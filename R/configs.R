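#' Session configuration for the synthetic odor-session generator
#'
#' Describes one head-fixed recording session: the odor panel and trial
#' schedule, the spiking statistics of the simulated units, and the mixture of
#' odor-excited / odor-inhibited cell-odor pairs. Defaults mirror the awake
#' AON recording design: 7 aldehyde odorants, each delivered 30 times in a
#' pseudo-randomized order with at most 3 consecutive presentations of the
#' same odorant, 500 ms stimulus, 10 s inter-trial interval.
#'
#' @param n_units Number of simulated single units.
#' @param n_odors Number of odorants in the panel.
#' @param n_trials_per_odor Presentations of each odorant.
#' @param stim_duration_s Odor stimulus duration (s).
#' @param iti_s Inter-trial interval (s), onset-spacing is
#'   `stim_duration_s + iti_s`.
#' @param max_consecutive_repeats Maximum allowed run of identical odors in
#'   the pseudo-randomized schedule.
#' @param p_excited,p_inhibited Probability that a given cell-odor pair is
#'   odor-excited / odor-inhibited; must sum to at most 1.
#' @param baseline_rate_mean_hz,baseline_rate_sd_hz Mean and SD (Hz) of the
#'   log-normal distribution of per-unit baseline firing rates.
#' @param excited_gain,inhibited_gain Multiplicative rate factor applied
#'   within the response window of odors for which a pair is labeled.
#' @param response_window_s Duration after odor onset over which the gain
#'   acts (covers responses outlasting the 0.5 s stimulus).
#' @param balanced_labels If `TRUE`, plant exactly `round(p * n_pairs)`
#'   excited/inhibited cell-odor pairs at random positions instead of
#'   independent per-pair draws, so the population E/I ratio equals
#'   `p_excited / p_inhibited` by construction (used by the
#'   parameter-recovery profiles); default independent draws.
#' @param first_onset_s Time of the first odor onset; the default leaves a
#'   full 2 s pre-odor baseline window and margin before it.
#' @param seed Optional integer seed; fixing it makes the generated session
#'   fully reproducible.
#'
#' @return An object of class `session_config` (a validated list).
#' @seealso [generate_session()]
#' @export
session_config <- function(n_units,
                           n_odors = 7,
                           n_trials_per_odor = 30,
                           stim_duration_s = 0.5,
                           iti_s = 10,
                           max_consecutive_repeats = 3,
                           p_excited = 0.1,
                           p_inhibited = 0.05,
                           baseline_rate_mean_hz = 5,
                           baseline_rate_sd_hz = 3,
                           excited_gain = 3,
                           inhibited_gain = 0.1,
                           response_window_s = 2,
                           first_onset_s = 10,
                           balanced_labels = FALSE,
                           seed = NULL) {
  stopifnot(length(n_units) == 1, n_units >= 0,
            n_odors >= 1, n_trials_per_odor >= 1,
            stim_duration_s > 0, iti_s > 0, max_consecutive_repeats >= 1,
            baseline_rate_mean_hz > 0, baseline_rate_sd_hz >= 0,
            excited_gain > 0, inhibited_gain > 0,
            response_window_s > 0, first_onset_s >= 0)
  if (p_excited < 0 || p_inhibited < 0 || p_excited > 1 || p_inhibited > 1 ||
      p_excited + p_inhibited > 1) {
    stop("`p_excited` and `p_inhibited` must be probabilities with ",
         "p_excited + p_inhibited <= 1")
  }
  if (n_odors == 1 && n_trials_per_odor > max_consecutive_repeats) {
    stop("impossible schedule: a single odor cannot satisfy the ",
         "maximum-consecutive-repeat constraint")
  }
  if (response_window_s > stim_duration_s + iti_s) {
    stop("`response_window_s` may not exceed the onset spacing ",
         "(stim_duration_s + iti_s): response windows would overlap")
  }
  structure(as.list(environment()), class = "session_config")
}

#' Trace-rendering configuration
#'
#' Parameters for rendering spike trains into raw multichannel voltage
#' traces: tetrode geometry, spike waveform template, per-unit amplitudes and
#' additive Gaussian noise. Defaults follow the recording hardware of the
#' emulated experiments (30 kHz sampling, tetrode groups of 4 channels).
#'
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param n_channels Number of channels; must be a positive multiple of 4
#'   (tetrode groups).
#' @param template Spike waveform template (numeric vector, arbitrary units,
#'   most-negative sample = -1 by convention); default a 1 ms biphasic
#'   negative-first shape from [spike_template()].
#' @param template_amplitude_uv Median peak amplitude (uV) of the per-unit
#'   log-normal amplitude distribution.
#' @param amplitude_sdlog Log-scale SD of per-unit amplitudes.
#' @param noise_sd_uv SD (uV) of the iid Gaussian noise added per sample.
#' @param uv_per_bit Quantization step used when writing 16-bit binary files.
#' @param seed Optional integer seed.
#'
#' @return An object of class `trace_config`.
#' @seealso [render_traces()]
#' @export
trace_config <- function(sampling_rate_hz = 30000,
                         n_channels = 4,
                         template = spike_template(sampling_rate_hz),
                         template_amplitude_uv = 100,
                         amplitude_sdlog = 0.2,
                         noise_sd_uv = 10,
                         uv_per_bit = 0.195,
                         seed = NULL) {
  stopifnot(sampling_rate_hz > 0, length(template) >= 1,
            template_amplitude_uv > 0, amplitude_sdlog >= 0,
            noise_sd_uv >= 0, uv_per_bit > 0)
  if (n_channels < 4 || n_channels %% 4 != 0) {
    stop("`n_channels` must be a positive multiple of 4 (tetrode groups)")
  }
  structure(as.list(environment()), class = "trace_config")
}

#' Spike-detection configuration
#'
#' Preprocessing and detection parameters: common-median referencing is
#' followed by a 4th-order Butterworth band-pass (300-5000 Hz), the per-channel
#' detection threshold is a multiple (default 7.5x) of the raw median absolute
#' deviation of the filtered trace, temporally proximal peaks within a tetrode
#' are pruned by height to a minimum separation of 1 ms, and waveforms are
#' extracted -10..+21 samples around the peak.
#'
#' @param band_low_hz,band_high_hz Band-pass edges (Hz).
#' @param filter_order Butterworth order (MATLAB convention: the band-pass has
#'   `2 * filter_order` poles).
#' @param threshold_k Threshold multiplier applied to the MAD.
#' @param mad_scaled If `TRUE`, divide the raw MAD by 0.6745 so the threshold
#'   is expressed in Gaussian-SD units; the default uses the raw MAD.
#' @param min_separation_s Minimum separation between same-tetrode events (s).
#' @param waveform_pre,waveform_post Samples kept before/after the peak
#'   (default -10..+21, i.e. 32 samples).
#' @param polarity `"negative"` to detect negative-going peaks on the inverted
#'   trace (extracellular convention), `"absolute"` to detect on the rectified
#'   trace.
#'
#' @return An object of class `detection_config`.
#' @seealso [reference_and_filter()], [detect_events()]
#' @export
detection_config <- function(band_low_hz = 300,
                             band_high_hz = 5000,
                             filter_order = 4,
                             threshold_k = 7.5,
                             mad_scaled = FALSE,
                             min_separation_s = 0.001,
                             waveform_pre = 10,
                             waveform_post = 21,
                             polarity = c("negative", "absolute")) {
  polarity <- match.arg(polarity)
  stopifnot(band_low_hz > 0, band_high_hz > band_low_hz, filter_order >= 1,
            threshold_k > 0, min_separation_s >= 0,
            waveform_pre >= 0, waveform_post >= 0)
  structure(list(band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 filter_order = filter_order, threshold_k = threshold_k,
                 mad_scaled = mad_scaled, min_separation_s = min_separation_s,
                 waveform_pre = waveform_pre, waveform_post = waveform_post,
                 polarity = polarity),
            class = "detection_config")
}
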