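#' Biphasic spike waveform template
#'
#' A 1 ms negative-first biphasic shape: a sharp Gaussian trough (the
#' sodium-current deflection, ~0.16 ms full width) followed by a slower,
#' smaller repolarization bump - the classic extracellular action-potential
#' silhouette. The template is scaled so its most negative sample equals -1;
#' multiplying by a per-unit amplitude gives the rendered peak in uV.
#'
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param duration_s Template duration (s); default 1 ms.
#' @return Numeric vector of template samples; attribute `peak_index` marks
#'   the (1-based) index of the negative peak.
#' @export
spike_template <- function(sampling_rate_hz = 30000, duration_s = 0.001) {
  n <- max(4L, round(sampling_rate_hz * duration_s))
  i <- seq_len(n) - 1L
  # trough centered exactly on a sample so rendered peaks align to the grid
  i0 <- round(0.3 * (n - 1))
  i1 <- round(0.65 * (n - 1))
  w <- -exp(-0.5 * ((i - i0) / (0.07 * (n - 1)))^2) +
    0.35 * exp(-0.5 * ((i - i1) / (0.25 * (n - 1)))^2)
  w <- w / max(abs(pmin(w, 0)))
  structure(w, peak_index = which.min(w))
}

#' Render spike trains into raw multichannel voltage traces
#'
#' Places each unit's waveform template at its spike times on the four
#' channels of the unit's tetrode (with a fixed fall-off across channels, the
#' peak channel rotating across units) and adds iid Gaussian noise.
#' Overlapping templates superpose linearly.
#'
#' @param spikes List of spike-time vectors (s), one per unit.
#' @param config A [trace_config()].
#' @param duration_s Trace duration (s); default covers the last spike plus
#'   margin.
#' @param unit_tetrode Optional integer vector assigning units to tetrodes
#'   (default round-robin).
#' @return A `voltage_recording`: list with `traces` (samples x channels
#'   matrix, uV), `sampling_rate_hz`, `tetrode` (channel -> tetrode map),
#'   `uv_per_bit`, `truth` (per unit: placed peak sample indices and
#'   amplitudes).
#' @export
render_traces <- function(spikes, config = trace_config(), duration_s = NULL,
                          unit_tetrode = NULL) {
  stopifnot(inherits(config, "trace_config"))
  if (config$n_channels < 1) stop("zero channels")
  if (!is.null(config$seed)) set.seed(config$seed)
  fs <- config$sampling_rate_hz
  n_units <- length(spikes)
  if (is.null(duration_s)) {
    last <- if (n_units > 0 && any(lengths(spikes) > 0)) {
      max(unlist(spikes))
    } else 0
    duration_s <- last + 0.1
  }
  n_samples <- ceiling(duration_s * fs)
  n_tet <- config$n_channels %/% 4L
  if (is.null(unit_tetrode)) {
    unit_tetrode <- if (n_units) ((seq_len(n_units) - 1L) %% n_tet) + 1L
    else integer(0)
  }
  stopifnot(length(unit_tetrode) == n_units, all(unit_tetrode %in% seq_len(n_tet)))

  tmpl <- config$template
  pk <- attr(tmpl, "peak_index")
  if (is.null(pk)) pk <- which.min(tmpl)
  L <- length(tmpl)
  falloff <- c(1, 0.55, 0.35, 0.2)

  traces <- matrix(if (config$noise_sd_uv > 0) {
    rnorm(n_samples * config$n_channels, 0, config$noise_sd_uv)
  } else 0, nrow = n_samples, ncol = config$n_channels)

  amp <- if (n_units) {
    config$template_amplitude_uv * rlnorm(n_units, 0, config$amplitude_sdlog)
  } else numeric(0)
  truth <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    st <- spikes[[u]]
    peak_samp <- round(st * fs) + 1L
    ok <- peak_samp - pk + 1L >= 1L & peak_samp - pk + L <= n_samples
    peak_samp <- peak_samp[ok]
    chans <- (unit_tetrode[u] - 1L) * 4L + seq_len(4L)
    w_order <- ((u - 1L + 0:3) %% 4L) + 1L # rotate peak channel across units
    for (ci in seq_len(4L)) {
      w <- amp[u] * falloff[w_order[ci]]
      ch <- chans[ci]
      for (s0 in peak_samp) {
        ix <- (s0 - pk + 1L):(s0 - pk + L)
        traces[ix, ch] <- traces[ix, ch] + w * tmpl
      }
    }
    truth[[u]] <- list(peak_sample = peak_samp, amplitude_uv = amp[u],
                       tetrode = unit_tetrode[u],
                       peak_channel = chans[w_order == 1L])
  }
  structure(list(traces = traces, sampling_rate_hz = fs,
                 tetrode = rep(seq_len(n_tet), each = 4L),
                 uv_per_bit = config$uv_per_bit, truth = truth),
            class = "voltage_recording")
}

#' Write / read raw traces as flat binary with a JSON sidecar
#'
#' Traces are stored channel-interleaved as little-endian 16-bit signed
#' integers; the sidecar records sampling rate, channel count, tetrode map and
#' the uV-per-bit quantization step.
#'
#' @param rec A `voltage_recording` (see [render_traces()]).
#' @param bin_path,json_path Output / input file paths.
#' @return `write_traces()` returns `bin_path` invisibly; `read_traces()`
#'   returns a `voltage_recording`.
#' @export
write_traces <- function(rec, bin_path, json_path = paste0(bin_path, ".json")) {
  q <- round(rec$traces / rec$uv_per_bit)
  q <- pmin(pmax(q, -32768), 32767)
  con <- file(bin_path, "wb")
  on.exit(close(con))
  # t(): channel-interleaved sample frames
  writeBin(as.integer(t(q)), con, size = 2L, endian = "little")
  meta <- list(sampling_rate_hz = rec$sampling_rate_hz,
               n_channels = ncol(rec$traces),
               tetrode = rec$tetrode,
               uv_per_bit = rec$uv_per_bit,
               dtype = "int16le-interleaved")
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(bin_path)
}

#' @rdname write_traces
#' @export
read_traces <- function(bin_path, json_path = paste0(bin_path, ".json")) {
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  n <- file.info(bin_path)$size / 2
  con <- file(bin_path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                 endian = "little")
  traces <- matrix(raw * meta$uv_per_bit, ncol = meta$n_channels, byrow = TRUE)
  structure(list(traces = traces, sampling_rate_hz = meta$sampling_rate_hz,
                 tetrode = meta$tetrode, uv_per_bit = meta$uv_per_bit,
                 truth = NULL),
            class = "voltage_recording")
}
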