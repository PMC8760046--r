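#' Pseudo-randomized odor schedule
#'
#' Draws a permutation of the full trial list (each odor exactly
#' `n_trials_per_odor` times) by rejection sampling until no odor occurs more
#' than `max_consecutive_repeats` times in a row.
#'
#' @param n_odors Number of odors.
#' @param n_trials_per_odor Trials per odor.
#' @param max_consecutive_repeats Longest allowed run of one odor.
#' @param max_attempts Rejection-sampling cap before giving up.
#' @return Integer vector of odor ids, length `n_odors * n_trials_per_odor`.
#' @export
odor_schedule <- function(n_odors, n_trials_per_odor,
                          max_consecutive_repeats = 3,
                          max_attempts = 10000L) {
  if (n_odors == 1 && n_trials_per_odor > max_consecutive_repeats) {
    stop("impossible schedule: a single odor cannot satisfy the ",
         "maximum-consecutive-repeat constraint")
  }
  base <- rep(seq_len(n_odors), each = n_trials_per_odor)
  for (i in seq_len(max_attempts)) {
    sched <- sample(base)
    if (max(rle(sched)$lengths) <= max_consecutive_repeats) return(sched)
  }
  stop("could not draw a schedule satisfying the repeat constraint in ",
       max_attempts, " attempts")
}

#' Generate a ground-truthed synthetic odor session
#'
#' Simulates spike timestamp tables for `n_units` units recorded during a
#' pseudo-randomized odor session. Each unit fires as an inhomogeneous Poisson
#' process: a constant baseline rate (drawn log-normal across units)
#' multiplied by `excited_gain` or `inhibited_gain` inside the response window
#' of odors for which the cell-odor pair carries the corresponding ground-truth
#' label. Labels are drawn independently per pair with probabilities
#' `p_excited` / `p_inhibited`.
#'
#' @param config A [session_config()].
#' @return A list with elements:
#'   * `spikes`: list of sorted spike-time vectors (s), one per unit;
#'   * `trials`: data.frame with `trial`, `odor`, `onset_s`;
#'   * `truth`: list with `labels` (units x odors character matrix in
#'     `{"excited","inhibited","none"}`) and `baseline_hz` (per-unit true
#'     rate);
#'   * `span_s`: session duration;
#'   * `config`: the input configuration.
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n_trials <- config$n_odors * config$n_trials_per_odor
  sched <- odor_schedule(config$n_odors, config$n_trials_per_odor,
                         config$max_consecutive_repeats)
  spacing <- config$stim_duration_s + config$iti_s
  onsets <- config$first_onset_s + (seq_len(n_trials) - 1) * spacing
  trials <- data.frame(trial = seq_len(n_trials), odor = sched,
                       onset_s = onsets)
  span <- config$first_onset_s + n_trials * spacing

  n_units <- config$n_units
  if (n_units == 0) {
    return(list(spikes = list(), trials = trials,
                truth = list(labels = matrix(character(0), 0, config$n_odors),
                             baseline_hz = numeric(0)),
                span_s = span, config = config))
  }

  # log-normal baseline rates parameterized by mean/SD on the Hz scale
  cv2 <- (config$baseline_rate_sd_hz / config$baseline_rate_mean_hz)^2
  sdlog <- sqrt(log1p(cv2))
  meanlog <- log(config$baseline_rate_mean_hz) - sdlog^2 / 2
  base_hz <- rlnorm(n_units, meanlog, sdlog)

  n_pairs <- n_units * config$n_odors
  lab_vec <- if (config$balanced_labels) {
    n_exc <- round(config$p_excited * n_pairs)
    n_inh <- round(config$p_inhibited * n_pairs)
    sample(c(rep("excited", n_exc), rep("inhibited", n_inh),
             rep("none", n_pairs - n_exc - n_inh)))
  } else {
    sample(c("excited", "inhibited", "none"), n_pairs, replace = TRUE,
           prob = c(config$p_excited, config$p_inhibited,
                    1 - config$p_excited - config$p_inhibited))
  }
  labels <- matrix(lab_vec, nrow = n_units, ncol = config$n_odors)

  win <- config$response_window_s
  onsets_by_odor <- split(trials$onset_s, trials$odor)
  spikes <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    r <- base_hz[u]
    n_base <- rpois(1, r * span)
    s <- runif(n_base, 0, span)
    extra <- NULL
    drop_in <- NULL # window starts where thinning applies
    for (o in seq_len(config$n_odors)) {
      lab <- labels[u, o]
      if (lab == "none") next
      ons <- onsets_by_odor[[as.character(o)]]
      if (lab == "excited") {
        n_extra <- rpois(length(ons), r * (config$excited_gain - 1) * win)
        if (sum(n_extra) > 0) {
          extra <- c(extra, rep(ons, n_extra) + runif(sum(n_extra), 0, win))
        }
      } else {
        drop_in <- c(drop_in, ons)
      }
    }
    if (length(drop_in) > 0) {
      # thin baseline spikes inside inhibited response windows
      drop_in <- sort(drop_in)
      idx <- findInterval(s, as.vector(rbind(drop_in, drop_in + win)))
      inside <- idx %% 2L == 1L
      keep <- !inside | runif(length(s)) < config$inhibited_gain
      s <- s[keep]
    }
    spikes[[u]] <- sort(c(s, extra))
  }

  list(spikes = spikes, trials = trials,
       truth = list(labels = labels, baseline_hz = base_hz),
       span_s = span, config = config)
}
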