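# shared fixtures built in code

# minimal one-odor trial table with the standard spacing
one_odor_trials <- function(n_trials = 30, first_onset = 10, spacing = 10.5) {
  data.frame(trial = seq_len(n_trials), odor = 1,
             onset_s = first_onset + (seq_len(n_trials) - 1) * spacing)
}

# stationary Poisson spike train on [0, span]
poisson_train <- function(rate_hz, span_s) {
  sort(runif(rpois(1, rate_hz * span_s), 0, span_s))
}
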