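test_that("PSTH of a silent unit is all zero with the right shape", {
  p <- build_psth(numeric(0), one_odor_trials(), 1)
  expect_equal(dim(p$counts), c(30, 60))
  expect_true(all(p$mean_rate_hz == 0))
  expect_equal(p$edges[1], -2)
  expect_equal(p$edges[length(p$edges)], 4)
  expect_error(build_psth(numeric(0), one_odor_trials(), 1,
                          window = c(1, 3)), "onset")
})

test_that("PSTH bin means are unbiased for stationary Poisson firing", {
  set.seed(1)
  trials <- one_odor_trials()
  spk <- poisson_train(10, 330)
  p <- build_psth(spk, trials, 1)
  se <- sqrt(10 / 0.1 / 30) # analytic SE of a trial-averaged bin rate
  expect_true(all(abs(p$mean_rate_hz - 10) < 3.5 * se))
  expect_equal(mean(p$mean_rate_hz), 10, tolerance = 0.1)
})

test_that("z is zero for bins at the baseline mean and NA when sigma_b = 0", {
  set.seed(2)
  trials <- one_odor_trials(20)
  spk <- poisson_train(5, 230)
  zp <- zscore_psth(build_psth(spk, trials, 1))
  flat_bins <- which(abs(zp$mean_rate_hz - zp$mu_b_hz) < 1e-12)
  expect_true(all(abs(zp$z[flat_bins]) < 1e-12))
  # silent baseline: sigma_b = 0, pair unclassifiable
  zp0 <- zscore_psth(build_psth(numeric(0), trials, 1))
  expect_false(zp0$classifiable)
  expect_true(all(is.na(zp0$z)))
  expect_identical(classify_response(zp0)$label, NA_character_)
})

test_that("z-scores are invariant under global rate scaling", {
  trials <- one_odor_trials()
  set.seed(3)
  spk <- poisson_train(6, 330)
  p <- build_psth(spk, trials, 1)
  z1 <- zscore_psth(p)$z
  p3 <- p
  p3$counts <- p$counts * 3
  p3$mean_rate_hz <- p$mean_rate_hz * 3
  expect_equal(zscore_psth(p3)$z, z1, tolerance = 1e-12)
})

test_that("null per-bin exceedance rate is calibrated", {
  # stationary Poisson pairs: fraction of response-window bins with
  # |z| > 1.96 should sit near the nominal 5% (Poisson discreteness and the
  # estimated sigma_b inflate it slightly)
  set.seed(4)
  trials <- one_odor_trials()
  hits <- 0L; tot <- 0L
  for (i in 1:300) {
    spk <- poisson_train(10, 330)
    zp <- zscore_psth(build_psth(spk, trials, 1))
    e <- zp$edges
    in_resp <- which(e[-length(e)] >= 0 & e[-1] <= 2)
    hits <- hits + sum(abs(zp$z[in_resp]) > 1.96)
    tot <- tot + length(in_resp)
  }
  expect_gte(hits / tot, 0.03)
  expect_lte(hits / tot, 0.08)
})

test_that("classification is monotone in the threshold", {
  set.seed(5)
  trials <- one_odor_trials()
  for (i in 1:20) {
    spk <- poisson_train(8, 330)
    zp <- zscore_psth(build_psth(spk, trials, 1))
    labs <- vapply(c(1.5, 1.96, 2.5, 3.5), function(th) {
      classify_response(zp, threshold = th)$label
    }, character(1))
    # once "none", never significant again at a higher threshold
    first_none <- match("none", labs)
    if (!is.na(first_none) && first_none < length(labs)) {
      expect_true(all(labs[first_none:length(labs)] == "none"))
    }
  }
})

test_that("a planted excited pair is detected with near-certain power", {
  # baseline 10 Hz, gain 2 during the 0.5 s stimulus, 30 trials
  set.seed(6)
  trials <- one_odor_trials()
  detected <- vapply(1:50, function(i) {
    base <- poisson_train(10, 330)
    extra <- rep(trials$onset_s, rpois(30, 10 * 0.5))
    extra <- extra + runif(length(extra), 0, 0.5)
    spk <- sort(c(base, extra))
    zp <- zscore_psth(build_psth(spk, trials, 1))
    classify_response(zp)$label
  }, character(1))
  expect_gte(mean(detected == "excited"), 0.98)
})

test_that("peak metrics recover a triangular bump exactly", {
  # triangular bump rising to 12 Hz over a 4 Hz baseline: peak response 8 Hz,
  # FWHM = half the bump base width (geometry of the triangle)
  trials <- one_odor_trials(1)
  p <- build_psth(numeric(0), trials, 1)
  base_hz <- 4
  bump <- rep(0, 60)
  centers <- p$edges[-61] + 0.05
  ramp <- which(centers > 0 & centers < 2)
  half_base <- 1 # bump spans 0..2 s, apex at 1 s
  bump[ramp] <- 8 * (1 - abs(centers[ramp] - 1) / half_base)
  p$mean_rate_hz <- base_hz + bump
  p$counts <- matrix(p$mean_rate_hz * 0.1, nrow = 1, byrow = TRUE)
  pm <- peak_metrics(p, "excited")
  expect_equal(pm$peak_hz, 8 * (1 - abs(0.95 - 1)), tolerance = 1e-9)
  expect_equal(pm$width_s, 1, tolerance = 0.11) # FWHM on the binned curve
  # flat PSTH: zero peak, undefined width
  p$mean_rate_hz <- rep(4, 60)
  pm0 <- peak_metrics(p, "excited")
  expect_equal(pm0$peak_hz, 0)
  expect_true(is.na(pm0$width_s))
})

test_that("session summary arithmetic and degenerate cases", {
  pairs <- data.frame(unit = rep(1:3, each = 5),
                      odor = rep(1:5, 3),
                      label = c(rep("excited", 5), rep("inhibited", 5),
                                rep("none", 5)),
                      peak_z = 0, peak_hz = 0, width_s = 0,
                      baseline_hz = rep(c(2, 4, 6), each = 5))
  s <- summarize_session(pairs)
  expect_equal(s$n_excited, 5)
  expect_equal(s$n_inhibited, 5)
  expect_equal(s$ei_ratio, 1)
  expect_equal(s$fraction_responsive, 2 / 3)
  expect_equal(unname(s$broadness), c(5, 5, 0))
  expect_equal(s$mean_baseline_hz_all, 4)
  expect_equal(s$mean_baseline_hz_excited, 2)
  pairs$label <- "none"
  s0 <- summarize_session(pairs)
  expect_equal(s0$fraction_responsive, 0)
  expect_true(is.na(s0$ei_ratio))
  # 10 excited / 5 inhibited -> E/I 2.0
  pairs2 <- data.frame(unit = 1, odor = 1:15,
                       label = rep(c("excited", "inhibited"), c(10, 5)),
                       peak_z = 0, peak_hz = 0, width_s = 0, baseline_hz = 1)
  expect_equal(summarize_session(pairs2)$ei_ratio, 2)
})

test_that("E/I estimates tighten as the number of units grows", {
  # consistency of the detected-ratio estimator: spread of repeated session
  # estimates shrinks with unit count
  set.seed(7)
  spread <- vapply(c(40, 360), function(n) {
    cfg <- session_config(n_units = n, p_excited = 0.3, p_inhibited = 0.15,
                          balanced_labels = TRUE)
    reps <- vapply(1:4, function(i) {
      estimate_session_ei(cfg, qc = FALSE)$ei_ratio
    }, numeric(1))
    sd(log(reps))
  }, numeric(1))
  expect_lt(spread[2], spread[1])
})
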