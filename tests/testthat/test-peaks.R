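test_that("Gaussian smoothing is normalized, phase-preserving and bounded", {
  const <- ts_recording(rep(3.7, 200), "locomotion", 5)
  expect_equal(smooth_gaussian(const, 60)$values, rep(3.7, 200))
  # unit impulse spreads into a bump conserving total mass
  imp <- ts_recording(c(rep(0, 100), 1, rep(0, 100)), "locomotion", 5)
  sm <- smooth_gaussian(imp, 30)
  expect_equal(sum(sm$values), 1, tolerance = 1e-10)
  expect_equal(which.max(sm$values), 101)
  # 24-h sinusoid: same phase, amplitude attenuated by exp(-w^2 s^2 / 2)
  rec <- make_sine_rec(period_hr = 24, days = 4)
  sm2 <- smooth_gaussian(rec, 60)
  w <- 2 * pi / (24 * 60)
  att <- exp(-w^2 * 60^2 / 2)
  inner <- 200:900  # away from the padded edges
  fit <- stats::lm(sm2$values[inner] - 2 ~ 0 + I(rec$values[inner] - 2))
  expect_equal(unname(coef(fit)), att, tolerance = 1e-3)
  expect_error(smooth_gaussian(ts_recording(1:10, "rer", 5), 60),
               "wider than")
})

test_that("minima detection finds troughs and thins flat ties", {
  cfg <- peak_config()
  increasing <- ts_recording(seq(0, 10, length.out = 500), "locomotion", 5)
  expect_equal(detect_minima(increasing, cfg), 0)
  # 24-h sinusoid over 5 days, 12-h window: 5 troughs ~ 24 h apart
  rec <- make_sine_rec(period_hr = 24, days = 5, phase_hr = -6)  # trough ZT 12
  m <- detect_minima(smooth_gaussian(rec, 30), cfg)
  expect_equal(length(m), 5)
  expect_equal(diff(m), rep(24 * 60, 4), tolerance = 10)
  # constant series: one minimum per non-overlapping window
  flat <- ts_recording(rep(1, 24 * 12 * 3), "locomotion", 5)  # 3 days
  mf <- detect_minima(flat, cfg)
  expect_equal(diff(mf), rep(12 * 60, length(mf) - 1))
})

test_that("peaks are the per-window argmax and respect 12-h separation", {
  cfg <- peak_config()
  rec <- make_sine_rec(period_hr = 24, days = 5)
  sm <- smooth_gaussian(rec, 30)
  minima <- detect_minima(sm, cfg)
  pk <- detect_peaks(sm, minima, cfg)
  expect_equal(nrow(pk), 5)
  expect_true(all(diff(pk$time_min) >= 12 * 60))
  expect_equal(diff(pk$time_min), rep(24 * 60, 4), tolerance = 10)
  # two candidates 6 h apart: the taller survives the greedy discard
  v <- rep(0, 24 * 12)
  v[60] <- 10; v[60 + 72] <- 8   # bumps 6 h apart, amplitudes 10 and 8
  toy <- ts_recording(v, "locomotion", 5)
  mins <- c(0, 55 * 5, (60 + 36) * 5, 287 * 5)  # minima bracketing each bump
  pk2 <- detect_peaks(toy, mins, cfg)
  expect_equal(nrow(pk2), 1)
  expect_equal(pk2$value, 10)
  expect_warning(detect_peaks(toy, c(100), cfg), "fewer than 2 minima")
})

test_that("onsets take the last sample strictly below the beta percentile", {
  cfg <- peak_config(beta_percentile = 50)
  # square wave between two peaks: flat 0 then flat 100
  v <- c(50, rep(0, 50), rep(100, 50), 80, rep(0, 20), 60)
  rec <- ts_recording(v, "locomotion", 5)
  peaks <- data.frame(time_min = c(0, 102 * 5), value = c(50, 80))
  ps <- detect_onsets(rec, peaks, cfg)
  expect_true(is.na(ps$onset_time_min[1]))  # first peak closes no window
  # percentile of the window's values is 50; last strictly-below sample is
  # the final 0 before the rise (index 51, time 50*5)
  expect_equal(ps$onset_time_min[2], 50 * 5)
  expect_lt(ps$onset_time_min[2], ps$peak_time_min[2])
  # constant window: nothing strictly below any percentile -> missing
  flat <- ts_recording(rep(5, 100), "locomotion", 5)
  ps2 <- detect_onsets(flat, data.frame(time_min = c(0, 400),
                                        value = c(5, 5)), cfg)
  expect_true(is.na(ps2$onset_time_min[2]))
  # high beta on a strictly increasing window: penultimate sample
  inc <- ts_recording(0:99, "locomotion", 5)
  cfg99 <- peak_config(beta_percentile = 99.9)
  ps3 <- detect_onsets(inc, data.frame(time_min = c(0, 99 * 5),
                                       value = c(0, 99)), cfg99)
  expect_equal(ps3$onset_time_min[2], 97 * 5)
})

test_that("peak times shift with offsets and ignore positive rescaling", {
  rec <- make_sine_rec(period_hr = 24, days = 6)
  base <- detect_daily_peaks(rec)
  shifted <- rec; shifted$values <- rec$values + 100
  scaled <- rec; scaled$values <- rec$values * 7.5
  expect_equal(detect_daily_peaks(shifted)$peak_time_min,
               base$peak_time_min)
  expect_equal(detect_daily_peaks(scaled)$peak_time_min,
               base$peak_time_min)
})

test_that("noiseless periodic signals yield inter-peak intervals of tau", {
  for (tau in c(20, 24, 28)) {
    rec <- make_sine_rec(period_hr = tau, days = 7)
    ps <- detect_daily_peaks(rec)
    gaps <- diff(ps$peak_time_min)
    expect_true(all(abs(gaps - tau * 60) <= 5),
                label = sprintf("tau = %g h", tau))
    expect_true(all(gaps >= 12 * 60))
    # onsets precede their peaks within each window
    ok <- !is.na(ps$onset_time_min)
    expect_true(all(ps$onset_time_min[ok] < ps$peak_time_min[ok]))
  }
})

test_that("control-parameter fitting selects a one-peak-per-day config", {
  recs <- lapply(cohort_channel(small_control_cohort(seed = 5), "locomotion"),
                 identity)
  fit <- fit_control_parameters(recs, sigma_grid = c(30, 60),
                                window_grid = c(8, 12),
                                beta_grid = c(20))
  expect_false(fit$low_confidence)
  # overdispersed counts jitter the daily argmax across the activity
  # plateau, so not every interval lands within the +/- 1 h band
  expect_gt(fit$score, 0.5)
  ps <- detect_daily_peaks(recs[[1]], fit$config)
  expect_equal(nrow(ps), 14, tolerance = 1)  # ~ one peak per day
  # arrhythmic cohort: no parameters reach criterion, flagged
  set.seed(3)
  noise <- ts_recording(rpois(12 * 24 * 7, 5), "locomotion", 5)
  fit2 <- fit_control_parameters(list(noise), sigma_grid = 60,
                                 window_grid = 12, beta_grid = 20)
  expect_true(fit2$low_confidence)
  expect_error(fit_control_parameters(list()), "empty control cohort")
})
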