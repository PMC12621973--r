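test_that("cross-correlation peaks at lag 0 for identical series and at the
           constructed shift otherwise", {
  set.seed(5)
  v <- rnorm(200) + sin(2 * pi * (1:200) / 24)
  x <- ts_recording(v, "rer", 60)
  expect_equal(cross_correlate(x, x)$lag_at_max_hr, 0)
  expect_equal(cross_correlate(x, x)$max_corr, 1, tolerance = 1e-12)
  # y equals x shifted later by exactly 1 bin -> max at +1
  y <- ts_recording(c(NA, v[-200]), "energy_expenditure", 60)
  cc <- cross_correlate(x, y)
  expect_equal(cc$lag_at_max_hr, 1)
  expect_error(cross_correlate(x, ts_recording(rep(2, 200), "rer", 60)),
               "zero variance")
})

test_that("cross-correlation matches the classical sample CCF", {
  set.seed(8)
  v1 <- rnorm(150); v2 <- 0.6 * v1 + rnorm(150, 0, 0.5)
  x <- ts_recording(v1, "feeding", 60)
  y <- ts_recording(v2, "rer", 60)
  ours <- cross_correlate(x, y, max_lag_hr = 10)
  ref <- stats::ccf(v1, v2, lag.max = 10, plot = FALSE)
  # stats::ccf stores cor(x[t+k], y[t]); our +k pairs y[t] with x[t-k],
  # i.e. ref lag -k; ref divides by n where we divide by the pair count
  n <- 150
  for (k in -10:10) {
    ref_val <- ref$acf[ref$lag == -k] * n / (n - abs(k))
    expect_equal(ours$correlations[ours$lags_hr == k], ref_val,
                 tolerance = 1e-10)
  }
})

test_that("CCF symmetry: swapping the channels mirrors the lag axis", {
  set.seed(6)
  x <- ts_recording(rnorm(120), "feeding", 60)
  y <- ts_recording(rnorm(120), "rer", 60)
  fwd <- cross_correlate(x, y, max_lag_hr = 8)
  bwd <- cross_correlate(y, x, max_lag_hr = 8)
  expect_equal(fwd$correlations, rev(bwd$correlations), tolerance = 1e-12)
})

test_that("lag-0 correlation equals the Pearson coefficient", {
  set.seed(13)
  v1 <- rnorm(100); v2 <- v1 * 0.4 + rnorm(100)
  cc <- cross_correlate(ts_recording(v1, "feeding", 60),
                        ts_recording(v2, "rer", 60))
  pr <- pearson(v1, v2)
  expect_equal(cc$correlations[cc$lags_hr == 0], pr$r, tolerance = 1e-12)
})

test_that("maximum-correlation ties break toward small then positive lags", {
  mk <- function(lags, cors) {
    structure(list(lags_hr = lags, correlations = cors), class = "ccf_result")
  }
  expect_equal(max_correlation(mk(-1:1, c(0.1, 0.9, 0.4))),
               list(max_corr = 0.9, lag_at_max_hr = 0))
  expect_equal(max_correlation(mk(-2:2, c(0.8, 0, 0.1, 0, 0.8))),
               list(max_corr = 0.8, lag_at_max_hr = 2))
  expect_equal(max_correlation(mk(3, 0.5)),
               list(max_corr = 0.5, lag_at_max_hr = 3))
})

test_that("Pearson handles exact linear relations and rejects bad input", {
  expect_equal(pearson(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson(1:10, -(1:10))$r, -1)
  # worked 5-pair table against the closed-form formula
  x <- c(1, 2, 4, 5, 8); y <- c(2, 1, 5, 4, 9)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  pr <- pearson(x, y)
  expect_equal(pr$r, r_hand)
  expect_equal(pr$n, 5)
  expect_lt(pr$p_value, 0.05)
  expect_error(pearson(1:2, 2:3), "insufficient data")
  expect_error(pearson(rep(1, 5), 1:5), "constant input")
})

test_that("percent-change transform references the trailing window mean", {
  const <- ts_recording(rep(4, 121), "energy_expenditure", 60)
  expect_equal(percent_change_transform(const, window_hr = 120)$values,
               rep(0, 121))
  v <- c(rep(2, 120), 4)  # final-window mean includes the last value
  rec <- ts_recording(v, "energy_expenditure", 60)
  m <- mean(v[2:121])
  expect_equal(percent_change_transform(rec, 120)$values[121],
               100 * (4 - m) / m)
  # worked 3-point series with a 3-h window
  rec3 <- ts_recording(c(1, 2, 3), "feeding", 60)
  expect_equal(percent_change_transform(rec3, window_hr = 3)$values,
               100 * (c(1, 2, 3) - 2) / 2)
  expect_error(percent_change_transform(rec3, window_hr = 5), "shorter")
  zero <- ts_recording(rep(0, 10), "feeding", 60)
  expect_error(percent_change_transform(zero, window_hr = 5), "zero")
})

test_that("generative coupling delays are recovered as modal CCF lags", {
  for (d in c(0, 1, 2)) {
    lags <- vapply(1:3, function(s) {
      coh <- simulate_cohort(simulation_preset(
        "control", seed = 200 + 10 * d + s, n_animals = 7, days = 14,
        coupling_delay_hr = d))
      vapply(coh$animals, function(ch) {
        cross_correlate(ch$feeding, ch$rer)$lag_at_max_hr
      }, numeric(1))
    }, numeric(7))
    modal <- as.numeric(names(which.max(table(lags))))
    expect_equal(modal, d, label = sprintf("delay %d h", d))
  }
})

test_that("weaker generative coupling lowers the mean maximum correlation", {
  mean_max <- vapply(c(0.03, 0.15), function(gain) {
    coh <- simulate_cohort(simulation_preset("control", seed = 77,
                                             n_animals = 5, days = 14,
                                             coupling_gain = gain))
    mean(vapply(coh$animals, function(ch) {
      cross_correlate(ch$feeding, ch$rer)$max_corr
    }, numeric(1)))
  }, numeric(1))
  expect_lt(mean_max[1], mean_max[2])
})
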