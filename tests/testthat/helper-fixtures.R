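# Shared fixtures: all synthetic, built in code at test time.

# Sinusoidal recording: period_hr cycle, sampled every interval_min, for
# days days; amplitude 1 around offset.
make_sine_rec <- function(period_hr = 24, days = 5, interval_min = 5,
                          channel = "locomotion", offset = 2, amp = 1,
                          phase_hr = 0) {
  n <- round(days * 24 * 60 / interval_min)
  t_hr <- (seq_len(n) - 1) * interval_min / 60
  v <- offset + amp * sin(2 * pi * (t_hr - phase_hr) / period_hr)
  ts_recording(v, channel, interval_min)
}

small_control_cohort <- function(seed = 1, n_animals = 3, days = 14) {
  simulate_cohort(simulation_preset("control", seed = seed,
                                    n_animals = n_animals, days = days))
}

# Independent brute-force chi-square periodogram for one candidate period
# (in bins), written as plain loops so it shares nothing with the
# implementation under test.
brute_force_qp <- function(x, p_bins) {
  k <- length(x) %/% p_bins
  xs <- x[1:(k * p_bins)]
  col_means <- numeric(p_bins)
  for (h in 1:p_bins) {
    acc <- 0
    for (cyc in 0:(k - 1)) acc <- acc + xs[cyc * p_bins + h]
    col_means[h] <- acc / k
  }
  m <- mean(xs)
  num <- 0
  for (h in 1:p_bins) num <- num + (col_means[h] - m)^2
  den <- 0
  for (i in seq_along(xs)) den <- den + (xs[i] - m)^2
  k * length(xs) * num / den
}
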