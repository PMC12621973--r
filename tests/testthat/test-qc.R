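test_that("quartiles follow the linear-interpolation convention", {
  expect_equal(quartiles(c(1, 1, 1, 1)), list(q1 = 1, q3 = 1, iqr = 0))
  expect_equal(quartiles(5), list(q1 = 5, q3 = 5, iqr = 0))
  # hand computation, type-7: h = (n-1)p + 1 on sorted values
  q <- quartiles(1:8)
  expect_equal(q$q1, 2.75)
  expect_equal(q$q3, 6.25)
  expect_equal(q$iqr, 3.5)
  expect_error(quartiles(numeric()), "insufficient data")
})

test_that("hoarding replacement swaps fence-exceeders for the group median", {
  # constant group: fence collapses onto the constant, nothing exceeds it
  r <- replace_hoarding_outliers(rep(1, 5))
  expect_equal(r$values, rep(1, 5))
  expect_equal(r$report$n_replaced, 0L)
  # [1,1,1,1,10]: Q3 = 1, IQR = 0 (type 7), fence = 1, median = 1
  r2 <- replace_hoarding_outliers(c(1, 1, 1, 1, 10))
  expect_equal(r2$values, rep(1, 5))
  expect_equal(r2$report$n_replaced, 1L)
  expect_equal(length(r2$values), 5L)  # count of observations unchanged
  # threshold is Q3 + 2.5*IQR exactly: a value at the fence is retained
  v <- c(1, 2, 3, 4, 100)
  q <- quartiles(v)
  at_fence <- q$q3 + 2.5 * q$iqr
  r3 <- replace_hoarding_outliers(c(1, 2, 3, 4, at_fence))
  expect_equal(r3$report$n_replaced, 0L)
  # grouping is respected: the spike is only an outlier within its group
  vals <- c(1, 1, 1, 1, 10, 10, 10, 10, 10, 1)
  grp <- rep(c("a", "b"), each = 5)
  r4 <- replace_hoarding_outliers(vals, grp)
  expect_equal(r4$values[5], 1)    # 10 in group of 1s -> replaced
  expect_equal(r4$values[10], 1)   # 1 in group of 10s is *low*, untouched
  expect_equal(r4$report$n_replaced, 1L)
  # all replaced values equal their group median exactly
  expect_true(all(r4$values[r4$replaced] == 1))
})

test_that("RER physiologic bounds are strict at 0.7 and 1.2", {
  r <- filter_rer(c(0.69, 0.70, 1.20, 1.21, 0.9, NA))
  expect_equal(r$values, c(0.70, 1.20, 0.9))
  expect_equal(r$report$n_excluded, 2L)
  expect_equal(r$keep, c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE))
})

test_that("Tukey fences exclude strictly outside Q1-1.5IQR / Q3+1.5IQR", {
  r <- tukey_fence_exclude(rep(3, 6))
  expect_equal(r$report$n_excluded, 0L)
  # [10,11,12,13,100]: Q1 = 11, Q3 = 13, IQR = 2, fences [8, 16]
  r2 <- tukey_fence_exclude(c(10, 11, 12, 13, 100))
  expect_equal(r2$values, c(10, 11, 12, 13))
  expect_equal(r2$report$n_excluded, 1L)
  # a value exactly on the fence survives (strict inequality)
  r3 <- tukey_fence_exclude(c(10, 11, 12, 13, 16))
  expect_equal(r3$report$n_excluded, 0L)
})

test_that("fence rules are idempotent with fences frozen from one pass", {
  set.seed(7)
  vals <- c(rnorm(40, 10), 25, 30)
  grp <- rep(c("x", "y"), 21)
  h1 <- replace_hoarding_outliers(vals, grp)
  h2 <- replace_hoarding_outliers(h1$values, grp)
  # replaced values sit at the group median, inside the original fences:
  # a second pass with the same fences finds nothing new
  expect_equal(h2$values, h1$values)
  t1 <- tukey_fence_exclude(vals, grp)
  keep_grp <- grp[t1$keep]
  # re-applying with the *first-pass* fences changes nothing
  for (g in unique(keep_grp)) {
    q <- quartiles(vals[grp == g])
    v_kept <- t1$values[keep_grp == g]
    expect_true(all(v_kept >= q$q1 - 1.5 * q$iqr &
                      v_kept <= q$q3 + 1.5 * q$iqr))
  }
})

test_that("duplicate wells reconcile on percent CV of the pair", {
  expect_equal(reconcile_duplicates(5, 5, group_mean = 99)$value, 5)
  # (10, 20): sd = 7.071, mean = 15, CV = 47.1% > 10 -> keep the closer
  r <- reconcile_duplicates(10, 20, group_mean = 11)
  expect_equal(r$value, 10)
  expect_equal(r$dropped_replicate, 2L)
  expect_gt(r$cv_percent, 10)
  # just under the threshold: pair mean
  a <- 100; b <- 100 * (1 + 2 * 0.0999 / (2 - 0.0999))  # CV ~ 9.99%
  r2 <- reconcile_duplicates(a, b, group_mean = 0)
  expect_lt(r2$cv_percent, 10)
  expect_equal(r2$value, mean(c(a, b)))
  # zero pair mean: CV undefined, flagged, mean returned
  r3 <- reconcile_duplicates(-1, 1, group_mean = 0)
  expect_equal(r3$flag, "cv_undefined")
  expect_equal(r3$value, 0)
})

test_that("replacement fraction rises with the injected hoarding rate", {
  # low-rate regime: once spikes contaminate a sizable share of a group,
  # they inflate the group's own fences and replacement saturates
  rates <- c(0.1, 0.2, 0.4)
  frac <- vapply(rates, function(rate) {
    reps <- vapply(1:6, function(s) {
      cfg <- simulation_preset("control", seed = s, n_animals = 1, days = 14)
      feeding <- simulate_animal(cfg, animal_seed(s, 1))$feeding
      spiked <- inject_hoarding(feeding, rate, magnitude_g = 1.5,
                                seed = s + 100)
      daily <- rebin(spiked, 12 * 60)  # half-day bins = light/dark phases
      phase <- rep_len(c("light", "dark"), length(daily$values))
      replace_hoarding_outliers(daily$values,
                                phase)$report$fraction_affected
    }, numeric(1))
    mean(reps)
  }, numeric(1))
  expect_true(all(diff(frac) > 0))
})
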