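# Daily behavioral peak / onset detection.
#
# Pipeline: 5-min binning -> Gaussian-kernel smoothing -> activity minima
# (lowest point within a sliding window) -> peaks as the argmax between
# consecutive minima, with peaks closer than 12 h discarded -> onset as the
# last sample below the beta-th percentile of the window between two peaks.

#' Peak-detection configuration
#'
#' The separation rule (12 h) and the working bin width (5 min) are fixed
#' properties of the method; the smoothing width, minima window and onset
#' percentile are tunable and can be fit on control animals with
#' [fit_control_parameters()] then frozen for all conditions.
#'
#' @param bin_min Working bin width in minutes (default 5).
#' @param kernel_sigma_min Gaussian smoothing SD in minutes (default 60).
#' @param minima_window_hr Width in hours of the centered sliding window used
#'   to declare activity minima (default 12).
#' @param min_peak_separation_hr Minimum real-hour spacing between surviving
#'   peaks (default 12).
#' @param beta_percentile Percentile (0-100) defining onsets (default 20).
#' @param quantile_type Percentile convention, as in [stats::quantile()];
#'   kept identical to the QC fence convention.
#' @return An object of class `peak_config`.
#' @export
peak_config <- function(bin_min = 5, kernel_sigma_min = 60,
                        minima_window_hr = 12, min_peak_separation_hr = 12,
                        beta_percentile = 20, quantile_type = 7) {
  stopifnot(bin_min > 0, kernel_sigma_min > 0, minima_window_hr > 0,
            min_peak_separation_hr > 0,
            beta_percentile > 0, beta_percentile < 100)
  structure(
    list(bin_min = bin_min, kernel_sigma_min = kernel_sigma_min,
         minima_window_hr = minima_window_hr,
         min_peak_separation_hr = min_peak_separation_hr,
         beta_percentile = beta_percentile, quantile_type = quantile_type),
    class = "peak_config"
  )
}

#' Gaussian smoothing of a recording
#'
#' Discrete convolution with a normalized Gaussian kernel (weights sum to 1,
#' truncated at 4 SD). A constant signal passes through unchanged and a unit
#' impulse spreads into a bump whose values still sum to 1. Edges use
#' reflection padding so the boundary does not manufacture artificial
#' troughs for the minima stage.
#'
#' @param rec A [ts_recording()], already at the working bin width.
#' @param sigma_min Kernel SD in real minutes.
#' @return A smoothed `tsrec` of the same length.
#' @export
smooth_gaussian <- function(rec, sigma_min) {
  stopifnot(inherits(rec, "tsrec"), sigma_min > 0)
  v <- rec$values
  n <- length(v)
  sigma_bins <- sigma_min / rec$interval_min
  half <- max(1L, ceiling(4 * sigma_bins))
  if (2L * half + 1L > n) {
    stop("smoothing kernel wider than the recording", call. = FALSE)
  }
  kern <- stats::dnorm(seq(-half, half), sd = sigma_bins)
  kern <- kern / sum(kern)
  padded <- c(rev(v[seq_len(half) + 1L]), v, rev(v[n - seq_len(half)]))
  sm <- stats::filter(padded, kern, method = "convolution", sides = 2)
  out <- rec
  out$values <- as.numeric(sm[(half + 1L):(half + n)])
  out
}

rolling_window_min_mask <- function(v, half) {
  n <- length(v)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    v[i] <= min(v[lo:hi])
  }, logical(1))
}

#' Detect activity minima
#'
#' A sample is a candidate minimum when it attains the lowest smoothed value
#' within the centered window of `minima_window_hr` around it. Ties (runs of
#' equal window-minimal values, e.g. a constant stretch) are thinned to the
#' earliest candidate per window span, so a flat series yields one minimum
#' per non-overlapping window rather than every sample.
#'
#' @param smoothed A smoothed `tsrec`.
#' @param config A [peak_config()].
#' @return Numeric vector of minima times (real minutes).
#' @export
detect_minima <- function(smoothed, config = peak_config()) {
  stopifnot(inherits(smoothed, "tsrec"))
  v <- smoothed$values
  window_min <- config$minima_window_hr * 60
  half <- max(1L, floor(window_min / smoothed$interval_min / 2))
  cand <- which(rolling_window_min_mask(v, half))
  if (length(cand) == 0L) return(numeric())
  times <- rec_times(smoothed)[cand]
  kept <- times[1]
  for (t in times[-1]) {
    if (t - kept[length(kept)] >= window_min) kept <- c(kept, t)
  }
  kept
}

#' Detect daily peaks between activity minima
#'
#' One candidate peak per inter-minima interval: the (earliest) argmax of
#' the smoothed signal between two consecutive minima. Candidates closer
#' than `min_peak_separation_hr` are then discarded greedily by descending
#' amplitude: the tallest survives, conflicting neighbors drop, repeat.
#'
#' @param smoothed A smoothed `tsrec`.
#' @param minima Times from [detect_minima()].
#' @param config A [peak_config()].
#' @return Data frame with `time_min` and `value`, ordered by time; empty
#'   (with a warning) when fewer than 2 minima exist.
#' @export
detect_peaks <- function(smoothed, minima, config = peak_config()) {
  stopifnot(inherits(smoothed, "tsrec"))
  empty <- data.frame(time_min = numeric(), value = numeric())
  if (length(minima) < 2L) {
    warning("fewer than 2 minima: no peaks detected")
    return(empty)
  }
  v <- smoothed$values
  t <- rec_times(smoothed)
  cand_t <- numeric(); cand_v <- numeric()
  for (j in seq_len(length(minima) - 1L)) {
    idx <- which(t >= minima[j] & t <= minima[j + 1L])
    if (length(idx) == 0L) next
    best <- idx[which.max(v[idx])]  # which.max takes the earliest tie
    cand_t <- c(cand_t, t[best]); cand_v <- c(cand_v, v[best])
  }
  dup <- duplicated(cand_t)
  cand_t <- cand_t[!dup]; cand_v <- cand_v[!dup]
  sep_min <- config$min_peak_separation_hr * 60
  ord <- order(-cand_v, cand_t)
  keep_t <- numeric(); keep_v <- numeric()
  for (i in ord) {
    if (all(abs(cand_t[i] - keep_t) >= sep_min)) {
      keep_t <- c(keep_t, cand_t[i]); keep_v <- c(keep_v, cand_v[i])
    }
  }
  o <- order(keep_t)
  data.frame(time_min = keep_t[o], value = keep_v[o])
}

#' Detect behavioral onsets between peaks
#'
#' For each window strictly between two consecutive peaks, the onset is the
#' time of the last sample strictly below the `beta_percentile`-th
#' percentile of the window's values; it is assigned to the peak that closes
#' the window (the first peak therefore has no onset). A window with no
#' sample below its percentile (e.g. a constant window) yields a missing,
#' flagged onset.
#'
#' @param smoothed A smoothed `tsrec`.
#' @param peaks Data frame from [detect_peaks()].
#' @param config A [peak_config()].
#' @return A `peak_set`: data frame with `peak_time_min`, `peak_value`,
#'   `onset_time_min` (NA when undefined).
#' @export
detect_onsets <- function(smoothed, peaks, config = peak_config()) {
  stopifnot(inherits(smoothed, "tsrec"))
  onset <- rep(NA_real_, nrow(peaks))
  if (nrow(peaks) >= 2L) {
    v <- smoothed$values
    t <- rec_times(smoothed)
    for (j in 2:nrow(peaks)) {
      idx <- which(t > peaks$time_min[j - 1L] & t < peaks$time_min[j])
      if (length(idx) == 0L) next
      thr <- stats::quantile(v[idx], probs = config$beta_percentile / 100,
                             type = config$quantile_type, names = FALSE)
      below <- idx[v[idx] < thr]
      if (length(below) > 0L) onset[j] <- t[max(below)]
    }
  }
  out <- data.frame(peak_time_min = peaks$time_min,
                    peak_value = peaks$value,
                    onset_time_min = onset)
  class(out) <- c("peak_set", class(out))
  out
}

#' Full daily peak/onset detection for one recording
#'
#' Rebins to the working bin width, smooths, finds minima, peaks and onsets.
#' When a schedule is supplied, peak times are also expressed in zeitgeber
#' time (`peak_zt`), the coordinate in which 20-h and 24-h days are
#' comparable.
#'
#' @param rec A [ts_recording()] at any interval dividing `config$bin_min`.
#' @param config A [peak_config()].
#' @param schedule Optional [light_schedule()] for ZT annotation.
#' @return A `peak_set` data frame (see [detect_onsets()]), plus `peak_zt`
#'   when a schedule is given.
#' @export
detect_daily_peaks <- function(rec, config = peak_config(),
                               schedule = NULL) {
  working <- if (rec$interval_min == config$bin_min) rec else
    rebin(rec, config$bin_min)
  sm <- smooth_gaussian(working, config$kernel_sigma_min)
  minima <- detect_minima(sm, config)
  pk <- detect_peaks(sm, minima, config)
  ps <- detect_onsets(sm, pk, config)
  if (!is.null(schedule) && nrow(ps) > 0) {
    ps$peak_zt <- real_to_zt(ps$peak_time_min, schedule)
  } else if (!is.null(schedule)) {
    ps$peak_zt <- numeric()
  }
  ps
}

#' Fit peak-detection parameters on control animals
#'
#' Grid search over smoothing SD, minima window and onset percentile. Each
#' configuration is scored by the mean, over control animals, of the
#' fraction of detected inter-peak intervals falling within +/- 1 h of 24 h;
#' the best configuration is returned frozen, to be applied identically to
#' all conditions. When no configuration reaches a score of 0.5 the fit is
#' flagged low-confidence (e.g. an arrhythmic cohort).
#'
#' @param control_recs List of control-condition [ts_recording()] objects.
#' @param sigma_grid,window_grid,beta_grid Candidate values for
#'   `kernel_sigma_min`, `minima_window_hr`, `beta_percentile`.
#' @param target_hr,tol_hr Interval criterion (defaults 24 +/- 1 h).
#' @return List with `config` (a [peak_config()]), `score` in [0, 1] and
#'   `low_confidence` flag.
#' @export
fit_control_parameters <- function(control_recs,
                                   sigma_grid = c(30, 60, 90),
                                   window_grid = c(8, 12, 16),
                                   beta_grid = c(10, 20, 30),
                                   target_hr = 24, tol_hr = 1) {
  if (length(control_recs) == 0L) {
    stop("empty control cohort", call. = FALSE)
  }
  best <- NULL; best_score <- -Inf
  for (sg in sigma_grid) for (wg in window_grid) for (bg in beta_grid) {
    cfg <- peak_config(kernel_sigma_min = sg, minima_window_hr = wg,
                       beta_percentile = bg)
    scores <- vapply(control_recs, function(rec) {
      ps <- suppressWarnings(detect_daily_peaks(rec, cfg))
      if (nrow(ps) < 2L) return(0)
      gaps <- diff(ps$peak_time_min) / 60
      mean(abs(gaps - target_hr) <= tol_hr)
    }, numeric(1))
    sc <- mean(scores)
    if (sc > best_score) { best_score <- sc; best <- cfg }
  }
  list(config = best, score = best_score,
       low_confidence = best_score < 0.5)
}
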