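# Coupling between physiological channels: lagged cross-correlation,
# Pearson correlation, and the percent-change display transform.
#
# Feeding drives RER with a metabolic delay of about an hour (substrate
# availability shifts VCO2/VO2 only after absorption), while locomotion
# drives energy expenditure essentially instantaneously; the lag of maximum
# cross-correlation between hourly-binned channels quantifies both.

#' Lagged cross-correlation between two channels
#'
#' Both recordings are rebinned to `bin_min` (default 1 h) on their common
#' grid. At lag `k`, the response `y(t)` is paired with the predictor
#' `x(t - k)`: a positive lag `k` means a change in `x` precedes the change
#' in `y` by `k` hours. Series are centered by their full-series means and
#' normalized by full-series (population) standard deviations — the
#' classical sample cross-correlation, not per-lag renormalization — and
#' pairs with a missing member are dropped (complete-case per lag).
#'
#' @param x_rec Predictor [ts_recording()] (e.g. feeding, locomotion).
#' @param y_rec Response [ts_recording()] (e.g. RER, energy expenditure).
#' @param max_lag_hr Maximum lag magnitude in hours (default 12).
#' @param bin_min Working bin width in minutes (default 60).
#' @return An object of class `ccf_result`: `lags_hr`, `correlations`,
#'   `max_corr`, `lag_at_max_hr`.
#' @export
cross_correlate <- function(x_rec, y_rec, max_lag_hr = 12, bin_min = 60) {
  stopifnot(inherits(x_rec, "tsrec"), inherits(y_rec, "tsrec"))
  x_rec <- if (x_rec$interval_min == bin_min) x_rec else rebin(x_rec, bin_min)
  y_rec <- if (y_rec$interval_min == bin_min) y_rec else rebin(y_rec, bin_min)
  if (!isTRUE(all.equal(x_rec$start_min, y_rec$start_min))) {
    stop("recordings must share a time grid (equal start times)",
         call. = FALSE)
  }
  n <- min(length(x_rec$values), length(y_rec$values))
  x <- x_rec$values[seq_len(n)]
  y <- y_rec$values[seq_len(n)]
  mx <- mean(x, na.rm = TRUE); my <- mean(y, na.rm = TRUE)
  sx <- sqrt(mean((x - mx)^2, na.rm = TRUE))
  sy <- sqrt(mean((y - my)^2, na.rm = TRUE))
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) {
    stop("undefined correlation: a series has zero variance", call. = FALSE)
  }
  lag_step <- bin_min / 60
  max_lag_bins <- floor(max_lag_hr / lag_step)
  lags_bins <- seq.int(-max_lag_bins, max_lag_bins)
  cc <- vapply(lags_bins, function(k) {
    # pair y[t] with x[t - k]
    t_idx <- seq_len(n)
    xs_idx <- t_idx - k
    ok <- xs_idx >= 1L & xs_idx <= n
    t_idx <- t_idx[ok]; xs_idx <- xs_idx[ok]
    xv <- x[xs_idx]; yv <- y[t_idx]
    valid <- is.finite(xv) & is.finite(yv)
    if (sum(valid) < 2L) return(NA_real_)
    mean((xv[valid] - mx) * (yv[valid] - my)) / (sx * sy)
  }, numeric(1))
  res <- structure(
    list(lags_hr = lags_bins * lag_step, correlations = cc,
         x_channel = x_rec$channel, y_channel = y_rec$channel,
         animal_id = x_rec$animal_id),
    class = "ccf_result"
  )
  mx_res <- max_correlation(res)
  res$max_corr <- mx_res$max_corr
  res$lag_at_max_hr <- mx_res$lag_at_max_hr
  res
}

#' @export
print.ccf_result <- function(x, ...) {
  cat(sprintf("<ccf_result> %s: %s -> %s, lags %g..%g h; max r = %.3f at %+g h\n",
              x$animal_id, x$x_channel, x$y_channel, min(x$lags_hr),
              max(x$lags_hr), x$max_corr, x$lag_at_max_hr))
  invisible(x)
}

#' Lag of maximum cross-correlation
#'
#' Global maximum over the lag grid; exact ties break toward the smallest
#' `|lag|`, then toward the positive lag.
#'
#' @param ccf A `ccf_result` from [cross_correlate()].
#' @return List with `max_corr` and `lag_at_max_hr`.
#' @export
max_correlation <- function(ccf) {
  cc <- ccf$correlations
  lags <- ccf$lags_hr
  ok <- is.finite(cc)
  if (!any(ok)) stop("no finite correlations", call. = FALSE)
  best <- max(cc[ok])
  at <- lags[ok][cc[ok] == best]
  at <- at[order(abs(at), -at)][1]
  list(max_corr = best, lag_at_max_hr = at)
}

#' Pearson correlation with two-sided p-value
#'
#' Standard Pearson `r` with the two-sided p-value from the t transform
#' (via [stats::cor.test()]); reported as an effect size alongside the
#' cross-correlation analyses.
#'
#' @param x,y Paired numeric vectors; incomplete pairs dropped; at least 3
#'   complete pairs required.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    stop("insufficient data: Pearson correlation needs >= 3 pairs",
         call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Percent change from the trailing window mean
#'
#' Display transform used to put channels with very different units on one
#' axis: `v -> 100 * (v - m) / m`, with `m` the channel mean over the final
#' `window_hr` of the experiment. Visualization aid only — cross-correlation
#' always runs on untransformed hourly bins.
#'
#' @param rec A [ts_recording()] covering at least `window_hr`.
#' @param window_hr Reference window in hours (default 120).
#' @param scale Optional display scale factor multiplying the result
#'   (default 1); a plotting convenience for dual-axis overlays, unused by
#'   any analysis path.
#' @return A transformed `tsrec` (unitless, percent).
#' @export
percent_change_transform <- function(rec, window_hr = 120, scale = 1) {
  stopifnot(inherits(rec, "tsrec"))
  n <- length(rec$values)
  span_hr <- n * rec$interval_min / 60
  if (span_hr < window_hr) {
    stop(sprintf("recording (%.1f h) shorter than the %g h reference window",
                 span_hr, window_hr), call. = FALSE)
  }
  n_win <- floor(window_hr * 60 / rec$interval_min)
  m <- mean(rec$values[(n - n_win + 1L):n], na.rm = TRUE)
  if (!is.finite(m) || m == 0) {
    stop("reference-window mean is zero or undefined", call. = FALSE)
  }
  out <- rec
  out$values <- scale * 100 * (rec$values - m) / m
  out
}
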