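# Circular statistics on daily peak phases: mean vector and Rayleigh test.

#' Map zeitgeber time onto the circle
#'
#' `angle = 2*pi*zt/24`. Because ZT already stretches any cycle onto 24
#' elastic hours, peaks from 20-h and 24-h days land on the same circle and
#' their clustering is directly comparable.
#'
#' @param zt ZT hours in `[0, 24)` (vectorized).
#' @return Angles in radians, `[0, 2*pi)`.
#' @export
zt_to_angle <- function(zt) {
  stopifnot(all(is.finite(zt)), all(zt >= 0 & zt < 24))
  2 * pi * zt / 24
}

#' Rayleigh test of circular uniformity
#'
#' The mean resultant vector of the unit vectors at each angle has length
#' `R` in `[0, 1]`; the Rayleigh statistic is `Z = n * R^2`. Identically
#' clustered angles give `R = 1`, `Z = n`; perfectly symmetric angles give
#' `Z = 0`. The p-value uses the standard series approximation
#' `p ~ exp(-Z) * [1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288n^2)]`,
#' clamped to `(0, 1]`.
#'
#' @param angles Angles in radians (any real; reduced mod `2*pi`). `NA`
#'   dropped; at least 2 finite angles required.
#' @param alpha Significance level for the `significant` flag (default
#'   0.05).
#' @return An object of class `rayleigh_result`: list with `n`,
#'   `mean_angle_rad` in `[0, 2*pi)`, `resultant_length_R`, `Z`, `p_value`,
#'   `significant`, `alpha`.
#' @export
rayleigh_test <- function(angles, alpha = 0.05) {
  angles <- angles[is.finite(angles)]
  n <- length(angles)
  if (n < 2L) {
    stop("insufficient data: Rayleigh test needs at least 2 angles",
         call. = FALSE)
  }
  c_bar <- mean(cos(angles))
  s_bar <- mean(sin(angles))
  R <- sqrt(c_bar^2 + s_bar^2)
  R <- min(R, 1)
  mu <- atan2(s_bar, c_bar) %% (2 * pi)
  Z <- n * R^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(
    list(n = n, mean_angle_rad = mu, resultant_length_R = R, Z = Z,
         p_value = p, significant = p < alpha, alpha = alpha),
    class = "rayleigh_result"
  )
}

#' @export
print.rayleigh_result <- function(x, ...) {
  cat(sprintf(
    "<rayleigh_result> n=%d R=%.3f Z=%.3f p=%.3g (%ssignificant at alpha=%g)\n",
    x$n, x$resultant_length_R, x$Z, x$p_value,
    if (x$significant) "" else "non-", x$alpha))
  invisible(x)
}

#' Rayleigh test on the detected daily peaks of one recording
#'
#' Convenience wrapper: converts peak times to ZT angles on the supplied
#' schedule and runs [rayleigh_test()].
#'
#' @param peak_set A `peak_set` from [detect_daily_peaks()].
#' @param schedule A [light_schedule()].
#' @param alpha Significance level.
#' @return A `rayleigh_result`.
#' @export
rayleigh_on_peaks <- function(peak_set, schedule, alpha = 0.05) {
  zt <- real_to_zt(peak_set$peak_time_min, schedule)
  rayleigh_test(zt_to_angle(zt), alpha = alpha)
}
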