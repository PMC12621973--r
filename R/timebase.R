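# Time base: light schedules, elastic zeitgeber time, recordings, rebinning.
#
# All absolute times are real minutes since recording start. Zeitgeber time
# (ZT) is a derived, elastic coordinate in which one full light/dark cycle --
# whatever its real duration -- spans 24 "ZT hours", with ZT 0 at lights-on.

CHANNELS <- c("locomotion", "feeding", "rer", "energy_expenditure")
EXTENSIVE_CHANNELS <- c("locomotion", "feeding")

#' Light schedule
#'
#' Describes the environmental light/dark cycle that defines zeitgeber time:
#' the real period of one full cycle, the light fraction, and the real time
#' (minutes since recording start) of a lights-on event.
#'
#' @param period_hours Real hours per full light+dark cycle (24 for a
#'   standard 12:12 day, 20 for a 10:10 T-cycle).
#' @param light_hours Real hours of light per cycle; must lie strictly
#'   between 0 and `period_hours`.
#' @param lights_on_anchor_min Real minutes since recording start at which a
#'   lights-on transition occurs. Defaults to 0 (recordings aligned to
#'   lights-on).
#' @return An object of class `light_schedule`.
#' @examples
#' light_schedule(24, 12)        # standard 12:12
#' light_schedule(20, 10)        # 20-h desynchronizing T-cycle
#' @export
light_schedule <- function(period_hours, light_hours = period_hours / 2,
                           lights_on_anchor_min = 0) {
  if (!is.numeric(period_hours) || length(period_hours) != 1L ||
      !is.finite(period_hours) || period_hours <= 0) {
    stop("invalid schedule: period_hours must be a single positive number",
         call. = FALSE)
  }
  if (!is.numeric(light_hours) || length(light_hours) != 1L ||
      !is.finite(light_hours) || light_hours <= 0 ||
      light_hours >= period_hours) {
    stop("invalid schedule: light_hours must lie in (0, period_hours)",
         call. = FALSE)
  }
  structure(
    list(period_hours = as.numeric(period_hours),
         light_hours = as.numeric(light_hours),
         lights_on_anchor_min = as.numeric(lights_on_anchor_min)),
    class = "light_schedule"
  )
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf("<light_schedule> %g h cycle (%g L : %g D), lights-on anchor %g min\n",
              x$period_hours, x$light_hours, x$period_hours - x$light_hours,
              x$lights_on_anchor_min))
  invisible(x)
}

#' Schedule presets
#'
#' `"LD12:12"` is the standard entraining 24-h day; `"LD10:10"` is the 20-h
#' T-cycle used to desynchronize the ~24-h endogenous clock from its
#' environment (environmental circadian desynchronization, ECD).
#'
#' @param name One of `"LD12:12"`, `"LD10:10"`.
#' @param lights_on_anchor_min Passed to [light_schedule()].
#' @return A `light_schedule`.
#' @export
schedule_preset <- function(name = c("LD12:12", "LD10:10"),
                            lights_on_anchor_min = 0) {
  name <- match.arg(name)
  switch(name,
         "LD12:12" = light_schedule(24, 12, lights_on_anchor_min),
         "LD10:10" = light_schedule(20, 10, lights_on_anchor_min))
}

#' Duration of one zeitgeber hour in real minutes
#'
#' One cycle spans 24 ZT hours regardless of its real length, so each ZT hour
#' lasts `period_hours * 60 / 24` real minutes: 60 min on a 24-h day, 50 min
#' on a 20-h day.
#'
#' @param schedule A [light_schedule()].
#' @return Real minutes per ZT hour.
#' @export
zt_hour_duration <- function(schedule) {
  stopifnot(inherits(schedule, "light_schedule"))
  schedule$period_hours * 60 / 24
}

#' Convert real time to zeitgeber time
#'
#' Maps minutes since recording start onto the elastic ZT circle:
#' `zt = 24 * frac((t - anchor) / period)`, in `[0, 24)`. ZT 0 is lights-on;
#' for half-light schedules lights-off falls at ZT 12.
#'
#' @param t_min Real minutes since recording start (vectorized).
#' @param schedule A [light_schedule()].
#' @return Numeric vector of ZT hours in `[0, 24)`.
#' @export
real_to_zt <- function(t_min, schedule) {
  stopifnot(inherits(schedule, "light_schedule"))
  period_min <- schedule$period_hours * 60
  frac <- ((t_min - schedule$lights_on_anchor_min) / period_min) %% 1
  zt <- 24 * frac
  # guard against 24 - eps rounding up to exactly 24
  zt[zt >= 24] <- 0
  zt
}

#' Convert zeitgeber time back to real time
#'
#' Returns the earliest real time at or after the lights-on anchor whose ZT
#' equals `zt`; the round trip `real_to_zt(zt_to_real(zt))` is the identity
#' on `[0, 24)`.
#'
#' @param zt ZT hours in `[0, 24)` (vectorized).
#' @param schedule A [light_schedule()].
#' @return Real minutes.
#' @export
zt_to_real <- function(zt, schedule) {
  stopifnot(inherits(schedule, "light_schedule"))
  stopifnot(all(zt >= 0 & zt < 24))
  schedule$lights_on_anchor_min + zt / 24 * schedule$period_hours * 60
}

#' Light/dark phase of a zeitgeber time
#'
#' For half-light schedules the light phase occupies ZT `[0, 12)` and the
#' dark phase ZT `[12, 24)`; in general the boundary sits at
#' `24 * light_hours / period_hours`.
#'
#' @param zt ZT hours in `[0, 24)` (vectorized).
#' @param schedule Optional [light_schedule()]; defaults to a half-light
#'   cycle (boundary at ZT 12).
#' @return Character vector, `"light"` or `"dark"`.
#' @export
phase_label <- function(zt, schedule = NULL) {
  stopifnot(all(is.finite(zt)), all(zt >= 0 & zt < 24))
  boundary <- if (is.null(schedule)) 12 else
    24 * schedule$light_hours / schedule$period_hours
  ifelse(zt < boundary, "light", "dark")
}

#' Single-channel recording
#'
#' One animal x one channel of uniformly sampled values. Values may contain
#' `NA` (missing samples). Sample i covers the real-time bin
#' `[start_min + (i-1)*interval, start_min + i*interval)`.
#'
#' @param values Numeric vector (missing allowed).
#' @param channel One of `"locomotion"` (beam-break counts/bin), `"feeding"`
#'   (g/bin), `"rer"` (VCO2/VO2, unitless), `"energy_expenditure"` (kcal/hr).
#' @param interval_min Sampling interval, real minutes (> 0).
#' @param start_min Real minutes of the first bin start (default 0).
#' @param animal_id,genotype,condition Metadata labels; `condition` is
#'   conventionally `"Control"` or `"ECD"`.
#' @return An object of class `tsrec`.
#' @export
ts_recording <- function(values, channel, interval_min,
                         start_min = 0, animal_id = "animal1",
                         genotype = "WT", condition = "Control") {
  channel <- match.arg(channel, CHANNELS)
  if (!is.numeric(interval_min) || length(interval_min) != 1L ||
      !is.finite(interval_min) || interval_min <= 0) {
    stop("interval_min must be a single positive number", call. = FALSE)
  }
  structure(
    list(animal_id = as.character(animal_id),
         genotype = as.character(genotype),
         condition = as.character(condition),
         channel = channel,
         start_min = as.numeric(start_min),
         interval_min = as.numeric(interval_min),
         values = as.numeric(values)),
    class = "tsrec"
  )
}

#' @export
print.tsrec <- function(x, ...) {
  cat(sprintf("<tsrec> %s / %s (%s, %s): %d samples @ %g min, start %g min\n",
              x$animal_id, x$channel, x$genotype, x$condition,
              length(x$values), x$interval_min, x$start_min))
  invisible(x)
}

#' @export
length.tsrec <- function(x) length(x$values)

#' Bin-start times of a recording, in real minutes
#' @param rec A [ts_recording()].
#' @return Numeric vector, one time per sample.
#' @export
rec_times <- function(rec) {
  stopifnot(inherits(rec, "tsrec"))
  rec$start_min + (seq_along(rec$values) - 1L) * rec$interval_min
}

is_extensive <- function(channel) channel %in% EXTENSIVE_CHANNELS

#' Rebin a recording to a coarser sampling interval
#'
#' Extensive channels (locomotion counts, feeding grams) are summed within
#' each new bin; intensive channels (RER, energy expenditure) are averaged.
#' Missing samples are skipped inside a bin; a bin with only missing samples
#' stays missing. Trailing samples that do not fill a complete new bin are
#' dropped, so extensive totals are conserved up to that truncated tail.
#'
#' @param rec A [ts_recording()].
#' @param new_interval_min Target interval; must be an integer multiple of
#'   the source interval.
#' @return A rebinned `tsrec`.
#' @export
rebin <- function(rec, new_interval_min) {
  stopifnot(inherits(rec, "tsrec"))
  ratio <- new_interval_min / rec$interval_min
  if (!isTRUE(all.equal(ratio, round(ratio))) || ratio < 1) {
    stop(sprintf(
      "rebin error: %g min is not an integer multiple of the source %g min",
      new_interval_min, rec$interval_min), call. = FALSE)
  }
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(rec)
  n_out <- length(rec$values) %/% ratio
  if (n_out == 0L) {
    stop("rebin error: recording shorter than one new bin", call. = FALSE)
  }
  kept <- rec$values[seq_len(n_out * ratio)]
  grp <- rep(seq_len(n_out), each = ratio)
  agg <- if (is_extensive(rec$channel)) {
    tapply(kept, grp, function(v) if (all(is.na(v))) NA_real_ else
      sum(v, na.rm = TRUE))
  } else {
    tapply(kept, grp, function(v) if (all(is.na(v))) NA_real_ else
      mean(v, na.rm = TRUE))
  }
  out <- rec
  out$values <- as.numeric(agg)
  out$interval_min <- rec$interval_min * ratio
  out
}
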