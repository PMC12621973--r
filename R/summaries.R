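# Phase-binned summaries, hourly ZT profiles, and energy accounting.

#' Diet configuration
#'
#' Metabolizable energy density of the diet, used to convert feeding grams
#' to energy intake. The default 3.16 kcal/g is the standard rodent chow
#' value used throughout.
#'
#' @param energy_density_kcal_per_g kcal per gram of food (default 3.16).
#' @return An object of class `diet_config`.
#' @export
diet_config <- function(energy_density_kcal_per_g = 3.16) {
  stopifnot(energy_density_kcal_per_g > 0)
  structure(list(energy_density_kcal_per_g = energy_density_kcal_per_g),
            class = "diet_config")
}

#' Convert feeding grams to energy intake
#'
#' @param feeding_g Grams of food (vectorized); must be non-negative.
#' @param diet A [diet_config()].
#' @return kcal.
#' @export
energy_intake <- function(feeding_g, diet = diet_config()) {
  stopifnot(inherits(diet, "diet_config"))
  if (any(feeding_g < 0, na.rm = TRUE)) {
    stop("negative feeding grams", call. = FALSE)
  }
  feeding_g * diet$energy_density_kcal_per_g
}

#' Cumulative series of an extensive channel
#'
#' Running sum over time (e.g. cumulative energy intake). Missing samples
#' contribute 0 to the sum; the returned coverage is the fraction of
#' non-missing samples so gappy records are flagged rather than silently
#' summed.
#'
#' @param rec A [ts_recording()] with an extensive channel (locomotion or
#'   feeding); cumulating an intensive channel such as RER is meaningless
#'   and raises an error.
#' @return A `tsrec` of running sums, with attribute `coverage` in [0, 1].
#' @export
cumulative_series <- function(rec) {
  stopifnot(inherits(rec, "tsrec"))
  if (!is_extensive(rec$channel)) {
    stop(sprintf("cannot cumulate intensive channel '%s'", rec$channel),
         call. = FALSE)
  }
  v <- rec$values
  coverage <- mean(is.finite(v))
  v[!is.finite(v)] <- 0
  out <- rec
  out$values <- cumsum(v)
  attr(out, "coverage") <- coverage
  out
}

#' Light/dark phase means of a recording
#'
#' Each bin is assigned a phase by the ZT of its midpoint. Extensive
#' channels are first totalled per phase within each cycle and the per-cycle
#' totals averaged across cycles (so the value reads as "per phase per
#' day"); intensive channels are averaged per phase per cycle, then across
#' cycles. Incomplete leading/trailing cycles contribute the bins they have.
#'
#' @param rec A [ts_recording()].
#' @param schedule A [light_schedule()].
#' @return Data frame with one row per phase: `animal_id`, `channel`,
#'   `phase`, `mean_value`, `n_bins`.
#' @export
phase_means <- function(rec, schedule) {
  stopifnot(inherits(rec, "tsrec"), inherits(schedule, "light_schedule"))
  mid <- rec_times(rec) + rec$interval_min / 2
  zt <- real_to_zt(mid, schedule)
  phase <- phase_label(zt, schedule)
  period_min <- schedule$period_hours * 60
  cycle <- floor((mid - schedule$lights_on_anchor_min) / period_min)
  v <- rec$values
  ok <- is.finite(v)
  out <- lapply(c("light", "dark"), function(ph) {
    sel <- ok & phase == ph
    if (!any(sel)) {
      return(data.frame(animal_id = rec$animal_id, channel = rec$channel,
                        phase = ph, mean_value = NA_real_, n_bins = 0L,
                        stringsAsFactors = FALSE))
    }
    per_cycle <- if (is_extensive(rec$channel)) {
      tapply(v[sel], cycle[sel], sum)
    } else {
      tapply(v[sel], cycle[sel], mean)
    }
    data.frame(animal_id = rec$animal_id, channel = rec$channel, phase = ph,
               mean_value = mean(per_cycle), n_bins = sum(sel),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Hourly zeitgeber-time profile of a recording
#'
#' For each integer ZT hour 0-23, the mean of all bins whose `floor(zt)`
#' (ZT of the bin midpoint) falls in that hour — the within-animal stage of
#' the two-stage profile averaging. Empty cells are `NA`.
#'
#' @param rec A [ts_recording()].
#' @param schedule A [light_schedule()].
#' @return Data frame with `zt_hour` (0-23), `mean_value`, `n_bins`.
#' @export
zt_profile <- function(rec, schedule) {
  stopifnot(inherits(rec, "tsrec"), inherits(schedule, "light_schedule"))
  mid <- rec_times(rec) + rec$interval_min / 2
  zth <- floor(real_to_zt(mid, schedule))
  v <- rec$values
  ok <- is.finite(v)
  mean_value <- rep(NA_real_, 24)
  n_bins <- integer(24)
  for (h in 0:23) {
    sel <- ok & zth == h
    n_bins[h + 1L] <- sum(sel)
    if (any(sel)) mean_value[h + 1L] <- mean(v[sel])
  }
  data.frame(animal_id = rec$animal_id, channel = rec$channel,
             zt_hour = 0:23, mean_value = mean_value, n_bins = n_bins,
             stringsAsFactors = FALSE)
}

#' Cohort-level zeitgeber-time profile
#'
#' Two-stage averaging: values are first averaged within animal and ZT hour
#' ([zt_profile()]), then the cohort mean and standard error are taken
#' across the per-animal profiles. Unlike pooled averaging, animals with
#' more data do not dominate.
#'
#' @param recs List of [ts_recording()] objects (one channel across
#'   animals).
#' @param schedule A [light_schedule()].
#' @return Data frame with `zt_hour`, `mean_value`, `sem`, `n_animals`.
#' @export
cohort_zt_profile <- function(recs, schedule) {
  stopifnot(length(recs) > 0)
  per <- vapply(recs, function(r) zt_profile(r, schedule)$mean_value,
                numeric(24))
  per <- matrix(per, nrow = 24)
  n_animals <- rowSums(is.finite(per))
  mean_value <- rowMeans(per, na.rm = TRUE)
  mean_value[n_animals == 0] <- NA_real_
  sem <- apply(per, 1, function(row) {
    row <- row[is.finite(row)]
    if (length(row) < 2L) NA_real_ else stats::sd(row) / sqrt(length(row))
  })
  data.frame(zt_hour = 0:23, mean_value = mean_value, sem = sem,
             n_animals = n_animals)
}
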