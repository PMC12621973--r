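# Full-pipeline driver: qc -> rebin -> peaks -> circular -> periodogram ->
# coupling -> summaries, with per-stage TSV outputs and a structured log.

#' Pipeline configuration
#'
#' Bundles every stage's settings; [run_pipeline()] writes the resolved
#' configuration next to its outputs so a run can be reproduced from the
#' written file alone.
#'
#' @param schedule A [light_schedule()].
#' @param peak_cfg A [peak_config()].
#' @param periodogram_range Length-2 hours (see
#'   [periodogram_range_preset()]).
#' @param periodogram_alpha Chi-square significance level (default 0.001).
#' @param rayleigh_alpha Rayleigh significance level (default 0.05).
#' @param ccf_max_lag_hr Maximum cross-correlation lag (default 12).
#' @param diet A [diet_config()].
#' @param qc_hoarding,qc_rer Logical toggles for the two cleaning rules.
#' @param quantile_type Quartile/percentile convention for fences and
#'   onsets.
#' @param outdir Output directory.
#' @param seed Recorded seed (provenance; the pipeline itself is
#'   deterministic given its inputs).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(schedule = schedule_preset("LD12:12"),
                            peak_cfg = peak_config(),
                            periodogram_range = periodogram_range_preset("standard"),
                            periodogram_alpha = 0.001,
                            rayleigh_alpha = 0.05,
                            ccf_max_lag_hr = 12,
                            diet = diet_config(),
                            qc_hoarding = TRUE,
                            qc_rer = TRUE,
                            quantile_type = 7,
                            outdir = "circaphen_out",
                            seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Serialize a pipeline configuration to YAML
#' @param config A [pipeline_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  flat <- list(
    schedule = list(period_hours = config$schedule$period_hours,
                    light_hours = config$schedule$light_hours,
                    lights_on_anchor_min = config$schedule$lights_on_anchor_min),
    peak_cfg = unclass(config$peak_cfg),
    periodogram_range = config$periodogram_range,
    periodogram_alpha = config$periodogram_alpha,
    rayleigh_alpha = config$rayleigh_alpha,
    ccf_max_lag_hr = config$ccf_max_lag_hr,
    diet = unclass(config$diet),
    qc_hoarding = config$qc_hoarding,
    qc_rer = config$qc_rer,
    quantile_type = config$quantile_type,
    seed = config$seed)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path A file written by [write_pipeline_config()].
#' @param outdir Output directory for the restored config.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, outdir = "circaphen_out") {
  y <- yaml::read_yaml(path)
  pipeline_config(
    schedule = light_schedule(y$schedule$period_hours,
                              y$schedule$light_hours,
                              y$schedule$lights_on_anchor_min),
    peak_cfg = do.call(peak_config, y$peak_cfg),
    periodogram_range = unlist(y$periodogram_range),
    periodogram_alpha = y$periodogram_alpha,
    rayleigh_alpha = y$rayleigh_alpha,
    ccf_max_lag_hr = y$ccf_max_lag_hr,
    diet = do.call(diet_config, y$diet),
    qc_hoarding = y$qc_hoarding,
    qc_rer = y$qc_rer,
    quantile_type = y$quantile_type,
    outdir = outdir,
    seed = y$seed)
}

stage_try <- function(stage, animal, channel, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed for %s/%s: %s", stage, animal, channel,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline on a cohort
#'
#' Stages, in order: RER bounds and hoarding QC; daily peak/onset detection
#' on locomotion and feeding; per-animal Rayleigh tests on peak ZT; the
#' chi-square periodogram on all four channels; feeding-to-RER and
#' locomotion-to-EE cross-correlation; light/dark phase means and hourly ZT
#' profiles. Channels that are entirely missing are skipped and logged; any
#' stage error aborts naming the stage and the offending animal/channel.
#' Every run writes per-stage TSVs, a QC report, a structured log, and its
#' resolved configuration into `config$outdir`.
#'
#' @param cohort A `cohort` from [simulate_cohort()] or [read_cohort()].
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of the per-stage result data frames.
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(cohort, "cohort"), inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  log_add <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  sched <- config$schedule
  usable <- function(rec) !is.null(rec) && any(is.finite(rec$values))

  qc_rows <- list(); peak_rows <- list(); ray_rows <- list()
  pgram_rows <- list(); pgram_peak_rows <- list(); ccf_rows <- list()
  ccf_max_rows <- list(); phase_rows <- list(); profile_rows <- list()

  for (aid in names(cohort$animals)) {
    chans <- cohort$animals[[aid]]

    # ---- qc ---------------------------------------------------------
    if (config$qc_rer && usable(chans$rer)) {
      fr <- stage_try("qc", aid, "rer", filter_rer(chans$rer$values))
      cleaned <- chans$rer
      cleaned$values[!fr$keep] <- NA_real_  # drop, keep the grid
      chans$rer <- cleaned
      qc_rows[[length(qc_rows) + 1L]] <-
        cbind(animal_id = aid, channel = "rer",
              as.data.frame(fr$report))
      log_add("qc\t%s\trer\tin=%d excluded=%d", aid, fr$report$n_total,
              fr$report$n_excluded)
    }
    if (config$qc_hoarding && usable(chans$feeding)) {
      ph <- stage_try("qc", aid, "feeding", {
        mid <- rec_times(chans$feeding) + chans$feeding$interval_min / 2
        zt <- real_to_zt(mid, sched)
        phase <- phase_label(zt, sched)
        cyc <- floor((mid - sched$lights_on_anchor_min) /
                       (sched$period_hours * 60))
        bins <- tapply(chans$feeding$values, interaction(cyc, phase),
                       sum, na.rm = TRUE)
        grp <- sub("^[^.]*\\.", "", names(bins))
        replace_hoarding_outliers(as.numeric(bins), grp,
                                  type = config$quantile_type)
      })
      qc_rows[[length(qc_rows) + 1L]] <-
        cbind(animal_id = aid, channel = "feeding",
              as.data.frame(ph$report))
      log_add("qc\t%s\tfeeding\tphase_bins=%d replaced=%d", aid,
              ph$report$n_total, ph$report$n_replaced)
    }

    # ---- peaks + circular ------------------------------------------
    for (ch in c("locomotion", "feeding")) {
      rec <- chans[[ch]]
      if (!usable(rec)) { log_add("peaks\t%s\t%s\tskipped (no data)", aid, ch); next }
      ps <- stage_try("peaks", aid, ch,
                      suppressWarnings(detect_daily_peaks(rec, config$peak_cfg,
                                                          sched)))
      if (nrow(ps) > 0) {
        peak_rows[[length(peak_rows) + 1L]] <-
          data.frame(animal_id = aid, channel = ch,
                     peak_time_min = ps$peak_time_min,
                     peak_zt = ps$peak_zt,
                     onset_time_min = ps$onset_time_min,
                     stringsAsFactors = FALSE)
      }
      log_add("peaks\t%s\t%s\tn_peaks=%d", aid, ch, nrow(ps))
      if (nrow(ps) >= 2) {
        rr <- stage_try("circular", aid, ch,
                        rayleigh_on_peaks(ps, sched,
                                          alpha = config$rayleigh_alpha))
        ray_rows[[length(ray_rows) + 1L]] <-
          data.frame(animal_id = aid, channel = ch, n = rr$n,
                     R = rr$resultant_length_R, Z = rr$Z,
                     p_value = rr$p_value, significant = rr$significant,
                     stringsAsFactors = FALSE)
      }
    }

    # ---- periodogram ------------------------------------------------
    for (ch in CHANNELS) {
      rec <- chans[[ch]]
      if (!usable(rec)) { log_add("periodogram\t%s\t%s\tskipped", aid, ch); next }
      pg <- stage_try("periodogram", aid, ch,
                      chi_square_periodogram(rec, config$periodogram_range,
                                             config$periodogram_alpha))
      pgram_rows[[length(pgram_rows) + 1L]] <-
        data.frame(animal_id = aid, channel = ch,
                   period_hr = pg$periods_hr, Qp = pg$Qp,
                   threshold = pg$threshold, stringsAsFactors = FALSE)
      pgram_peak_rows[[length(pgram_peak_rows) + 1L]] <-
        data.frame(animal_id = aid, channel = ch,
                   primary_peak_hr = pg$primary_peak_hr,
                   primary_power = pg$primary_power,
                   secondary_peak_hr = pg$secondary_peak_hr,
                   secondary_power = pg$secondary_power,
                   classification = classify_rhythmicity(pg),
                   stringsAsFactors = FALSE)
      log_add("periodogram\t%s\t%s\tprimary=%s", aid, ch,
              format(pg$primary_peak_hr))
    }

    # ---- coupling ---------------------------------------------------
    pairs <- list(c("feeding", "rer"), c("locomotion", "energy_expenditure"))
    for (pr in pairs) {
      if (!usable(chans[[pr[1]]]) || !usable(chans[[pr[2]]])) next
      cc <- stage_try("coupling", aid, paste(pr, collapse = "->"),
                      cross_correlate(chans[[pr[1]]], chans[[pr[2]]],
                                      max_lag_hr = config$ccf_max_lag_hr))
      ccf_rows[[length(ccf_rows) + 1L]] <-
        data.frame(animal_id = aid, x_channel = pr[1], y_channel = pr[2],
                   lag_hr = cc$lags_hr, correlation = cc$correlations,
                   stringsAsFactors = FALSE)
      ccf_max_rows[[length(ccf_max_rows) + 1L]] <-
        data.frame(animal_id = aid, x_channel = pr[1], y_channel = pr[2],
                   max_corr = cc$max_corr, lag_at_max_hr = cc$lag_at_max_hr,
                   stringsAsFactors = FALSE)
      log_add("coupling\t%s\t%s->%s\tlag_at_max=%+g", aid, pr[1], pr[2],
              cc$lag_at_max_hr)
    }

    # ---- summaries --------------------------------------------------
    for (ch in CHANNELS) {
      rec <- chans[[ch]]
      if (!usable(rec)) next
      phase_rows[[length(phase_rows) + 1L]] <-
        stage_try("summaries", aid, ch, phase_means(rec, sched))
      profile_rows[[length(profile_rows) + 1L]] <-
        stage_try("summaries", aid, ch, zt_profile(rec, sched))
    }
  }

  results <- list(
    qc = do.call(rbind, qc_rows),
    peaks = do.call(rbind, peak_rows),
    rayleigh = do.call(rbind, ray_rows),
    periodogram = do.call(rbind, pgram_rows),
    periodogram_peaks = do.call(rbind, pgram_peak_rows),
    ccf = do.call(rbind, ccf_rows),
    ccf_max = do.call(rbind, ccf_max_rows),
    phase_summary = do.call(rbind, phase_rows),
    zt_profile = do.call(rbind, profile_rows))
  for (nm in names(results)) {
    if (!is.null(results[[nm]])) {
      write_tsv(results[[nm]], file.path(config$outdir,
                                         paste0(nm, ".tsv")))
    }
  }
  write_pipeline_config(config, file.path(config$outdir, "config.yaml"))
  writeLines(log_lines, file.path(config$outdir, "run.log"))
  invisible(results)
}
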