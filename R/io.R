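# Long-format CSV input/output and configuration files.
#
# Cohorts travel as plain long CSV with the header
#   animal_id, genotype, condition, channel, t_min, value
# (empty value = missing sample); light schedules as small YAML files with
# keys period_hours, light_hours, lights_on_anchor_min. No binary formats.

COHORT_COLUMNS <- c("animal_id", "genotype", "condition", "channel",
                    "t_min", "value")

#' Flatten a cohort to a long data frame
#' @param cohort A `cohort`.
#' @return Data frame with the standard long columns.
#' @export
cohort_to_df <- function(cohort) {
  rows <- lapply(cohort$animals, function(channels) {
    do.call(rbind, lapply(channels, function(rec) {
      data.frame(animal_id = rec$animal_id, genotype = rec$genotype,
                 condition = rec$condition, channel = rec$channel,
                 t_min = rec_times(rec), value = rec$values,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a cohort to long-format CSV
#' @param cohort A `cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort_to_df(cohort), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read a cohort from long-format CSV
#'
#' Validates the header, channel labels, timestamp monotonicity and
#' uniqueness per (animal, channel), and uniform sampling; malformed input
#' is reported with the offending rows.
#'
#' @param path CSV file with columns `animal_id`, `genotype`, `condition`,
#'   `channel`, `t_min`, `value` (empty value = missing).
#' @return A `cohort` (without simulation config).
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad_channel <- which(!df$channel %in% CHANNELS)
  if (length(bad_channel) > 0) {
    stop(sprintf("unknown channel '%s' at row %d (of the data rows)",
                 df$channel[bad_channel[1]], bad_channel[1]), call. = FALSE)
  }
  if (any(!is.finite(df$t_min))) {
    stop("non-numeric or missing t_min at row ",
         which(!is.finite(df$t_min))[1], call. = FALSE)
  }
  key <- interaction(df$animal_id, df$channel, drop = TRUE)
  animals <- list()
  for (k in levels(key)) {
    sub <- df[key == k, ]
    if (anyDuplicated(sub$t_min)) {
      stop(sprintf("duplicated (animal_id, channel, t_min) for %s at t_min=%g",
                   k, sub$t_min[duplicated(sub$t_min)][1]), call. = FALSE)
    }
    if (is.unsorted(sub$t_min, strictly = TRUE)) {
      stop(sprintf("non-monotone timestamps for %s", k), call. = FALSE)
    }
    if (nrow(sub) >= 2) {
      steps <- diff(sub$t_min)
      if (max(steps) - min(steps) > 1e-8 * max(steps)) {
        stop(sprintf("non-uniform sampling for %s", k), call. = FALSE)
      }
      interval <- steps[1]
    } else interval <- 1
    rec <- ts_recording(sub$value, channel = sub$channel[1],
                        interval_min = interval, start_min = sub$t_min[1],
                        animal_id = sub$animal_id[1],
                        genotype = sub$genotype[1],
                        condition = sub$condition[1])
    aid <- sub$animal_id[1]
    if (is.null(animals[[aid]])) animals[[aid]] <- list()
    animals[[aid]][[sub$channel[1]]] <- rec
  }
  structure(list(animals = animals, config = NULL), class = "cohort")
}

#' Read a light schedule from a YAML config file
#' @param path YAML file with keys `period_hours`, `light_hours`,
#'   `lights_on_anchor_min` (optional, default 0).
#' @return A [light_schedule()].
#' @export
read_schedule <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$period_hours) || is.null(cfg$light_hours)) {
    stop("schedule config must define period_hours and light_hours",
         call. = FALSE)
  }
  light_schedule(cfg$period_hours, cfg$light_hours,
                 if (is.null(cfg$lights_on_anchor_min)) 0 else
                   cfg$lights_on_anchor_min)
}

#' Write a light schedule to a YAML config file
#' @param schedule A [light_schedule()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "light_schedule"))
  yaml::write_yaml(list(period_hours = schedule$period_hours,
                        light_hours = schedule$light_hours,
                        lights_on_anchor_min = schedule$lights_on_anchor_min),
                   path)
  invisible(path)
}

write_tsv <- function(df, path, digits = 6) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}
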