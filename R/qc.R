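# Quality control: fence-based outlier handling and duplicate reconciliation.
#
# Three rules operate on grouped values (group = e.g. genotype x condition x
# phase): hoarding replacement at Q3 + 2.5*IQR (replace with group median),
# Tukey-fence exclusion at Q1 - 1.5*IQR / Q3 + 1.5*IQR, and physiologic RER
# bounds. All inequalities are strict, and fences are applied in a single
# pass (fences are not recomputed after replacement/exclusion; re-fencing
# could cascade, which the pipeline deliberately avoids).

#' Quartiles and interquartile range
#'
#' Quartiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7, the common default of mainstream numerics
#' libraries); the convention is configurable because fence rules are
#' sensitive to it.
#'
#' @param values Numeric vector; `NA` dropped. At least one finite value
#'   required.
#' @param type Quantile algorithm passed to [stats::quantile()].
#' @return Named list with `q1`, `q3`, `iqr`.
#' @export
quartiles <- function(values, type = 7) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) {
    stop("insufficient data: no finite values for quartiles", call. = FALSE)
  }
  q <- stats::quantile(values, probs = c(0.25, 0.75), type = type,
                       names = FALSE)
  list(q1 = q[1], q3 = q[2], iqr = q[2] - q[1])
}

qc_report <- function(rule, n_total, n_replaced = 0L, n_excluded = 0L,
                      notes = character()) {
  structure(
    list(rule = rule,
         n_total = as.integer(n_total),
         n_replaced = as.integer(n_replaced),
         n_excluded = as.integer(n_excluded),
         fraction_affected = if (n_total > 0)
           (n_replaced + n_excluded) / n_total else 0,
         notes = notes),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> rule=%s n=%d replaced=%d excluded=%d (%.2f%%)\n",
              x$rule, x$n_total, x$n_replaced, x$n_excluded,
              100 * x$fraction_affected))
  for (n in x$notes) cat("  note: ", n, "\n", sep = "")
  invisible(x)
}

#' One-row data frame view of a QC report (for TSV output)
#' @param x A `qc_report`.
#' @param ... Unused.
#' @export
as.data.frame.qc_report <- function(x, ...) {
  data.frame(rule = x$rule, n_total = x$n_total, n_replaced = x$n_replaced,
             n_excluded = x$n_excluded,
             fraction_affected = x$fraction_affected,
             stringsAsFactors = FALSE)
}

#' Replace hoarding outliers in phase-binned feeding
#'
#' Mice occasionally hoard: they pull a large amount of food from the basket
#' and waste it, producing spuriously large feeding readings. On feeding
#' already binned into daily light/dark phases, any value strictly greater
#' than `Q3 + 2.5 * IQR` of its group is replaced with the group median; the
#' number of observations never changes.
#'
#' @param values Numeric vector of phase-binned feeding values.
#' @param group Vector/factor of group labels, same length as `values`
#'   (e.g. interaction of genotype, condition and phase). Default: one group.
#' @param k Fence multiplier (default 2.5).
#' @param type Quartile convention, see [quartiles()].
#' @return List with `values` (cleaned, same length), `replaced` (logical
#'   mask) and `report` (a `qc_report`).
#' @export
replace_hoarding_outliers <- function(values, group = NULL, k = 2.5,
                                      type = 7) {
  if (is.null(group)) group <- rep_len("all", length(values))
  stopifnot(length(group) == length(values))
  out <- values
  replaced <- rep(FALSE, length(values))
  notes <- character()
  for (g in unique(group)) {
    idx <- which(group == g)
    v <- values[idx]
    if (!any(is.finite(v))) {
      notes <- c(notes, sprintf("group '%s' empty, skipped", g))
      next
    }
    q <- quartiles(v, type = type)
    fence <- q$q3 + k * q$iqr
    med <- stats::median(v, na.rm = TRUE)
    hit <- is.finite(v) & v > fence
    out[idx][hit] <- med
    replaced[idx][hit] <- TRUE
  }
  list(values = out, replaced = replaced,
       report = qc_report("hoarding_replacement", sum(is.finite(values)),
                          n_replaced = sum(replaced), notes = notes))
}

#' Filter respiratory exchange ratio to physiologic bounds
#'
#' RER = VCO2/VO2 lies near 0.7 for pure fat oxidation and near 1.0 for pure
#' carbohydrate oxidation; values below 0.7 or above 1.2 reflect technical
#' anomalies and are excluded. Bounds are strict: 0.7 and 1.2 themselves are
#' retained.
#'
#' @param values Numeric RER values.
#' @param lower,upper Physiologic bounds (defaults 0.7 and 1.2).
#' @return List with `values` (retained), `keep` (logical mask over input;
#'   `NA` inputs are not counted as exclusions) and `report`.
#' @export
filter_rer <- function(values, lower = 0.7, upper = 1.2) {
  bad <- is.finite(values) & (values < lower | values > upper)
  keep <- !bad
  list(values = values[keep & !is.na(values)], keep = keep,
       report = qc_report("rer_bounds", sum(is.finite(values)),
                          n_excluded = sum(bad)))
}

#' Tukey-fence exclusion within groups
#'
#' Excludes any value strictly below `Q1 - k*IQR` or strictly above
#' `Q3 + k*IQR` of its group (default k = 1.5), as applied to assay and
#' endocannabinoid group means. Single pass: fences come from the original
#' group, never recomputed after exclusion.
#'
#' @param values Numeric vector.
#' @param group Group labels (default: one group).
#' @param k Fence multiplier (default 1.5).
#' @param type Quartile convention, see [quartiles()].
#' @return List with `values` (retained), `keep` (logical mask) and `report`.
#' @export
tukey_fence_exclude <- function(values, group = NULL, k = 1.5, type = 7) {
  if (is.null(group)) group <- rep_len("all", length(values))
  stopifnot(length(group) == length(values))
  keep <- rep(TRUE, length(values))
  notes <- character()
  for (g in unique(group)) {
    idx <- which(group == g)
    v <- values[idx]
    if (!any(is.finite(v))) {
      notes <- c(notes, sprintf("group '%s' empty, skipped", g))
      next
    }
    q <- quartiles(v, type = type)
    lo <- q$q1 - k * q$iqr
    hi <- q$q3 + k * q$iqr
    bad <- is.finite(v) & (v < lo | v > hi)
    keep[idx][bad] <- FALSE
  }
  list(values = values[keep & !is.na(values)], keep = keep,
       report = qc_report("tukey_fence", sum(is.finite(values)),
                          n_excluded = sum(!keep), notes = notes))
}

#' Reconcile duplicate assay wells
#'
#' For a duplicate-well pair, if the percent coefficient of variation
#' (sample SD of the two replicates over their mean, as percent) is strictly
#' greater than `cv_threshold`, the replicate more distal from the group
#' mean is dropped and the closer one returned; otherwise the pair mean is
#' returned. A pair mean of zero makes the CV undefined; the pair mean is
#' returned with a flag.
#'
#' @param rep_a,rep_b The two replicate measurements.
#' @param group_mean Mean of the sample's group (genotype x condition).
#' @param cv_threshold Percent CV above which reconciliation triggers
#'   (default 10).
#' @return List with `value`, `cv_percent`, `dropped_replicate` (NA, 1 or 2)
#'   and `flag` (character, `"cv_undefined"` when the pair mean is zero).
#' @export
reconcile_duplicates <- function(rep_a, rep_b, group_mean,
                                 cv_threshold = 10) {
  stopifnot(is.finite(rep_a), is.finite(rep_b))
  m <- mean(c(rep_a, rep_b))
  if (m == 0) {
    return(list(value = m, cv_percent = NA_real_,
                dropped_replicate = NA_integer_, flag = "cv_undefined"))
  }
  cv <- 100 * stats::sd(c(rep_a, rep_b)) / m
  if (cv > cv_threshold) {
    d <- abs(c(rep_a, rep_b) - group_mean)
    keep <- which.min(d)  # ties keep the first replicate
    list(value = c(rep_a, rep_b)[keep], cv_percent = cv,
         dropped_replicate = setdiff(1:2, keep), flag = character())
  } else {
    list(value = m, cv_percent = cv, dropped_replicate = NA_integer_,
         flag = character())
  }
}
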