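#' Known analyte codes
#'
#' Fecal steroid metabolites are reported per gram of dry feces; serum analytes
#' in ug/ml or ng/ml. Units are carried through the pipeline but never
#' converted.
#' @export
ANALYTES <- c(
  "E2_fecal", "P4_fecal", "AMH_serum", "LH_serum", "INHA_serum",
  "INHB_serum", "FST_serum", "T_serum", "CNP_serum"
)

#' Allowed exclusion-interval reasons
#' @export
EXCLUSION_REASONS <- c("pregnancy", "lactation", "collection_suspended")

STUDY_GROUPS <- c("control", "low_dose", "high_dose")

#' Analysis configuration
#'
#' Bundles the tunable parameters of the baseline / phase-calling / frequency
#' analysis. Defaults implement the standard fecal-endocrinology workflow:
#' an iterative baseline excluding points above mean + 1.5 SD, an estrous
#' phase of >= 2 consecutive elevated E2 samples, a luteal phase of >= 6
#' consecutive elevated P4 samples, and phase frequencies normalized to
#' 30-day (estrous) and 180-day (luteal) reporting windows.
#'
#' @param baseline_k positive multiplier `k` of the exclusion threshold.
#' @param baseline_mode `"sd_above_mean"` (threshold = mean + k * SD) or
#'   `"fold_of_mean"` (threshold = k * mean). Both appear in the
#'   fecal-endocrinology literature; the SD form is the default.
#' @param estrous_min_run,luteal_min_run minimum number of consecutive
#'   above-threshold samples for a phase call.
#' @param estrous_norm_days,luteal_norm_days reporting-window lengths (days)
#'   used to normalize phase counts.
#' @param baseline_window name of the study period the baseline is fit on.
#' @param amh_target serum AMH concentration (ug/ml) regarded as the
#'   contraceptive target level.
#' @param max_lag_days maximum days after the end of a breeding bout within
#'   which a luteal-phase onset is attributed to that bout.
#' @param rng_seed integer seed recorded with pipeline runs.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(baseline_k = 1.5,
                            baseline_mode = c("sd_above_mean", "fold_of_mean"),
                            estrous_min_run = 2L,
                            luteal_min_run = 6L,
                            estrous_norm_days = 30L,
                            luteal_norm_days = 180L,
                            baseline_window = "pre_treatment",
                            amh_target = 0.25,
                            max_lag_days = 21L,
                            rng_seed = 1L) {
  baseline_mode <- match.arg(baseline_mode)
  stopifnot(
    is.numeric(baseline_k), length(baseline_k) == 1L, baseline_k > 0,
    estrous_min_run >= 1L, luteal_min_run >= 1L,
    estrous_norm_days > 0L, luteal_norm_days > 0L,
    amh_target > 0, max_lag_days >= 1L
  )
  structure(
    list(
      baseline_k = as.numeric(baseline_k),
      baseline_mode = baseline_mode,
      estrous_min_run = as.integer(estrous_min_run),
      luteal_min_run = as.integer(luteal_min_run),
      estrous_norm_days = as.integer(estrous_norm_days),
      luteal_norm_days = as.integer(luteal_norm_days),
      baseline_window = baseline_window,
      amh_target = as.numeric(amh_target),
      max_lag_days = as.integer(max_lag_days),
      rng_seed = as.integer(rng_seed)
    ),
    class = "analysis_config"
  )
}

#' Default study periods
#'
#' Day offsets are relative to treatment (day 0). Months are 30-day blocks:
#' a 6-month pre-treatment window, a 2-month transition and a 22-month
#' post-treatment window. All intervals are half-open `[start, end)`.
#' @export
default_periods <- function() {
  list(
    pre_treatment = c(-180, 0),
    transition = c(0, 60),
    post_treatment = c(60, 720)
  )
}

#' Study design: group assignment, periods and exclusion intervals
#'
#' @param groups a data frame with columns `animal_id`, `group`
#'   (one of control / low_dose / high_dose), or a named character vector
#'   mapping animal ids to groups.
#' @param treatment_day integer day of treatment; 0 by convention.
#' @param periods named list of half-open `c(start, end)` day intervals;
#'   must be disjoint and ordered.
#' @param exclusions optional data frame with columns `animal_id`,
#'   `start_day`, `end_day` (half-open), `reason` (see [EXCLUSION_REASONS]).
#' @return A list of class `study_design`.
#' @export
study_design <- function(groups,
                         treatment_day = 0L,
                         periods = default_periods(),
                         exclusions = NULL) {
  if (is.character(groups) && !is.null(names(groups))) {
    groups <- tibble::tibble(animal_id = names(groups), group = unname(groups))
  }
  groups <- tibble::as_tibble(groups)
  stopifnot(all(c("animal_id", "group") %in% names(groups)))
  bad <- setdiff(unique(groups$group), STUDY_GROUPS)
  if (length(bad) > 0) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(groups$animal_id)) {
    stop("duplicated animal_id in group assignment", call. = FALSE)
  }

  stopifnot(is.list(periods), length(periods) >= 1, !is.null(names(periods)))
  for (p in periods) {
    stopifnot(length(p) == 2L, p[1] < p[2])
  }
  ord <- order(vapply(periods, `[`, numeric(1), 1))
  sorted <- periods[ord]
  for (i in seq_along(sorted)[-1]) {
    if (sorted[[i]][1] < sorted[[i - 1]][2]) {
      stop("study periods overlap: ", names(sorted)[i - 1], " and ",
           names(sorted)[i], call. = FALSE)
    }
  }

  exclusions <- validate_exclusions(exclusions)

  structure(
    list(
      groups = groups,
      treatment_day = as.integer(treatment_day),
      periods = periods,
      exclusions = exclusions
    ),
    class = "study_design"
  )
}

validate_exclusions <- function(exclusions) {
  if (is.null(exclusions) || (is.data.frame(exclusions) && nrow(exclusions) == 0)) {
    return(tibble::tibble(
      animal_id = character(), start_day = integer(),
      end_day = integer(), reason = character()
    ))
  }
  exclusions <- tibble::as_tibble(exclusions)
  stopifnot(all(c("animal_id", "start_day", "end_day", "reason") %in% names(exclusions)))
  if (any(exclusions$start_day >= exclusions$end_day)) {
    stop("exclusion intervals must satisfy start_day < end_day", call. = FALSE)
  }
  bad <- setdiff(unique(exclusions$reason), EXCLUSION_REASONS)
  if (length(bad) > 0) {
    stop("unknown exclusion reason(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  exclusions
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  cat(sprintf("  threshold: %s, k = %g; baseline window: %s\n",
              x$baseline_mode, x$baseline_k, x$baseline_window))
  cat(sprintf("  estrous: >= %d samples (norm %d d); luteal: >= %d samples (norm %d d)\n",
              x$estrous_min_run, x$estrous_norm_days,
              x$luteal_min_run, x$luteal_norm_days))
  cat(sprintf("  AMH target: %g ug/ml; bout->luteal lag: %d d; seed: %d\n",
              x$amh_target, x$max_lag_days, x$rng_seed))
  invisible(x)
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design>\n")
  cat(sprintf("  %d animals in %d groups; treatment day %d\n",
              nrow(x$groups), length(unique(x$groups$group)), x$treatment_day))
  for (nm in names(x$periods)) {
    cat(sprintf("  period %-14s [%5d, %5d)\n", nm, x$periods[[nm]][1], x$periods[[nm]][2]))
  }
  cat(sprintf("  %d exclusion interval(s)\n", nrow(x$exclusions)))
  invisible(x)
}

# ---- interval helpers (half-open [start, end)) ------------------------------

in_window <- function(day, window) {
  day >= window[1] & day < window[2]
}

window_length <- function(window) {
  window[2] - window[1]
}

# total days of `window` covered by (possibly overlapping) intervals;
# overlapping intervals are merged first so days are not double-counted
overlap_days <- function(intervals, window) {
  if (is.null(intervals) || nrow(intervals) == 0) return(0)
  s <- pmax(intervals$start_day, window[1])
  e <- pmin(intervals$end_day, window[2])
  keep <- s < e
  if (!any(keep)) return(0)
  s <- s[keep]; e <- e[keep]
  o <- order(s)
  s <- s[o]; e <- e[o]
  total <- 0
  cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] <= cur_e) {
      cur_e <- max(cur_e, e[i])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- s[i]; cur_e <- e[i]
    }
  }
  total + (cur_e - cur_s)
}

animal_exclusions <- function(exclusions, animal) {
  if (is.null(exclusions) || nrow(exclusions) == 0) return(exclusions)
  exclusions[exclusions$animal_id == animal, , drop = FALSE]
}

# TRUE for days falling inside any of the intervals
day_excluded <- function(day, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) return(rep(FALSE, length(day)))
  out <- rep(FALSE, length(day))
  for (i in seq_len(nrow(intervals))) {
    out <- out | (day >= intervals$start_day[i] & day < intervals$end_day[i])
  }
  out
}
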