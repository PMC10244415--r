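#' Iterative hormone-baseline estimation
#'
#' Estimates the non-elevated baseline of a hormone series by iterative
#' exclusion: starting from all samples in the baseline window, the mean and
#' sample SD (n - 1 denominator) of the retained points are computed, every
#' retained point strictly greater than the threshold is excluded
#' (permanently), and the procedure repeats until an iteration excludes
#' nothing. The threshold is `mean + k * SD` in `sd_above_mean` mode or
#' `k * mean` in `fold_of_mean` mode, always recomputed from the currently
#' retained points.
#'
#' @param series a hormone table restricted to one (animal, analyte); see
#'   [read_hormone_table()].
#' @param window half-open `c(start, end)` day interval to fit on, typically
#'   the pre-treatment period.
#' @param k positive threshold multiplier (default 1.5).
#' @param mode `"sd_above_mean"` or `"fold_of_mean"`.
#' @param exclusions optional exclusion intervals; samples inside them are
#'   dropped before fitting.
#' @return An object of class `baseline_fit` with the converged
#'   `baseline_mean`, `baseline_sd`, `threshold`, the retained-point mask over
#'   the window samples, and iteration counts.
#' @export
fit_baseline <- function(series, window, k = 1.5,
                         mode = c("sd_above_mean", "fold_of_mean"),
                         exclusions = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(k), length(k) == 1L, k > 0,
            length(window) == 2L, window[1] < window[2])
  series <- one_series(series)
  animal <- series$animal_id[1]
  if (!is.null(exclusions)) {
    ex <- animal_exclusions(exclusions, animal)
    series <- series[!day_excluded(series$day, ex), , drop = FALSE]
  }
  inw <- in_window(series$day, window)
  v <- series$value[inw]
  days <- series$day[inw]
  n <- length(v)
  if (n < 3) {
    stop("insufficient data: baseline window holds ", n,
         " samples (need >= 3)", call. = FALSE)
  }

  retained <- rep(TRUE, n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    m <- mean(v[retained])
    s <- if (sum(retained) > 1) stats::sd(v[retained]) else 0
    thr <- if (mode == "sd_above_mean") m + k * s else k * m
    drop <- retained & (v > thr)
    if (!any(drop)) break
    if (all(drop == retained)) {
      # cannot happen in sd mode with k > 0 (the minimum never exceeds
      # mean + k*SD), but guards fold mode with k < 1
      stop("baseline exclusion removed every point; check k and mode",
           call. = FALSE)
    }
    retained[drop] <- FALSE
  }

  structure(
    list(
      animal_id = animal,
      analyte = series$analyte[1],
      baseline_mean = m,
      baseline_sd = s,
      k = k,
      mode = mode,
      threshold = thr,
      n_input = n,
      n_retained = sum(retained),
      n_iterations = iter,
      retained_mask = retained,
      window_days = days,
      window = window
    ),
    class = "baseline_fit"
  )
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("<baseline_fit> %s / %s\n", x$animal_id, x$analyte))
  cat(sprintf("  mean %.4g, SD %.4g, threshold %.4g (%s, k = %g)\n",
              x$baseline_mean, x$baseline_sd, x$threshold, x$mode, x$k))
  cat(sprintf("  retained %d / %d samples in %d iteration(s)\n",
              x$n_retained, x$n_input, x$n_iterations))
  invisible(x)
}

#' Fit baselines for every (animal, analyte) series in a table
#'
#' @param hormones a hormone table.
#' @param window baseline window, e.g. `design$periods$pre_treatment`.
#' @inheritParams fit_baseline
#' @param analytes which analytes to fit (default: fecal E2 and P4).
#' @return A tibble with one row per fitted series (animal_id, analyte,
#'   baseline_mean, baseline_sd, k, mode, threshold, n_input, n_retained,
#'   n_iterations); the `baseline_fit` objects are attached as a list column
#'   `fit`.
#' @export
fit_baselines <- function(hormones, window, k = 1.5,
                          mode = c("sd_above_mean", "fold_of_mean"),
                          exclusions = NULL,
                          analytes = c("E2_fecal", "P4_fecal")) {
  mode <- match.arg(mode)
  keys <- dplyr::distinct(
    hormones[hormones$analyte %in% analytes, c("animal_id", "analyte")]
  )
  fits <- lapply(seq_len(nrow(keys)), function(i) {
    s <- hormones[hormones$animal_id == keys$animal_id[i] &
                    hormones$analyte == keys$analyte[i], , drop = FALSE]
    fit_baseline(s, window, k = k, mode = mode, exclusions = exclusions)
  })
  out <- dplyr::bind_rows(lapply(fits, function(f) {
    tibble::tibble(
      animal_id = f$animal_id, analyte = f$analyte,
      baseline_mean = f$baseline_mean, baseline_sd = f$baseline_sd,
      k = f$k, mode = f$mode, threshold = f$threshold,
      n_input = f$n_input, n_retained = f$n_retained,
      n_iterations = f$n_iterations
    )
  }))
  out$fit <- fits
  out
}

#' Call estrous or luteal phases as run-length events
#'
#' Samples falling in exclusion intervals (pregnancy, lactation, suspended
#' collection) are removed and the remaining samples are segmented at
#' exclusion boundaries, so a run never spans an exclusion. Within each
#' segment, maximal runs of consecutive samples with value strictly greater
#' than the fitted threshold, of length at least `min_run`, become phase
#' calls. Consecutiveness is in collection order (sampling is thrice weekly),
#' not calendar days.
#'
#' @param series a hormone table restricted to one (animal, analyte).
#' @param fit the [fit_baseline()] result for the same animal and analyte.
#' @param phase_type `"estrous"` (E2) or `"luteal"` (P4).
#' @param min_run minimum run length: 2 for estrous, 6 for luteal by
#'   convention.
#' @param exclusions optional exclusion intervals for this cohort.
#' @return A tibble of phase calls (animal_id, phase_type, start_day,
#'   end_day, n_samples, peak_value); `start_day`/`end_day` are the collection
#'   days of the first and last sample of the run (inclusive).
#' @export
call_phases <- function(series, fit, phase_type = c("estrous", "luteal"),
                        min_run = if (phase_type == "estrous") 2L else 6L,
                        exclusions = NULL) {
  phase_type <- match.arg(phase_type)
  stopifnot(inherits(fit, "baseline_fit"), min_run >= 1L)
  series <- one_series(series)
  if (series$animal_id[1] != fit$animal_id || series$analyte[1] != fit$analyte) {
    stop("contract error: series and baseline fit refer to different ",
         "animal or analyte", call. = FALSE)
  }

  ex <- animal_exclusions(exclusions, series$animal_id[1])
  keep <- !day_excluded(series$day, ex)
  day <- series$day[keep]
  value <- series$value[keep]
  if (length(day) == 0) return(empty_phase_calls())

  # segment index: number of exclusion intervals lying entirely before the
  # sample; samples separated by an exclusion land in different segments
  seg <- if (is.null(ex) || nrow(ex) == 0) rep(0L, length(day)) else
    vapply(day, function(d) sum(ex$end_day <= d), integer(1))

  above <- value > fit$threshold
  calls <- list()
  r <- rle(paste0(seg, "_", above))
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  for (j in seq_along(r$lengths)) {
    if (!endsWith(r$values[j], "_TRUE")) next
    if (r$lengths[j] < min_run) next
    i0 <- idx_start[j]; i1 <- idx_end[j]
    calls[[length(calls) + 1L]] <- tibble::tibble(
      animal_id = series$animal_id[1],
      phase_type = phase_type,
      start_day = day[i0],
      end_day = day[i1],
      n_samples = i1 - i0 + 1L,
      peak_value = max(value[i0:i1])
    )
  }
  if (length(calls) == 0) return(empty_phase_calls())
  dplyr::bind_rows(calls)
}

empty_phase_calls <- function() {
  tibble::tibble(
    animal_id = character(), phase_type = character(),
    start_day = integer(), end_day = integer(),
    n_samples = integer(), peak_value = numeric()
  )
}

#' Call phases for a whole cohort
#'
#' Fits nothing itself: takes the output of [fit_baselines()] and calls
#' estrous phases on E2 series and luteal phases on P4 series.
#'
#' @param hormones hormone table.
#' @param baselines result of [fit_baselines()].
#' @param config an [analysis_config()].
#' @param exclusions exclusion intervals.
#' @return A tibble of phase calls across animals.
#' @export
call_phases_cohort <- function(hormones, baselines, config = analysis_config(),
                               exclusions = NULL) {
  spec <- list(
    E2_fecal = list(type = "estrous", min_run = config$estrous_min_run),
    P4_fecal = list(type = "luteal", min_run = config$luteal_min_run)
  )
  out <- list()
  for (i in seq_len(nrow(baselines))) {
    an <- baselines$analyte[i]
    if (!an %in% names(spec)) next
    s <- hormones[hormones$animal_id == baselines$animal_id[i] &
                    hormones$analyte == an, , drop = FALSE]
    out[[length(out) + 1L]] <- call_phases(
      s, baselines$fit[[i]], phase_type = spec[[an]]$type,
      min_run = spec[[an]]$min_run, exclusions = exclusions
    )
  }
  if (length(out) == 0) return(empty_phase_calls())
  dplyr::bind_rows(out)
}

#' Normalized phase frequency in a window
#'
#' Counts phase calls whose start day lies in the half-open window, divides by
#' the effective number of days (window length minus days overlapped by
#' exclusion intervals) and scales to a fixed-length reporting window:
#' `normalized = n_phases / effective_days * norm_days`. Estrous frequencies
#' are conventionally reported per 30 days and luteal frequencies per 180
#' days.
#'
#' @param calls phase-call tibble for one animal and one phase type.
#' @param window half-open `c(start, end)` day interval.
#' @param norm_days reporting-window length in days.
#' @param exclusions optional exclusion intervals (for the same animal).
#' @param animal_id,phase_type optional labels, inferred from `calls` when it
#'   is non-empty.
#' @return A one-row tibble (animal_id, phase_type, n_phases, effective_days,
#'   normalized).
#' @export
phase_frequency <- function(calls, window, norm_days,
                            exclusions = NULL,
                            animal_id = NULL, phase_type = NULL) {
  stopifnot(length(window) == 2L, window[1] < window[2], norm_days > 0)
  if (is.null(animal_id)) {
    animal_id <- if (nrow(calls) > 0) calls$animal_id[1] else NA_character_
  }
  if (is.null(phase_type)) {
    phase_type <- if (nrow(calls) > 0) calls$phase_type[1] else NA_character_
  }
  ex <- if (is.na(animal_id)) exclusions else animal_exclusions(exclusions, animal_id)
  effective <- window_length(window) - overlap_days(ex, window)
  if (effective <= 0) {
    stop("degenerate window: no effective sampling days remain", call. = FALSE)
  }
  n <- if (nrow(calls) == 0) 0L else sum(in_window(calls$start_day, window))
  tibble::tibble(
    animal_id = animal_id,
    phase_type = phase_type,
    n_phases = as.integer(n),
    effective_days = as.numeric(effective),
    normalized = n / effective * norm_days
  )
}

#' Per-animal phase-frequency table across study periods
#'
#' @param calls cohort phase-call tibble from [call_phases_cohort()].
#' @param design a [study_design()].
#' @param config an [analysis_config()].
#' @param periods which named periods to tabulate (default pre- and
#'   post-treatment).
#' @return A tibble with one row per animal x phase type x period.
#' @export
phase_frequency_table <- function(calls, design, config = analysis_config(),
                                  periods = c("pre_treatment", "post_treatment")) {
  stopifnot(inherits(design, "study_design"))
  norm <- c(estrous = config$estrous_norm_days, luteal = config$luteal_norm_days)
  out <- list()
  for (a in design$groups$animal_id) {
    for (pt in c("estrous", "luteal")) {
      ac <- calls[calls$animal_id == a & calls$phase_type == pt, , drop = FALSE]
      for (p in periods) {
        row <- phase_frequency(
          ac, design$periods[[p]], norm_days = norm[[pt]],
          exclusions = design$exclusions, animal_id = a, phase_type = pt
        )
        row$period <- p
        out[[length(out) + 1L]] <- row
      }
    }
  }
  res <- dplyr::bind_rows(out)
  res <- dplyr::left_join(res, design$groups, by = "animal_id")
  res[, c("animal_id", "group", "phase_type", "period", "n_phases",
          "effective_days", "normalized")]
}

#' Serum AMH compliance with a target concentration
#'
#' @param series hormone table restricted to one animal's `AMH_serum` series.
#' @param target target concentration in the series' units (default 0.25
#'   ug/ml).
#' @param treatment_day day treatment was given; samples from this day on are
#'   evaluated.
#' @return A list with `fraction` (share of post-treatment samples at or above
#'   target) and `all_above` (TRUE iff every post-treatment sample is at or
#'   above target).
#' @export
amh_threshold_compliance <- function(series, target = 0.25, treatment_day = 0L) {
  series <- one_series(series)
  if (series$analyte[1] != "AMH_serum") {
    stop("contract error: expected an AMH_serum series, got ",
         series$analyte[1], call. = FALSE)
  }
  post <- series$value[series$day >= treatment_day]
  if (length(post) == 0) {
    stop("insufficient data: no post-treatment AMH samples", call. = FALSE)
  }
  list(
    fraction = mean(post >= target),
    all_above = all(post >= target)
  )
}

#' Sample-level detector performance against simulator ground truth
#'
#' Classifies each analysable sample (scheduled collection day outside
#' exclusions) as truth-positive when it falls inside a ground-truth window of
#' the given kind and call-positive when it falls inside a phase call, then
#' reports sensitivity and specificity. Truth windows containing fewer than
#' `min_run` analysable samples are undetectable by construction of the
#' run-length rule (e.g. windows truncated by the study end, or elevations
#' hidden inside pregnancy exclusions) and are masked out of the evaluation.
#'
#' @param calls phase-call tibble for one animal and phase type.
#' @param truth_windows tibble with `start_day`, `end_day` (half-open)
#'   ground-truth windows for the same animal.
#' @param sample_days analysable collection days for the animal.
#' @param min_run the run-length threshold used by the caller.
#' @return A list with `sensitivity`, `specificity` and the confusion counts
#'   (`tp`, `fp`, `tn`, `fn`); sensitivity is `NA` when no detectable truth
#'   samples exist.
#' @export
detector_performance <- function(calls, truth_windows, sample_days, min_run) {
  in_truth <- rep(FALSE, length(sample_days))
  masked <- rep(FALSE, length(sample_days))
  if (nrow(truth_windows) > 0) {
    for (i in seq_len(nrow(truth_windows))) {
      inside <- sample_days >= truth_windows$start_day[i] &
        sample_days < truth_windows$end_day[i]
      if (sum(inside) >= min_run) in_truth <- in_truth | inside
      else masked <- masked | inside
    }
  }
  in_call <- rep(FALSE, length(sample_days))
  if (nrow(calls) > 0) {
    for (i in seq_len(nrow(calls))) {
      in_call <- in_call |
        (sample_days >= calls$start_day[i] & sample_days <= calls$end_day[i])
    }
  }
  keep <- !masked
  tp <- sum(in_truth[keep] & in_call[keep])
  fn <- sum(in_truth[keep] & !in_call[keep])
  fp <- sum(!in_truth[keep] & in_call[keep])
  tn <- sum(!in_truth[keep] & !in_call[keep])
  list(
    sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

#' Cohort-level luteal/estrous detector validation
#'
#' Runs the full baseline + phase-calling pipeline on a simulated cohort and
#' pools the sample-level confusion counts across animals for the requested
#' phase type.
#'
#' @param cohort a `sim_cohort` from [simulate_cohort()].
#' @param phase_type `"estrous"` or `"luteal"`.
#' @param config an [analysis_config()].
#' @return As [detector_performance()], pooled over animals.
#' @export
validate_detector <- function(cohort, phase_type = c("luteal", "estrous"),
                              config = analysis_config()) {
  phase_type <- match.arg(phase_type)
  analyte <- if (phase_type == "estrous") "E2_fecal" else "P4_fecal"
  min_run <- if (phase_type == "estrous") config$estrous_min_run else
    config$luteal_min_run
  truth_tbl <- if (phase_type == "estrous") cohort$truth$estrus else
    cohort$truth$luteal
  window <- cohort$design$periods[[config$baseline_window]]

  tot <- c(tp = 0, fp = 0, tn = 0, fn = 0)
  for (a in cohort$design$groups$animal_id) {
    s <- cohort$hormones[cohort$hormones$animal_id == a &
                           cohort$hormones$analyte == analyte, , drop = FALSE]
    fit <- fit_baseline(s, window, k = config$baseline_k,
                        mode = config$baseline_mode,
                        exclusions = cohort$exclusions)
    calls <- call_phases(s, fit, phase_type = phase_type, min_run = min_run,
                         exclusions = cohort$exclusions)
    ex <- animal_exclusions(cohort$exclusions, a)
    days <- s$day[!day_excluded(s$day, ex)]
    tw <- truth_tbl[truth_tbl$animal_id == a, , drop = FALSE]
    perf <- detector_performance(calls, tw, days, min_run)
    tot <- tot + c(tp = perf$tp, fp = perf$fp, tn = perf$tn, fn = perf$fn)
  }
  list(
    sensitivity = if (tot[["tp"]] + tot[["fn"]] == 0) NA_real_ else
      tot[["tp"]] / (tot[["tp"]] + tot[["fn"]]),
    specificity = if (tot[["tn"]] + tot[["fp"]] == 0) NA_real_ else
      tot[["tn"]] / (tot[["tn"]] + tot[["fp"]]),
    tp = tot[["tp"]], fp = tot[["fp"]], tn = tot[["tn"]], fn = tot[["fn"]]
  )
}
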