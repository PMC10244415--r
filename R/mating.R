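#' Detect breeding bouts from a mating-event log
#'
#' A breeding bout is a maximal run of consecutive calendar days each
#' containing at least one confirmed breeding (intromission) event for the
#' female; breeding attempts never enter bout detection.
#'
#' @param events event tibble (day, female_id, male_id, event_type).
#' @param female_id optional single female; when `NULL`, bouts are detected
#'   for every female in the log.
#' @return A tibble (female_id, start_day, end_day, n_days); `end_day` is
#'   inclusive.
#' @export
detect_bouts <- function(events, female_id = NULL) {
  stopifnot(all(c("day", "female_id", "event_type") %in% names(events)))
  ev <- events[events$event_type == "breeding", , drop = FALSE]
  if (!is.null(female_id)) ev <- ev[ev$female_id == female_id, , drop = FALSE]
  empty <- tibble::tibble(female_id = character(), start_day = integer(),
                          end_day = integer(), n_days = integer())
  if (nrow(ev) == 0) return(empty)
  out <- list()
  for (f in unique(ev$female_id)) {
    days <- sort(unique(ev$day[ev$female_id == f]))
    run_id <- cumsum(c(1L, diff(days) > 1L))
    for (r in unique(run_id)) {
      d <- days[run_id == r]
      out[[length(out) + 1L]] <- tibble::tibble(
        female_id = f,
        start_day = as.integer(min(d)),
        end_day = as.integer(max(d)),
        n_days = as.integer(max(d) - min(d) + 1L)
      )
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$female_id, .data$start_day)
}

#' Link breeding bouts to subsequent luteal phases
#'
#' A bout is "followed by a luteal phase" when some luteal call starts
#' strictly after the bout's last day and no later than `max_lag_days` after
#' it. Each luteal call credits at most one bout — the nearest preceding one —
#' so two bouts cannot share a single luteal phase.
#'
#' @param bouts bout tibble from [detect_bouts()] for one female.
#' @param luteal_calls luteal phase-call tibble for the same female.
#' @param max_lag_days positive linkage window in days (default 21).
#' @return A list with `n_linked` (number of distinct bouts credited) and
#'   `links` (bout start/end with the luteal start day credited to it).
#' @export
link_luteal <- function(bouts, luteal_calls, max_lag_days = 21L) {
  if (max_lag_days <= 0) {
    stop("contract error: max_lag_days must be positive", call. = FALSE)
  }
  links <- tibble::tibble(bout_start = integer(), bout_end = integer(),
                          luteal_start = integer())
  if (nrow(bouts) == 0 || nrow(luteal_calls) == 0) {
    return(list(n_linked = 0L, links = links))
  }
  if ("phase_type" %in% names(luteal_calls) &&
      any(luteal_calls$phase_type != "luteal")) {
    stop("contract error: calls must be luteal phases", call. = FALSE)
  }
  credited <- rep(FALSE, nrow(bouts))
  rows <- list()
  for (i in order(luteal_calls$start_day)) {
    ls <- luteal_calls$start_day[i]
    cand <- which(bouts$end_day < ls & ls <= bouts$end_day + max_lag_days)
    if (length(cand) == 0) next
    j <- cand[which.max(bouts$end_day[cand])]
    if (!credited[j]) {
      credited[j] <- TRUE
      rows[[length(rows) + 1L]] <- tibble::tibble(
        bout_start = bouts$start_day[j], bout_end = bouts$end_day[j],
        luteal_start = as.integer(ls)
      )
    }
  }
  if (length(rows) > 0) links <- dplyr::bind_rows(rows)
  list(n_linked = sum(credited), links = links)
}

#' Chi-square goodness-of-fit test against a uniform null
#'
#' Tests observed per-group counts against the null hypothesis of a uniform
#' distribution across groups: expected count is `total / g` in every group,
#' the statistic is `sum((O - E)^2 / E)` on `g - 1` degrees of freedom, and
#' the p-value is the upper tail of the chi-square distribution. No
#' continuity correction is applied. With three groups the p-value has the
#' closed form `exp(-chi2 / 2)`.
#'
#' @param counts numeric vector of g >= 2 non-negative counts with a positive
#'   total.
#' @return A list with `statistic`, `df` and `p_value`.
#' @export
chisq_uniform <- function(counts) {
  stopifnot(is.numeric(counts), length(counts) >= 2, all(counts >= 0))
  total <- sum(counts)
  if (total <= 0) {
    stop("undefined test: total count is zero", call. = FALSE)
  }
  g <- length(counts)
  expected <- total / g
  statistic <- sum((counts - expected)^2 / expected)
  df <- g - 1L
  list(
    statistic = statistic,
    df = df,
    p_value = stats::pchisq(statistic, df = df, lower.tail = FALSE)
  )
}

#' Build the mating-trial summary table and uniform-null tests
#'
#' Aggregates, per treatment group and for one trial window: the number of
#' females that allowed breeding (had at least one bout), the total number of
#' breeding bouts, the number of luteal phases that followed a bout, the
#' number of pregnant females and the total kittens produced. Each count row
#' is then tested against a uniform distribution across groups with
#' [chisq_uniform()]; rows whose total is zero are reported with `NA`
#' statistics and a note rather than aborting.
#'
#' @param events mating-event log.
#' @param luteal_calls cohort luteal phase-call tibble.
#' @param pregnancies tibble (animal_id or female_id, conception_day,
#'   kittens); may be `NULL` when no pregnancy data exist.
#' @param design a [study_design()]; every female in `events` must appear in
#'   its group assignment.
#' @param trial_window half-open `c(start, end)` day interval of the trial.
#' @param max_lag_days bout-to-luteal linkage window (default 21).
#' @return A list of class `trial_table` with `table` (one row per group) and
#'   `tests` (metric, chi2, df, p_value, note).
#' @export
build_trial_table <- function(events, luteal_calls, pregnancies, design,
                              trial_window, max_lag_days = 21L) {
  stopifnot(inherits(design, "study_design"),
            length(trial_window) == 2L, trial_window[1] < trial_window[2])
  ev <- events[in_window(events$day, trial_window), , drop = FALSE]
  unknown <- setdiff(unique(ev$female_id), design$groups$animal_id)
  if (length(unknown) > 0) {
    stop("contract error: female(s) absent from study design: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(pregnancies) && nrow(pregnancies) > 0) {
    if ("female_id" %in% names(pregnancies) && !"animal_id" %in% names(pregnancies)) {
      names(pregnancies)[names(pregnancies) == "female_id"] <- "animal_id"
    }
    stopifnot(all(c("animal_id", "conception_day", "kittens") %in% names(pregnancies)))
    pregnancies <- pregnancies[in_window(pregnancies$conception_day, trial_window), ,
                               drop = FALSE]
  }

  group_names <- STUDY_GROUPS[STUDY_GROUPS %in% design$groups$group]
  rows <- list()
  for (g in group_names) {
    females <- design$groups$animal_id[design$groups$group == g]
    n_bred <- 0L; n_bouts <- 0L; n_linked <- 0L
    n_pregnant <- 0L; n_kittens <- 0L
    for (f in females) {
      b <- detect_bouts(ev, f)
      if (nrow(b) > 0) n_bred <- n_bred + 1L
      n_bouts <- n_bouts + nrow(b)
      lc <- luteal_calls[luteal_calls$animal_id == f &
                           luteal_calls$phase_type == "luteal", , drop = FALSE]
      n_linked <- n_linked + link_luteal(b, lc, max_lag_days)$n_linked
      if (!is.null(pregnancies) && nrow(pregnancies) > 0) {
        pf <- pregnancies[pregnancies$animal_id == f, , drop = FALSE]
        if (nrow(pf) > 0) n_pregnant <- n_pregnant + 1L
        n_kittens <- n_kittens + sum(pf$kittens)
      }
    }
    rows[[g]] <- tibble::tibble(
      group = g, n_females = length(females), n_females_bred = n_bred,
      n_bouts = n_bouts, n_luteal_after_bout = n_linked,
      n_pregnant = n_pregnant, n_kittens = as.integer(n_kittens)
    )
  }
  tab <- dplyr::bind_rows(rows)

  metrics <- c("n_females_bred", "n_bouts", "n_luteal_after_bout",
               "n_pregnant", "n_kittens")
  tests <- list()
  for (m in metrics) {
    counts <- tab[[m]]
    if (sum(counts) == 0) {
      tests[[m]] <- tibble::tibble(
        metric = m, statistic = NA_real_, df = length(counts) - 1L,
        p_value = NA_real_, note = "undefined: total count is zero"
      )
    } else {
      r <- chisq_uniform(counts)
      tests[[m]] <- tibble::tibble(
        metric = m, statistic = r$statistic, df = r$df,
        p_value = r$p_value, note = ""
      )
    }
  }

  structure(
    list(table = tab, tests = dplyr::bind_rows(tests),
         trial_window = trial_window, max_lag_days = as.integer(max_lag_days)),
    class = "trial_table"
  )
}

#' @export
print.trial_table <- function(x, ...) {
  cat(sprintf("<trial_table> trial window [%d, %d), bout->luteal lag %d d\n",
              x$trial_window[1], x$trial_window[2], x$max_lag_days))
  print(as.data.frame(x$table), row.names = FALSE)
  cat("uniform-null chi-square tests:\n")
  print(as.data.frame(x$tests), row.names = FALSE)
  invisible(x)
}
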