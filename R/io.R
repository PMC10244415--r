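#' Read a hormone concentration table
#'
#' Expects comma-separated text with header columns `animal_id`, `analyte`,
#' `day`, `value`, `units`. `day` is an integer offset from the treatment day
#' (day 0); `value` is a non-negative concentration. One row per collected
#' sample; missing collections are absent rows, never placeholders.
#'
#' @param path path to a CSV file.
#' @return A tibble sorted by (animal_id, analyte, day), one row per sample.
#'   Each (animal_id, analyte) combination is one hormone series.
#' @export
read_hormone_table <- function(path) {
  x <- read_checked_csv(
    path,
    cols = c("animal_id", "analyte", "day", "value", "units"),
    numeric_cols = c("day", "value")
  )
  bad <- setdiff(unique(x$analyte), ANALYTES)
  if (length(bad) > 0) {
    stop("validation error: unknown analyte(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(x$value < 0)) {
    i <- which(x$value < 0)[1]
    stop("validation error: negative concentration at data row ", i, call. = FALSE)
  }
  if (any(x$day != round(x$day))) {
    stop("validation error: non-integer collection day", call. = FALSE)
  }
  x$day <- as.integer(x$day)
  dup <- duplicated(x[, c("animal_id", "analyte", "day")])
  if (any(dup)) {
    d <- x[which(dup)[1], ]
    stop(sprintf(
      "validation error: duplicate sample for %s/%s on day %d",
      d$animal_id, d$analyte, d$day
    ), call. = FALSE)
  }
  dplyr::arrange(x, .data$animal_id, .data$analyte, .data$day)
}

#' Write a hormone concentration table
#' @param x tibble as returned by [read_hormone_table()].
#' @param path output CSV path.
#' @export
write_hormone_table <- function(x, path) {
  readr::write_csv(x[, c("animal_id", "analyte", "day", "value", "units")], path)
  invisible(path)
}

#' Read a mating-event log
#'
#' Comma-separated text with columns `day`, `female_id`, `male_id`,
#' `event_type`. Event types are `breeding` (confirmed intromission) or
#' `attempt`; attempts never enter bout detection.
#'
#' @param path path to a CSV file.
#' @return A tibble of events sorted by day.
#' @export
read_event_log <- function(path) {
  x <- read_checked_csv(
    path,
    cols = c("day", "female_id", "male_id", "event_type"),
    numeric_cols = "day"
  )
  bad <- setdiff(unique(x$event_type), c("breeding", "attempt"))
  if (length(bad) > 0) {
    stop("validation error: unknown event_type: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  x$day <- as.integer(x$day)
  dplyr::arrange(x, .data$day, .data$female_id)
}

#' Write a mating-event log
#' @param x tibble of events.
#' @param path output CSV path.
#' @export
write_event_log <- function(x, path) {
  readr::write_csv(x[, c("day", "female_id", "male_id", "event_type")], path)
  invisible(path)
}

#' Read per-animal exclusion intervals
#'
#' Columns `animal_id`, `start_day`, `end_day` (half-open), `reason`
#' (pregnancy, lactation, or collection_suspended). Samples falling in an
#' exclusion interval are removed from baseline fitting, phase calling and
#' frequency denominators.
#' @param path path to a CSV file.
#' @return A validated tibble of intervals.
#' @export
read_exclusions <- function(path) {
  x <- read_checked_csv(
    path,
    cols = c("animal_id", "start_day", "end_day", "reason"),
    numeric_cols = c("start_day", "end_day")
  )
  x$start_day <- as.integer(x$start_day)
  x$end_day <- as.integer(x$end_day)
  validate_exclusions(x)
}

#' Read an analysis configuration from a YAML file
#'
#' Flat key-value file whose keys mirror the arguments of
#' [analysis_config()]; unknown keys are rejected.
#' @param path path to a YAML (or plain `key: value`) file.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(y), known)
  if (length(bad) > 0) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(analysis_config, y)
}

#' Read a study design from a YAML file
#'
#' Expected keys: `groups` (mapping animal id -> group), `treatment_day`,
#' `periods` (mapping name -> [start, end) day pair) and optionally
#' `exclusions` (list of records with animal_id/start_day/end_day/reason).
#' @param path path to a YAML file.
#' @return A `study_design`.
#' @export
read_study_design <- function(path) {
  y <- yaml::read_yaml(path)
  stopifnot(!is.null(y$groups))
  groups <- tibble::tibble(
    animal_id = names(y$groups),
    group = unname(unlist(y$groups))
  )
  periods <- if (is.null(y$periods)) default_periods() else
    lapply(y$periods, function(p) as.numeric(unlist(p)))
  exclusions <- NULL
  if (!is.null(y$exclusions)) {
    exclusions <- dplyr::bind_rows(lapply(y$exclusions, tibble::as_tibble))
  }
  study_design(
    groups = groups,
    treatment_day = if (is.null(y$treatment_day)) 0L else as.integer(y$treatment_day),
    periods = periods,
    exclusions = exclusions
  )
}

# Shared CSV reader: checks header, reports malformed rows with their line
# number (header = line 1, first data row = line 2).
read_checked_csv <- function(path, cols, numeric_cols = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  ))
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    stop("parse error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- x[, cols]
  for (nc in numeric_cols) {
    v <- suppressWarnings(as.numeric(x[[nc]]))
    bad <- which(is.na(v) & !is.na(x[[nc]]) | is.na(x[[nc]]))
    if (length(bad) > 0) {
      stop(sprintf("parse error: malformed value in column '%s' at line %d of %s",
                   nc, bad[1] + 1L, path), call. = FALSE)
    }
    x[[nc]] <- v
  }
  tibble::as_tibble(x)
}

# restrict a hormone table to one (animal, analyte) series; errors otherwise
one_series <- function(series) {
  stopifnot(is.data.frame(series), all(c("animal_id", "analyte", "day", "value") %in% names(series)))
  if (nrow(series) == 0) stop("empty hormone series", call. = FALSE)
  if (length(unique(series$animal_id)) != 1L || length(unique(series$analyte)) != 1L) {
    stop("expected a single (animal_id, analyte) series", call. = FALSE)
  }
  if (is.unsorted(series$day, strictly = TRUE)) {
    series <- series[order(series$day), , drop = FALSE]
    if (anyDuplicated(series$day)) {
      stop("validation error: duplicate collection day in series", call. = FALSE)
    }
  }
  series
}
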