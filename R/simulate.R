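#' Simulator configuration for an induced-ovulator feline cohort
#'
#' Parameterizes a stochastic state-machine model of feline reproductive
#' cycling: estrus recurs as a renewal process (interestrous interval draw),
#' suspended while the animal is in a luteal, pregnant or lactating state.
#' Ovulation is mating-induced with high probability, or spontaneous with a
#' low per-estrus probability; ovulation starts a multi-week luteal phase with
#' sustained progestogen elevation, and conception leads to gestation and
#' lactation, during which sample collection is excluded from analysis.
#' Hormone kinetics are piecewise-constant fold-changes over a baseline with
#' multiplicative lognormal noise; fecal samples are drawn on three fixed
#' weekdays per week.
#'
#' Treatment-group effects (suppressed ovulation probability and reduced
#' luteal progestogen amplitude) act from day 0; before treatment every animal
#' follows the control parameters. An optional linear onset ramps the effect
#' in over `treatment_onset_days`.
#'
#' The spontaneous-ovulation probabilities default to a low-ovulating colony.
#' Colony rates vary widely in this species and the value is a modelling
#' choice; see the methods vignette for the identifiability argument behind
#' the default.
#'
#' @param n_per_group animals per group (control, low_dose, high_dose).
#' @param study_start,study_end half-open day range of the study relative to
#'   treatment at day 0.
#' @param sampling_weekdays integers in 0..6; a day `d` is a scheduled
#'   collection day when `d %% 7` is one of these.
#' @param e2_baseline,e2_sigma,e2_estrus_fold fecal estrogen metabolite
#'   baseline (ng/g dry feces), lognormal noise sdlog, and fold-elevation
#'   during estrus.
#' @param estrus_duration,interestrous_interval inclusive integer ranges
#'   (days) for estrus length and the interestrous interval.
#' @param p4_baseline,p4_sigma fecal progestogen metabolite baseline (ng/g)
#'   and lognormal noise sdlog.
#' @param p4_luteal_fold named per-group fold-elevation of P4 during luteal
#'   and pregnancy windows.
#' @param luteal_duration inclusive range (days) of the non-pregnant luteal
#'   phase.
#' @param gestation_days,lactation_days fixed gestation and lactation lengths.
#' @param p_ovulation_given_mating named per-group probability that a mated
#'   estrus ovulates.
#' @param p_spontaneous_ovulation named per-group probability that an unmated
#'   estrus ovulates.
#' @param p_conception probability of conception given ovulation with mating.
#' @param trial_windows list of half-open day intervals during which a male is
#'   present and mating can occur.
#' @param p_mating_bout named per-group probability that an estrus overlapping
#'   a trial window produces a breeding bout.
#' @param bout_length inclusive range (days) of a breeding bout.
#' @param litter_size inclusive range of kittens per completed pregnancy.
#' @param p_attempt_only probability that a trial-window estrus without a bout
#'   still produces a recorded breeding attempt.
#' @param treatment_onset_days 0 for a step effect at day 0, or a positive
#'   ramp length.
#' @param suspend_windows list of half-open day intervals with collection
#'   suspended for the whole colony.
#' @param master_seed integer master seed; per-animal substreams are derived
#'   from it and the animal index, so enlarging the cohort does not reshuffle
#'   existing animals.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 3L,
                       study_start = -180L,
                       study_end = 720L,
                       sampling_weekdays = c(0L, 2L, 4L),
                       e2_baseline = 20,
                       e2_sigma = 0.15,
                       e2_estrus_fold = 6,
                       estrus_duration = c(5L, 7L),
                       interestrous_interval = c(14L, 21L),
                       p4_baseline = 500,
                       p4_sigma = 0.15,
                       p4_luteal_fold = c(control = 8, low_dose = 5, high_dose = 4),
                       luteal_duration = c(30L, 45L),
                       gestation_days = 65L,
                       lactation_days = 56L,
                       p_ovulation_given_mating = c(control = 0.9, low_dose = 0.1, high_dose = 0.05),
                       p_spontaneous_ovulation = c(control = 0.02, low_dose = 0.01, high_dose = 0.005),
                       p_conception = 0.85,
                       trial_windows = list(trial1 = c(240L, 360L), trial2 = c(600L, 720L)),
                       p_mating_bout = c(control = 0.8, low_dose = 0.35, high_dose = 0.15),
                       bout_length = c(1L, 4L),
                       litter_size = c(2L, 4L),
                       p_attempt_only = 0.3,
                       treatment_onset_days = 0L,
                       suspend_windows = list(),
                       master_seed = 1L) {
  cfg <- as.list(environment())
  for (p in list(cfg$p_ovulation_given_mating, cfg$p_spontaneous_ovulation,
                 cfg$p_mating_bout)) {
    stopifnot(all(STUDY_GROUPS %in% names(p)), all(p >= 0 & p <= 1))
  }
  stopifnot(
    n_per_group >= 1, study_start < study_end,
    all(sampling_weekdays %in% 0:6), length(sampling_weekdays) >= 1,
    e2_sigma >= 0, p4_sigma >= 0, e2_estrus_fold > 1,
    all(STUDY_GROUPS %in% names(p4_luteal_fold)), all(p4_luteal_fold > 1),
    estrus_duration[1] >= 1, estrus_duration[1] <= estrus_duration[2],
    interestrous_interval[1] >= 1,
    luteal_duration[1] >= 1, gestation_days > 0, lactation_days > 0,
    p_conception >= 0, p_conception <= 1,
    p_attempt_only >= 0, p_attempt_only <= 1,
    treatment_onset_days >= 0
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d animals/group over days [%d, %d); %d samples/week\n",
              x$n_per_group, x$study_start, x$study_end,
              length(x$sampling_weekdays)))
  cat(sprintf("  E2: %g ng/g x%g in estrus (sdlog %g); P4: %g ng/g, luteal fold %s (sdlog %g)\n",
              x$e2_baseline, x$e2_estrus_fold, x$e2_sigma, x$p4_baseline,
              paste(x$p4_luteal_fold, collapse = "/"), x$p4_sigma))
  cat(sprintf("  master seed %d\n", x$master_seed))
  invisible(x)
}

#' Scheduled fecal-collection days
#'
#' @param start,end half-open day range.
#' @param weekdays integers in 0..6 selecting collection days by `day %% 7`.
#' @return Integer vector of scheduled days.
#' @export
sampling_schedule <- function(start, end, weekdays = c(0L, 2L, 4L)) {
  d <- seq.int(start, end - 1L)
  d[(d %% 7L) %in% weekdays]
}

derive_seed <- function(master_seed, animal_index) {
  as.integer((as.numeric(master_seed) + 1000003 * animal_index) %% 2147483647)
}

draw_int <- function(range) {
  if (range[1] >= range[2]) return(as.integer(range[1]))
  sample.int(range[2] - range[1] + 1L, 1L) + as.integer(range[1]) - 1L
}

# effective per-group parameter at a given day: control value before day 0,
# group value afterwards, optionally linearly ramped over the onset window
effective_param <- function(p, group, day, onset) {
  w <- if (day < 0) 0 else if (onset <= 0) 1 else min(1, day / onset)
  (1 - w) * p[["control"]] + w * p[[group]]
}

#' Simulate a feline estrous-cycle cohort
#'
#' Runs the per-animal state machine described in [sim_config()] and generates
#' thrice-weekly fecal E2 and P4 metabolite series, a mating-event log,
#' per-animal exclusion intervals exactly covering pregnancy and lactation,
#' and the ground-truth event windows needed to validate the phase detectors.
#'
#' Each animal consumes an independent RNG substream derived from
#' `master_seed` and its index, so the same configuration and seed reproduce
#' the same cohort, and extending the cohort leaves existing animals
#' unchanged. The global RNG state is restored on exit.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_cohort` with elements `hormones`, `events`,
#'   `exclusions`, `truth` (a `sim_truth` list of event tables:
#'   `estrus`, `ovulations`, `luteal`, `pregnancies`, `lactation`, `matings`)
#'   and `design` (a ready-made [study_design()] for the cohort).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)

  ids <- character(0)
  groups <- character(0)
  prefix <- c(control = "C", low_dose = "L", high_dose = "H")
  for (g in STUDY_GROUPS) {
    ids <- c(ids, sprintf("%s%d", prefix[[g]], seq_len(config$n_per_group)))
    groups <- c(groups, rep(g, config$n_per_group))
  }

  per_animal <- lapply(seq_along(ids), function(i) {
    simulate_animal(ids[i], groups[i], i, config)
  })

  hormones <- dplyr::bind_rows(lapply(per_animal, `[[`, "hormones"))
  events <- dplyr::bind_rows(lapply(per_animal, `[[`, "events"))
  if (nrow(events) == 0) {
    events <- tibble::tibble(day = integer(), female_id = character(),
                             male_id = character(), event_type = character())
  } else {
    events <- dplyr::arrange(events, .data$day, .data$female_id)
  }
  exclusions <- dplyr::bind_rows(lapply(per_animal, `[[`, "exclusions"))
  if (nrow(exclusions) == 0) {
    exclusions <- tibble::tibble(animal_id = character(), start_day = integer(),
                                 end_day = integer(), reason = character())
  }

  truth <- structure(list(
    estrus = bind_truth(per_animal, "estrus",
                        c(animal_id = "character", start_day = "integer", end_day = "integer")),
    ovulations = bind_truth(per_animal, "ovulations",
                            c(animal_id = "character", day = "integer", cause = "character")),
    luteal = bind_truth(per_animal, "luteal",
                        c(animal_id = "character", start_day = "integer", end_day = "integer")),
    pregnancies = bind_truth(per_animal, "pregnancies",
                             c(animal_id = "character", conception_day = "integer",
                               start_day = "integer", end_day = "integer",
                               birth_day = "integer", kittens = "integer")),
    lactation = bind_truth(per_animal, "lactation",
                           c(animal_id = "character", start_day = "integer", end_day = "integer")),
    matings = bind_truth(per_animal, "matings",
                         c(animal_id = "character", day = "integer"))
  ), class = "sim_truth")

  design <- study_design(
    groups = tibble::tibble(animal_id = ids, group = groups),
    treatment_day = 0L,
    periods = default_periods(),
    exclusions = exclusions
  )

  structure(
    list(hormones = hormones, events = events, exclusions = exclusions,
         truth = truth, design = design, config = config),
    class = "sim_cohort"
  )
}

bind_truth <- function(per_animal, what, proto) {
  rows <- dplyr::bind_rows(lapply(per_animal, function(a) a$truth[[what]]))
  if (nrow(rows) > 0) return(rows)
  cols <- lapply(proto, function(tp) vector(tp, 0L))
  names(cols) <- names(proto)
  tibble::as_tibble(cols)
}

simulate_animal <- function(animal_id, group, animal_index, cfg) {
  set.seed(derive_seed(cfg$master_seed, animal_index))
  end <- cfg$study_end

  estrus <- list(); ovul <- list(); luteal <- list()
  preg <- list(); lact <- list(); bouts <- list(); attempts <- integer(0)

  trial_of_day <- function(d) {
    for (i in seq_along(cfg$trial_windows)) {
      tw <- cfg$trial_windows[[i]]
      if (d >= tw[1] && d < tw[2]) return(i)
    }
    0L
  }

  day <- cfg$study_start + draw_int(cfg$interestrous_interval)
  while (day < end) {
    dur <- draw_int(cfg$estrus_duration)
    e_start <- day
    estrus[[length(estrus) + 1L]] <- c(e_start, min(e_start + dur, end))

    # mating: at most one bout per estrus, inside estrus x trial-window days
    bout_days <- integer(0)
    ov_s <- ov_e <- NA_integer_
    for (tw in cfg$trial_windows) {
      s <- max(e_start, tw[1]); e <- min(e_start + dur, tw[2], end)
      if (s < e) { ov_s <- s; ov_e <- e; break }
    }
    if (!is.na(ov_s)) {
      if (stats::runif(1) < effective_param(cfg$p_mating_bout, group, e_start,
                                            cfg$treatment_onset_days)) {
        blen <- min(draw_int(cfg$bout_length), ov_e - ov_s)
        b_start <- ov_s + sample.int(ov_e - ov_s - blen + 1L, 1L) - 1L
        bout_days <- seq.int(b_start, b_start + blen - 1L)
        bouts[[length(bouts) + 1L]] <- bout_days
      } else if (stats::runif(1) < cfg$p_attempt_only) {
        attempts <- c(attempts, ov_s)
      }
    }
    mated <- length(bout_days) > 0

    # ovulation: induced ~2 days after the last coital act, or spontaneous at
    # the end of estrus
    ov_day <- if (mated) max(bout_days) + 2L else e_start + dur
    p_ov <- if (mated) {
      effective_param(cfg$p_ovulation_given_mating, group, ov_day,
                      cfg$treatment_onset_days)
    } else {
      effective_param(cfg$p_spontaneous_ovulation, group, ov_day,
                      cfg$treatment_onset_days)
    }
    ovulates <- (stats::runif(1) < p_ov) && ov_day < end

    day <- e_start + dur
    if (ovulates) {
      cause <- if (mated) "induced" else "spontaneous"
      ovul[[length(ovul) + 1L]] <- list(day = ov_day, cause = cause)
      ldur <- draw_int(cfg$luteal_duration)
      luteal[[length(luteal) + 1L]] <- c(ov_day, min(ov_day + ldur, end))
      conceives <- mated && stats::runif(1) < cfg$p_conception
      if (conceives) {
        birth <- ov_day + cfg$gestation_days
        preg[[length(preg) + 1L]] <- list(
          conception_day = ov_day,
          start_day = ov_day,
          end_day = min(birth, end),
          birth_day = if (birth < end) birth else NA_integer_,
          kittens = if (birth < end) draw_int(cfg$litter_size) else 0L
        )
        if (birth < end) {
          lact[[length(lact) + 1L]] <- c(birth, min(birth + cfg$lactation_days, end))
        }
        day <- birth + cfg$lactation_days
      } else {
        day <- ov_day + ldur
      }
    }
    day <- day + draw_int(cfg$interestrous_interval)
  }

  # ---- hormone series on the sampling schedule ------------------------------
  sched <- sampling_schedule(cfg$study_start, end, cfg$sampling_weekdays)
  if (length(cfg$suspend_windows) > 0) {
    susp <- tibble::tibble(
      start_day = vapply(cfg$suspend_windows, `[`, numeric(1), 1),
      end_day = vapply(cfg$suspend_windows, `[`, numeric(1), 2)
    )
    sched <- sched[!day_excluded(sched, susp)]
  }

  in_any <- function(d, wins) {
    if (length(wins) == 0) return(rep(FALSE, length(d)))
    out <- rep(FALSE, length(d))
    for (w in wins) out <- out | (d >= w[1] & d < w[2])
    out
  }
  estrus_w <- estrus
  luteal_w <- luteal
  preg_w <- lapply(preg, function(p) c(p$start_day, p$end_day))

  e2_level <- cfg$e2_baseline * ifelse(in_any(sched, estrus_w), cfg$e2_estrus_fold, 1)
  p4_fold <- vapply(sched, function(d) {
    effective_param(cfg$p4_luteal_fold, group, d, cfg$treatment_onset_days)
  }, numeric(1))
  p4_level <- cfg$p4_baseline *
    ifelse(in_any(sched, luteal_w) | in_any(sched, preg_w), p4_fold, 1)

  noise <- function(n, sigma) {
    if (sigma == 0) rep(1, n) else exp(stats::rnorm(n, 0, sigma) - sigma^2 / 2)
  }
  e2_val <- e2_level * noise(length(sched), cfg$e2_sigma)
  p4_val <- p4_level * noise(length(sched), cfg$p4_sigma)

  hormones <- tibble::tibble(
    animal_id = animal_id,
    analyte = rep(c("E2_fecal", "P4_fecal"), each = length(sched)),
    day = rep(as.integer(sched), 2L),
    value = c(e2_val, p4_val),
    units = "ng/g"
  )

  # ---- mating-event log -----------------------------------------------------
  ev <- list()
  for (bd in bouts) {
    male <- sprintf("M%d", max(1L, trial_of_day(bd[1])))
    ev[[length(ev) + 1L]] <- tibble::tibble(
      day = as.integer(bd), female_id = animal_id, male_id = male,
      event_type = "breeding"
    )
  }
  for (ad in attempts) {
    male <- sprintf("M%d", max(1L, trial_of_day(ad)))
    ev[[length(ev) + 1L]] <- tibble::tibble(
      day = as.integer(ad), female_id = animal_id, male_id = male,
      event_type = "attempt"
    )
  }
  events <- if (length(ev) > 0) dplyr::bind_rows(ev) else
    tibble::tibble(day = integer(), female_id = character(),
                   male_id = character(), event_type = character())

  # ---- exclusions exactly cover pregnancy + lactation -----------------------
  excl <- list()
  for (p in preg) {
    excl[[length(excl) + 1L]] <- tibble::tibble(
      animal_id = animal_id, start_day = as.integer(p$start_day),
      end_day = as.integer(p$end_day), reason = "pregnancy"
    )
  }
  for (lw in lact) {
    excl[[length(excl) + 1L]] <- tibble::tibble(
      animal_id = animal_id, start_day = as.integer(lw[1]),
      end_day = as.integer(lw[2]), reason = "lactation"
    )
  }
  exclusions <- if (length(excl) > 0) dplyr::bind_rows(excl) else
    tibble::tibble(animal_id = character(), start_day = integer(),
                   end_day = integer(), reason = character())

  win_tbl <- function(wins) {
    if (length(wins) == 0) {
      return(tibble::tibble(animal_id = character(), start_day = integer(),
                            end_day = integer()))
    }
    tibble::tibble(
      animal_id = animal_id,
      start_day = vapply(wins, function(w) as.integer(w[1]), integer(1)),
      end_day = vapply(wins, function(w) as.integer(w[2]), integer(1))
    )
  }

  truth <- list(
    estrus = win_tbl(estrus_w),
    ovulations = if (length(ovul) > 0) tibble::tibble(
      animal_id = animal_id,
      day = vapply(ovul, function(o) as.integer(o$day), integer(1)),
      cause = vapply(ovul, function(o) o$cause, character(1))
    ) else tibble::tibble(animal_id = character(), day = integer(),
                          cause = character()),
    luteal = win_tbl(luteal_w),
    pregnancies = if (length(preg) > 0) tibble::tibble(
      animal_id = animal_id,
      conception_day = vapply(preg, function(p) as.integer(p$conception_day), integer(1)),
      start_day = vapply(preg, function(p) as.integer(p$start_day), integer(1)),
      end_day = vapply(preg, function(p) as.integer(p$end_day), integer(1)),
      birth_day = vapply(preg, function(p) as.integer(p$birth_day), integer(1)),
      kittens = vapply(preg, function(p) as.integer(p$kittens), integer(1))
    ) else tibble::tibble(animal_id = character(), conception_day = integer(),
                          start_day = integer(), end_day = integer(),
                          birth_day = integer(), kittens = integer()),
    lactation = win_tbl(lact),
    matings = if (length(bouts) > 0) tibble::tibble(
      animal_id = animal_id,
      day = as.integer(unlist(bouts))
    ) else tibble::tibble(animal_id = character(), day = integer())
  )

  list(hormones = hormones, events = events, exclusions = exclusions,
       truth = truth)
}

#' Count ground-truth phases starting in a window
#'
#' An event is counted when its start day lies in the half-open `window`.
#'
#' @param truth a `sim_truth` (element `truth` of [simulate_cohort()]).
#' @param window half-open `c(start, end)` day interval.
#' @return A tibble with one row per animal appearing in the truth tables and
#'   columns `n_estrus`, `n_luteal`.
#' @export
truth_phase_counts <- function(truth, window) {
  stopifnot(inherits(truth, "sim_truth"), length(window) == 2L,
            window[1] < window[2])
  animals <- sort(unique(c(truth$estrus$animal_id, truth$luteal$animal_id)))
  count_in <- function(tbl, a) {
    sum(tbl$animal_id == a & in_window(tbl$start_day, window))
  }
  tibble::tibble(
    animal_id = animals,
    n_estrus = vapply(animals, function(a) count_in(truth$estrus, a),
                      integer(1), USE.NAMES = FALSE),
    n_luteal = vapply(animals, function(a) count_in(truth$luteal, a),
                      integer(1), USE.NAMES = FALSE)
  )
}

#' Write a simulated cohort to CSV files
#'
#' Writes `hormones.csv`, `events.csv`, `exclusions.csv`, `pregnancies.csv`
#' and a long-format `truth.csv` (animal_id, kind, start_day, end_day,
#' detail).
#'
#' @param cohort a `sim_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_hormone_table(cohort$hormones, file.path(dir, "hormones.csv"))
  write_event_log(cohort$events, file.path(dir, "events.csv"))
  readr::write_csv(cohort$exclusions, file.path(dir, "exclusions.csv"))
  readr::write_csv(cohort$truth$pregnancies, file.path(dir, "pregnancies.csv"))

  tr <- cohort$truth
  long <- dplyr::bind_rows(
    dplyr::mutate(tr$estrus, kind = "estrus", detail = NA_character_),
    tibble::tibble(animal_id = tr$ovulations$animal_id, kind = "ovulation",
                   start_day = tr$ovulations$day, end_day = tr$ovulations$day,
                   detail = tr$ovulations$cause),
    dplyr::mutate(tr$luteal, kind = "luteal", detail = NA_character_),
    tibble::tibble(animal_id = tr$pregnancies$animal_id, kind = "pregnancy",
                   start_day = tr$pregnancies$start_day,
                   end_day = tr$pregnancies$end_day,
                   detail = as.character(tr$pregnancies$kittens)),
    dplyr::mutate(tr$lactation, kind = "lactation", detail = NA_character_)
  )
  long <- long[, c("animal_id", "kind", "start_day", "end_day", "detail")]
  readr::write_csv(dplyr::arrange(long, .data$animal_id, .data$start_day, .data$kind),
                   file.path(dir, "truth.csv"))
  invisible(dir)
}
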