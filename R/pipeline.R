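#' Run the full longitudinal analysis pipeline
#'
#' Ties the stages together: read inputs, fit per-animal iterative baselines
#' on the baseline window, call estrous (E2) and luteal (P4) phases, tabulate
#' normalized phase frequencies per period, run the period comparisons
#' (randomized-complete-block ANOVA with Tukey contrasts on phase
#' frequencies; log-scale t tests on metabolite concentrations), build the
#' mating-trial table per trial window and test each count row against a
#' uniform null. All results are written as CSV into `out_dir`, together with
#' a run log recording the configuration, seed and package version. Outputs
#' are written only after every stage has completed, so a failed run leaves
#' no partial tables.
#'
#' @param config an [analysis_config()].
#' @param design a [study_design()] (its exclusion intervals are used
#'   throughout).
#' @param hormones hormone table or path to a hormones CSV.
#' @param events mating-event tibble or path to an events CSV.
#' @param out_dir output directory, created if needed.
#' @param pregnancies optional pregnancy table (animal_id/female_id,
#'   conception_day, kittens) or path; without it the pregnancy and kitten
#'   rows of the trial table are zero.
#' @param trial_windows named list of half-open day intervals, one per mating
#'   trial.
#' @return Invisibly, a list with all computed objects (`baselines`,
#'   `phases`, `frequencies`, `period_stats`, `trials`) and the output paths.
#' @export
run_pipeline <- function(config, design, hormones, events, out_dir,
                         pregnancies = NULL,
                         trial_windows = list(trial1 = c(240L, 360L),
                                              trial2 = c(600L, 720L))) {
  stopifnot(inherits(config, "analysis_config"), inherits(design, "study_design"))
  set.seed(config$rng_seed)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  note("estrocycle pipeline run")
  note("package version: %s", as.character(utils::packageVersion("estrocycle")))
  note("seed: %d", config$rng_seed)
  note("config: k=%g mode=%s estrous_min_run=%d luteal_min_run=%d norm=%d/%d baseline_window=%s max_lag_days=%d",
       config$baseline_k, config$baseline_mode, config$estrous_min_run,
       config$luteal_min_run, config$estrous_norm_days, config$luteal_norm_days,
       config$baseline_window, config$max_lag_days)

  hormones <- stage("read_hormones", {
    if (is.character(hormones)) read_hormone_table(hormones) else
      tibble::as_tibble(hormones)
  })
  events <- stage("read_events", {
    if (is.character(events)) read_event_log(events) else
      tibble::as_tibble(events)
  })
  if (is.character(pregnancies)) {
    pregnancies <- stage("read_pregnancies", {
      readr::read_csv(pregnancies, show_col_types = FALSE, progress = FALSE)
    })
  }
  note("inputs: %d hormone samples (%d series), %d mating events, %d exclusion intervals",
       nrow(hormones), nrow(dplyr::distinct(hormones[, c("animal_id", "analyte")])),
       nrow(events), nrow(design$exclusions))

  baseline_window <- design$periods[[config$baseline_window]]
  if (is.null(baseline_window)) {
    stop("pipeline stage 'baseline' failed: baseline window '",
         config$baseline_window, "' is not a study period", call. = FALSE)
  }

  baselines <- stage("baseline", fit_baselines(
    hormones, baseline_window, k = config$baseline_k,
    mode = config$baseline_mode, exclusions = design$exclusions
  ))
  note("baseline: fitted %d series", nrow(baselines))

  phases <- stage("phases", call_phases_cohort(
    hormones, baselines, config = config, exclusions = design$exclusions
  ))
  note("phases: %d calls (%d estrous, %d luteal)", nrow(phases),
       sum(phases$phase_type == "estrous"), sum(phases$phase_type == "luteal"))

  frequencies <- stage("frequencies", phase_frequency_table(
    phases, design, config = config
  ))

  period_stats <- stage("periods", {
    out <- list()
    for (pt in c("estrous", "luteal")) {
      sub <- frequencies[frequencies$phase_type == pt, , drop = FALSE]
      samp <- tibble::tibble(
        animal_id = sub$animal_id, group = sub$group,
        period = sub$period, value = sub$normalized
      )
      res <- withCallingHandlers(
        rcb_anova_tukey(samp),
        warning = function(w) invokeRestart("muffleWarning")
      )
      a <- res$anova
      a$analysis <- paste0(pt, "_frequency_rcb_anova")
      a$contrast <- NA_character_
      out[[length(out) + 1L]] <- a[, c("analysis", "term", "contrast", "df",
                                       "sumsq", "meansq", "statistic", "p_value")]
      tk <- res$tukey
      out[[length(out) + 1L]] <- tibble::tibble(
        analysis = paste0(pt, "_frequency_tukey"),
        term = "cell_means",
        contrast = paste(tk$cell_1, "vs", tk$cell_2),
        df = NA_integer_, sumsq = NA_real_, meansq = NA_real_,
        statistic = tk$diff, p_value = tk$p_adj
      )
    }
    for (an in c("E2_fecal", "P4_fecal")) {
      samples <- collect_period_samples(hormones, design, an,
                                        aggregate = "none")
      for (g in unique(samples$group)) {
        pre <- samples$value[samples$group == g & samples$period == "pre_treatment"]
        post <- samples$value[samples$group == g & samples$period == "post_treatment"]
        row <- tryCatch({
          tt <- log_t_test(pre, post)
          tibble::tibble(
            analysis = paste0(an, "_log_t_test"), term = g,
            contrast = "pre_treatment vs post_treatment",
            df = as.integer(tt$df), sumsq = NA_real_, meansq = NA_real_,
            statistic = tt$statistic, p_value = tt$p_value
          )
        }, error = function(e) {
          tibble::tibble(
            analysis = paste0(an, "_log_t_test"), term = g,
            contrast = paste("skipped:", conditionMessage(e)),
            df = NA_integer_, sumsq = NA_real_, meansq = NA_real_,
            statistic = NA_real_, p_value = NA_real_
          )
        })
        out[[length(out) + 1L]] <- row
      }
    }
    dplyr::bind_rows(out)
  })

  trials <- stage("trial", {
    luteal_calls <- phases[phases$phase_type == "luteal", , drop = FALSE]
    lapply(trial_windows, function(tw) {
      build_trial_table(events, luteal_calls, pregnancies, design, tw,
                        max_lag_days = config$max_lag_days)
    })
  })

  trial_table <- dplyr::bind_rows(lapply(names(trials), function(nm) {
    x <- trials[[nm]]$table
    x$trial <- nm
    x[, c("trial", setdiff(names(x), "trial"))]
  }))
  trial_tests <- dplyr::bind_rows(lapply(names(trials), function(nm) {
    x <- trials[[nm]]$tests
    x$trial <- nm
    x$max_lag_days <- trials[[nm]]$max_lag_days
    x[, c("trial", setdiff(names(x), "trial"))]
  }))
  note("trials: %d window(s); %d trial-test rows", length(trials),
       nrow(trial_tests))

  stage("write", {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(baselines[, setdiff(names(baselines), "fit")],
                     file.path(out_dir, "baselines.csv"))
    readr::write_csv(phases, file.path(out_dir, "phases.csv"))
    readr::write_csv(frequencies, file.path(out_dir, "frequencies.csv"))
    readr::write_csv(period_stats, file.path(out_dir, "period_stats.csv"))
    readr::write_csv(trial_table, file.path(out_dir, "trial_table.csv"))
    readr::write_csv(trial_tests, file.path(out_dir, "trial_tests.csv"))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  })

  invisible(list(
    baselines = baselines, phases = phases, frequencies = frequencies,
    period_stats = period_stats, trials = trials,
    out_dir = out_dir,
    files = file.path(out_dir, c("baselines.csv", "phases.csv",
                                 "frequencies.csv", "period_stats.csv",
                                 "trial_table.csv", "trial_tests.csv"))
  ))
}
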