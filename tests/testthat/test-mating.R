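mk_events <- function(days, female = "C1", type = "breeding") {
  tibble::tibble(day = as.integer(days), female_id = female, male_id = "M1",
                 event_type = type)
}

mk_luteal <- function(starts, female = "C1") {
  tibble::tibble(
    animal_id = female, phase_type = "luteal",
    start_day = as.integer(starts), end_day = as.integer(starts) + 30L,
    n_samples = 12L, peak_value = 5
  )
}

test_that("breeding bouts are maximal runs of consecutive breeding days", {
  b <- detect_bouts(mk_events(c(5, 6, 7)))
  expect_equal(nrow(b), 1)
  expect_equal(b$start_day, 5)
  expect_equal(b$end_day, 7)
  expect_equal(b$n_days, 3)

  b2 <- detect_bouts(mk_events(c(5, 7)))
  expect_equal(nrow(b2), 2)
  expect_equal(b2$n_days, c(1, 1))

  # attempts never form bouts; repeated events within a day count once
  expect_equal(nrow(detect_bouts(mk_events(c(5, 6), type = "attempt"))), 0)
  b3 <- detect_bouts(mk_events(c(5, 5, 6)))
  expect_equal(nrow(b3), 1)
  expect_equal(b3$n_days, 2)
})

test_that("bout maximality and disjointness hold on random event logs", {
  withr::local_seed(303)
  for (rep in 1:40) {
    days <- sort(sample(1:120, sample(1:40, 1)))
    b <- detect_bouts(mk_events(days))
    expect_equal(sum(b$n_days), length(unique(days)))
    for (i in seq_len(nrow(b))) {
      run <- b$start_day[i]:b$end_day[i]
      expect_true(all(run %in% days))
      expect_false((b$start_day[i] - 1) %in% days)
      expect_false((b$end_day[i] + 1) %in% days)
    }
    if (nrow(b) > 1) expect_true(all(b$start_day[-1] > b$end_day[-nrow(b)] + 1))
  }
})

test_that("bout-to-luteal linkage respects the lag window and credits once", {
  bout <- detect_bouts(mk_events(c(8, 9, 10)))
  expect_equal(link_luteal(bout, mk_luteal(15), 21)$n_linked, 1)
  expect_equal(link_luteal(bout, mk_luteal(40), 21)$n_linked, 0)
  expect_equal(link_luteal(bout, mk_luteal(integer(0)), 21)$n_linked, 0)
  # start must be strictly after the bout and within end + lag (inclusive)
  expect_equal(link_luteal(bout, mk_luteal(10), 21)$n_linked, 0)
  expect_equal(link_luteal(bout, mk_luteal(31), 21)$n_linked, 1)
  expect_equal(link_luteal(bout, mk_luteal(32), 21)$n_linked, 0)

  # a luteal phase between two bouts credits only the nearest preceding bout
  bouts2 <- detect_bouts(mk_events(c(5, 20)))
  r <- link_luteal(bouts2, mk_luteal(25), 21)
  expect_equal(r$n_linked, 1)
  expect_equal(r$links$bout_start, 20)

  # two luteal phases cannot double-credit one bout
  r2 <- link_luteal(bout, mk_luteal(c(15, 20)), 21)
  expect_equal(r2$n_linked, 1)

  expect_error(link_luteal(bout, mk_luteal(15), 0), "contract")
})

test_that("uniform-null chi-square matches closed forms and invariances", {
  r <- chisq_uniform(c(1, 1, 1))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  r2 <- chisq_uniform(c(3, 0, 0))
  expect_equal(r2$statistic, 6)
  expect_equal(r2$df, 2)
  expect_equal(r2$p_value, exp(-3), tolerance = 1e-12)

  r3 <- chisq_uniform(c(10, 0, 0))
  expect_equal(r3$statistic, 20)
  expect_equal(r3$p_value, exp(-10), tolerance = 1e-12)

  expect_error(chisq_uniform(c(0, 0, 0)), "undefined")
  expect_error(chisq_uniform(5), "length")

  withr::local_seed(404)
  for (rep in 1:25) {
    counts <- rpois(sample(2:6, 1), 4) + c(1, rep(0, 0))
    if (sum(counts) == 0) counts[1] <- 1
    base <- chisq_uniform(counts)
    # permutation invariance
    perm <- chisq_uniform(sample(counts))
    expect_equal(perm$statistic, base$statistic, tolerance = 1e-12)
    expect_equal(perm$p_value, base$p_value, tolerance = 1e-12)
    # integer scaling multiplies the statistic by the scale
    sc <- chisq_uniform(counts * 3)
    expect_equal(sc$statistic, 3 * base$statistic, tolerance = 1e-12)
    # df = 2 closed form
    if (length(counts) == 3) {
      expect_equal(base$p_value, exp(-base$statistic / 2), tolerance = 1e-12)
    }
  }
})

table1_fixture <- function() {
  # trial-like fixture: 3 control females each with one bout followed by a
  # luteal phase and a pregnancy; one low-dose female with 6 bouts and one
  # high-dose female with 1 bout, none followed by luteal activity
  design <- study_design(c(
    C1 = "control", C2 = "control", C3 = "control",
    L1 = "low_dose", L2 = "low_dose", L3 = "low_dose",
    H1 = "high_dose", H2 = "high_dose", H3 = "high_dose"
  ))
  events <- dplyr::bind_rows(
    mk_events(250:251, "C1"), mk_events(260, "C2"), mk_events(270:272, "C3"),
    mk_events(c(245, 250, 255, 260, 265, 270), "L1"),
    mk_events(258, "H1"),
    mk_events(280, "L2", type = "attempt")
  )
  luteal <- dplyr::bind_rows(
    mk_luteal(255, "C1"), mk_luteal(263, "C2"), mk_luteal(275, "C3")
  )
  pregnancies <- tibble::tibble(
    animal_id = c("C1", "C2", "C3"),
    conception_day = c(253L, 262L, 274L),
    kittens = c(4L, 3L, 3L)
  )
  list(design = design, events = events, luteal = luteal,
       pregnancies = pregnancies)
}

test_that("the trial table reproduces the study-style count layout", {
  fx <- table1_fixture()
  tt <- build_trial_table(fx$events, fx$luteal, fx$pregnancies, fx$design,
                          trial_window = c(240, 360))
  tab <- tt$table
  expect_equal(tab$group, c("control", "low_dose", "high_dose"))
  expect_equal(tab$n_females_bred, c(3, 1, 1))
  expect_equal(tab$n_bouts, c(3, 6, 1))
  expect_equal(tab$n_luteal_after_bout, c(3, 0, 0))
  expect_equal(tab$n_pregnant, c(3, 0, 0))
  expect_equal(tab$n_kittens, c(10, 0, 0))

  tests <- tt$tests
  p_of <- function(m) tests$p_value[tests$metric == m]
  expect_equal(p_of("n_luteal_after_bout"), exp(-3), tolerance = 1e-12)
  expect_equal(p_of("n_pregnant"), exp(-3), tolerance = 1e-12)
  expect_lt(p_of("n_kittens"), 1e-4)
  # bred females 3/1/1 and bouts 3/6/1 are not significant
  expect_gt(p_of("n_females_bred"), 0.05)
  expect_gt(p_of("n_bouts"), 0.05)
})

test_that("trial table flags zero-total rows and unknown females", {
  design <- study_design(c(C1 = "control", L1 = "low_dose", H1 = "high_dose"))
  empty_ev <- mk_events(integer(0))
  tt <- build_trial_table(empty_ev, mk_luteal(integer(0)), NULL, design,
                          c(240, 360))
  expect_true(all(is.na(tt$tests$p_value)))
  expect_true(all(grepl("zero", tt$tests$note)))

  stranger <- mk_events(250, female = "ZZ")
  expect_error(
    build_trial_table(stranger, mk_luteal(integer(0)), NULL, design, c(240, 360)),
    "absent from study design"
  )
})

test_that("simulated pregnancies propagate into the trial table", {
  co <- simulate_cohort(sim_config(master_seed = 57))
  cfg <- analysis_config()
  baselines <- fit_baselines(co$hormones, co$design$periods$pre_treatment,
                             exclusions = co$exclusions)
  phases <- call_phases_cohort(co$hormones, baselines, cfg, co$exclusions)
  luteal <- phases[phases$phase_type == "luteal", ]
  tw <- co$config$trial_windows$trial1
  tt <- build_trial_table(co$events, luteal,
                          co$truth$pregnancies[, c("animal_id", "conception_day", "kittens")],
                          co$design, tw)
  truth_preg <- co$truth$pregnancies
  in_tw <- truth_preg$conception_day >= tw[1] & truth_preg$conception_day < tw[2]
  expect_equal(sum(tt$table$n_pregnant), length(unique(truth_preg$animal_id[in_tw])))
  expect_equal(sum(tt$table$n_kittens), sum(truth_preg$kittens[in_tw]))
})
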