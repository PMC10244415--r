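fixed_fit <- function(threshold, animal = "A1", analyte = "E2_fecal") {
  structure(
    list(animal_id = animal, analyte = analyte, baseline_mean = threshold,
         baseline_sd = 0, k = 1.5, mode = "sd_above_mean",
         threshold = threshold, n_input = 10L, n_retained = 10L,
         n_iterations = 1L, retained_mask = rep(TRUE, 10),
         window_days = integer(), window = c(-180, 0)),
    class = "baseline_fit"
  )
}

test_that("phase calls are maximal runs of strictly elevated samples", {
  s <- make_series(c(1, 3, 5, 8, 10, 12), c(2, 4, 4, 2, 4, 2))
  calls <- call_phases(s, fixed_fit(3.5), "estrous", min_run = 2)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$start_day, 3)
  expect_equal(calls$end_day, 5)
  expect_equal(calls$n_samples, 2)
  expect_equal(calls$peak_value, 4)

  # all at baseline -> nothing; ties are baseline (strict inequality)
  s2 <- make_series(1:5, rep(3.5, 5))
  expect_equal(nrow(call_phases(s2, fixed_fit(3.5), "estrous", 2)), 0)

  # run length below min_run is not a phase
  s3 <- make_series(1:5, rep(10, 5))
  expect_equal(nrow(call_phases(s3, fixed_fit(3.5), "luteal", 6)), 0)
  c3 <- call_phases(s3, fixed_fit(3.5), "estrous", 2)
  expect_equal(c3$n_samples, 5)

  # mismatched fit is a contract error
  expect_error(
    call_phases(s3, fixed_fit(3.5, animal = "B9"), "estrous", 2),
    "contract"
  )
})

test_that("runs never span an exclusion interval", {
  # elevated days 1..20; exclusion [8, 13) removes day 10 and splits the rest
  s <- make_series(c(1, 4, 7, 10, 14, 17, 20), rep(9, 7))
  ex <- tibble::tibble(animal_id = "A1", start_day = 8L, end_day = 13L,
                       reason = "pregnancy")
  calls <- call_phases(s, fixed_fit(5), "estrous", min_run = 2, exclusions = ex)
  expect_equal(nrow(calls), 2)
  expect_equal(calls$start_day, c(1, 14))
  expect_equal(calls$end_day, c(7, 20))

  # segments too short after the split yield no call
  calls6 <- call_phases(s, fixed_fit(5), "luteal", min_run = 6, exclusions = ex)
  expect_equal(nrow(calls6), 0)
})

test_that("phase calls are maximal and disjoint on randomized inputs", {
  withr::local_seed(202)
  for (rep in 1:40) {
    n <- sample(10:60, 1)
    days <- sort(sample(-180:180, n))
    vals <- rlnorm(n, 0, 0.8)
    thr <- quantile(vals, runif(1, 0.3, 0.9))
    min_run <- sample(2:6, 1)
    calls <- call_phases(make_series(days, vals), fixed_fit(unname(thr)),
                         "estrous", min_run)
    if (nrow(calls) == 0) next
    above <- vals > thr
    for (i in seq_len(nrow(calls))) {
      idx <- which(days >= calls$start_day[i] & days <= calls$end_day[i])
      expect_true(all(above[idx]))                       # all samples elevated
      expect_gte(length(idx), min_run)
      lo <- min(idx); hi <- max(idx)                     # maximality
      if (lo > 1) expect_false(above[lo - 1])
      if (hi < n) expect_false(above[hi + 1])
    }
    # disjoint
    if (nrow(calls) > 1) {
      expect_true(all(calls$start_day[-1] > calls$end_day[-nrow(calls)]))
    }
  }
})

test_that("phase frequency normalizes by effective days", {
  calls <- tibble::tibble(
    animal_id = "A1", phase_type = "luteal",
    start_day = c(70L, 150L, 300L, 400L), end_day = c(100L, 180L, 330L, 430L),
    n_samples = 12L, peak_value = 5
  )
  f <- phase_frequency(calls, c(60, 420), norm_days = 180)
  expect_equal(f$n_phases, 4)
  expect_equal(f$normalized, 4 / 360 * 180)

  expect_equal(phase_frequency(calls[0, ], c(60, 420), 180,
                               animal_id = "A1", phase_type = "luteal")$normalized, 0)

  # 3 calls in a 90-day window with 30 excluded days -> 3/60 * 30 = 1.5
  calls3 <- tibble::tibble(
    animal_id = "A1", phase_type = "estrous",
    start_day = c(10L, 40L, 80L), end_day = c(12L, 42L, 82L),
    n_samples = 2L, peak_value = 5
  )
  ex <- tibble::tibble(animal_id = "A1", start_day = 50L, end_day = 80L,
                       reason = "pregnancy")
  f3 <- phase_frequency(calls3, c(0, 90), norm_days = 30, exclusions = ex)
  expect_equal(f3$effective_days, 60)
  expect_equal(f3$normalized, 1.5)

  # fully excluded window is degenerate
  ex_all <- tibble::tibble(animal_id = "A1", start_day = 0L, end_day = 90L,
                           reason = "collection_suspended")
  expect_error(
    phase_frequency(calls3, c(0, 90), 30, exclusions = ex_all),
    "degenerate"
  )
})

test_that("only phases starting inside the window are counted", {
  calls <- tibble::tibble(
    animal_id = "A1", phase_type = "luteal",
    start_day = c(-10L, 0L, 59L, 60L), end_day = c(20L, 30L, 89L, 90L),
    n_samples = 10L, peak_value = 5
  )
  f <- phase_frequency(calls, c(0, 60), norm_days = 180)
  expect_equal(f$n_phases, 2)  # starts at 0 and 59; -10 and 60 excluded
})
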