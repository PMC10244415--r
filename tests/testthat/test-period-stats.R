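test_that("log-scale t test matches the pooled-variance hand computation", {
  # identical multisets: t = 0, p = 1
  r <- log_t_test(c(1, 2, 3), c(3, 1, 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # textbook case: logs [0,1,2] vs [2,3,4] -> t = -2 / sqrt(2/3), df 4
  r2 <- log_t_test(c(1, exp(1), exp(2)), c(exp(2), exp(3), exp(4)))
  expect_equal(r2$statistic, -2 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(r2$df, 4)
  expect_equal(r2$p_value, 2 * pt(-2 / sqrt(2 / 3), 4), tolerance = 1e-10)

  # zero pooled variance is degenerate
  expect_error(log_t_test(c(2, 2, 2), c(6, 6, 6)), "degenerate")
  # log undefined for non-positive data
  expect_error(log_t_test(c(1, -1), c(2, 3)), "positive")
  expect_error(log_t_test(2, c(1, 2)), "insufficient")
})

test_that("log t test is scale-equivariant through the log-mean shift", {
  withr::local_seed(5)
  a <- rlnorm(8); b <- rlnorm(9)
  base <- log_t_test(a, b)
  scaled <- log_t_test(a * 7, b)
  # multiplying one group by c shifts its log-mean by log(c), variances fixed
  se <- sqrt((1 / 8 + 1 / 9)) *
    sqrt((sum((log(a) - mean(log(a)))^2) + sum((log(b) - mean(log(b)))^2)) / 15)
  expect_equal(scaled$statistic, base$statistic + log(7) / se, tolerance = 1e-10)
})

test_that("RCB ANOVA decomposition matches the hand-computed sums of squares", {
  withr::local_seed(77)
  for (rep in 1:20) {
    d <- make_rcb_data(rnorm(18, sd = 3), n_per_group = 3)
    res <- rcb_anova_tukey(d)
    o <- oracle_rcb_ss(d)
    got <- res$anova$sumsq
    names(got) <- res$anova$term
    expect_equal(got[["Group"]], o$group, tolerance = 1e-9)
    expect_equal(got[["Block"]], o$block, tolerance = 1e-9)
    expect_equal(got[["Period"]], o$period, tolerance = 1e-9)
    expect_equal(got[["Period:Group"]], o$interaction, tolerance = 1e-9)
    expect_equal(got[["Residual"]], o$residual, tolerance = 1e-9)
    # conservation: components sum to the total SS
    expect_equal(sum(got), o$total, tolerance = 1e-9)
  }
})

test_that("RCB ANOVA handles degenerate and block-only layouts", {
  # constant response: F undefined, Tukey p = 1, flagged
  expect_warning(res <- rcb_anova_tukey(make_rcb_data(rep(4, 18))), "constant")
  expect_true(res$zero_variance)
  expect_true(all(is.na(res$anova$statistic)))
  expect_true(all(res$tukey$p_adj == 1))

  # pure block effects balanced across groups: Block SS = total SS
  blocks <- rep(c(1, 5, 9), times = 3)          # same constants in every group
  d <- make_rcb_data(rep(blocks, each = 2))
  res2 <- rcb_anova_tukey(d)
  ss <- res2$anova$sumsq
  names(ss) <- res2$anova$term
  expect_equal(ss[["Block"]], sum(ss), tolerance = 1e-9)
  expect_equal(ss[["Group"]], 0, tolerance = 1e-9)
  expect_equal(ss[["Period"]], 0, tolerance = 1e-9)

  # unbalance is rejected
  d3 <- make_rcb_data(rnorm(18))[-1, ]
  expect_error(rcb_anova_tukey(d3), "unbalanced")
})

test_that("an injected period-by-group effect is detected and localized", {
  withr::local_seed(88)
  base <- rnorm(18, mean = 10, sd = 0.5)
  d <- make_rcb_data(base)
  # raise the high-dose group's post-treatment cell only
  hit <- d$group == "high_dose" & d$period == "post_treatment"
  d$value[hit] <- d$value[hit] + 8
  res <- rcb_anova_tukey(d)
  p_int <- res$anova$p_value[res$anova$term == "Period:Group"]
  expect_lt(p_int, 0.05)
  # the high-dose pre-vs-post contrast is flagged ...
  hd <- res$tukey[grepl("high_dose:pre_treatment", res$tukey$cell_1) &
                    grepl("high_dose:post_treatment", res$tukey$cell_2) |
                  grepl("high_dose:post_treatment", res$tukey$cell_1) &
                    grepl("high_dose:pre_treatment", res$tukey$cell_2), ]
  expect_equal(nrow(hd), 1)
  expect_lt(hd$p_adj, 0.05)
  # ... and the other groups' period contrasts are not
  for (g in c("control", "low_dose")) {
    gg <- res$tukey[grepl(paste0(g, ":pre_treatment"), res$tukey$cell_1) &
                      grepl(paste0(g, ":post_treatment"), res$tukey$cell_2) |
                    grepl(paste0(g, ":post_treatment"), res$tukey$cell_1) &
                      grepl(paste0(g, ":pre_treatment"), res$tukey$cell_2), ]
    expect_gt(gg$p_adj, 0.05)
  }
})

test_that("Dunnett contrasts behave and dominate the unadjusted p", {
  withr::local_seed(99)
  d_null <- tibble::tibble(
    group = rep(c("control", "low_dose", "high_dose"), each = 4),
    value = rnorm(12, mean = 5)
  )
  r <- one_way_anova_dunnett(d_null)
  expect_equal(nrow(r$dunnett), 2)
  expect_true(all(r$dunnett$p_adj >= r$dunnett$p_unadj - 1e-9))

  # a group shifted > 10 SD is flagged; the other stays near 1
  d_shift <- d_null
  d_shift$value[d_shift$group == "high_dose"] <-
    d_shift$value[d_shift$group == "high_dose"] + 50
  r2 <- one_way_anova_dunnett(d_shift)
  p_high <- r2$dunnett$p_adj[grepl("high_dose", r2$dunnett$contrast)]
  p_low <- r2$dunnett$p_adj[grepl("low_dose", r2$dunnett$contrast)]
  expect_lt(p_high, 1e-4)
  expect_gt(p_low, 0.2)

  expect_error(one_way_anova_dunnett(d_null, control = "placebo"), "contract")
  expect_warning(
    r3 <- one_way_anova_dunnett(tibble::tibble(
      group = rep(c("control", "low_dose"), each = 3), value = rep(2, 6)
    )),
    "constant"
  )
  expect_true(all(r3$dunnett$p_adj == 1))
})

test_that("stereological correction multiplies raw counts", {
  raw <- tibble::tibble(
    animal_id = "M1", group = "control",
    stage = c("primordial", "primary", "secondary", "antral"),
    raw_count = c(0L, 7L, 3L, 12L)
  )
  r <- correct_counts(raw)
  expect_equal(r$corrected_count, c(0, 35, 15, 60))
  expect_true(all(r$corrected_count %% r$correction_factor == 0))
  r1 <- correct_counts(raw, factor = 1)
  expect_equal(r1$corrected_count, raw$raw_count)
})
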