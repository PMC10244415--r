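#' Log-scale unpaired two-sample t test
#'
#' Concentration data are log-transformed (natural log; the statistic and
#' p-value are invariant to the base) and compared with a classical
#' pooled-variance two-sided Student t test on `n_a + n_b - 2` degrees of
#' freedom. Welch's correction is available behind `var_equal = FALSE`.
#'
#' @param a,b numeric vectors of positive values, each of length >= 2.
#' @param var_equal pool variances (classical Student t) when TRUE.
#' @return A list with `statistic`, `df`, `p_value`, and the group log-means.
#' @export
log_t_test <- function(a, b, var_equal = TRUE) {
  if (any(a <= 0) || any(b <= 0)) {
    stop("domain error: log transform requires strictly positive values",
         call. = FALSE)
  }
  if (length(a) < 2 || length(b) < 2) {
    stop("insufficient data: each sample needs >= 2 values", call. = FALSE)
  }
  la <- log(a); lb <- log(b)
  pooled_var <- (sum((la - mean(la))^2) + sum((lb - mean(lb))^2)) /
    (length(a) + length(b) - 2)
  if (var_equal && pooled_var == 0) {
    stop("degenerate variance: both samples are constant on the log scale",
         call. = FALSE)
  }
  ht <- stats::t.test(la, lb, var.equal = var_equal)
  list(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_log_a = mean(la),
    mean_log_b = mean(lb)
  )
}

#' Per-animal period samples of a hormone or phase-frequency variable
#'
#' Collects one value per animal x period, either the per-animal mean of all
#' samples in the period (`aggregate = "mean"`, the layout the block ANOVA
#' needs) or every sample (`aggregate = "none"`, for per-sample t tests).
#' Samples inside exclusion intervals are dropped.
#'
#' @param hormones hormone table.
#' @param design a [study_design()].
#' @param analyte analyte code to collect.
#' @param periods named periods to include.
#' @param aggregate `"mean"` or `"none"`.
#' @return A tibble (animal_id, group, period, value).
#' @export
collect_period_samples <- function(hormones, design, analyte,
                                   periods = c("pre_treatment", "post_treatment"),
                                   aggregate = c("mean", "none")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(design, "study_design"), analyte %in% ANALYTES)
  h <- hormones[hormones$analyte == analyte, , drop = FALSE]
  out <- list()
  for (a in unique(h$animal_id)) {
    sa <- h[h$animal_id == a, , drop = FALSE]
    ex <- animal_exclusions(design$exclusions, a)
    sa <- sa[!day_excluded(sa$day, ex), , drop = FALSE]
    for (p in periods) {
      v <- sa$value[in_window(sa$day, design$periods[[p]])]
      if (length(v) == 0) next
      if (aggregate == "mean") v <- mean(v)
      out[[length(out) + 1L]] <- tibble::tibble(
        animal_id = a, period = p, value = v
      )
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(animal_id = character(), group = character(),
                          period = character(), value = numeric()))
  }
  res <- dplyr::left_join(res, design$groups, by = "animal_id")
  res[, c("animal_id", "group", "period", "value")]
}

#' Randomized-complete-block ANOVA with Tukey pairwise comparisons
#'
#' Fits the two-period treatment comparison as a randomized complete block
#' design: Period, Group and their interaction are fixed effects and each
#' animal is a block. Blocks enter the sequential sums-of-squares
#' decomposition as a fixed additive term nested in group
#' (order: Group, Block, Period, Period x Group); with one observation per
#' animal x period cell this yields the same F tests as the random-block
#' formulation — the Group effect is tested against the block
#' (animal-within-group) mean square, Period and the interaction against the
#' residual. Tukey's studentized-range adjustment is applied to all pairwise
#' differences among the Period x Group cell means using the residual mean
#' square.
#'
#' When the response is constant the F statistics are undefined; the table is
#' flagged and all Tukey p-values are reported as 1 with a warning, so
#' degenerate simulated cohorts do not abort a pipeline run.
#'
#' @param samples tibble (animal_id, group, period, value) with exactly one
#'   value per animal x period, every animal observed in every period.
#' @return A list of class `rcb_anova` with elements `anova` (term, df,
#'   sumsq, meansq, statistic, p_value), `tukey` (pairwise cell-mean
#'   comparisons with adjusted p-values), `cell_means` and `zero_variance`.
#' @export
rcb_anova_tukey <- function(samples) {
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("animal_id", "group", "period", "value") %in% names(samples)))
  if (anyDuplicated(samples[, c("animal_id", "period")])) {
    stop("unbalanced design: more than one value per animal x period; ",
         "aggregate first (see collect_period_samples)", call. = FALSE)
  }
  periods <- unique(samples$period)
  tab <- table(samples$animal_id)
  if (any(tab != length(periods))) {
    stop("unbalanced design: every animal must be observed in every period",
         call. = FALSE)
  }
  g_of_animal <- unique(samples[, c("animal_id", "group")])
  if (anyDuplicated(g_of_animal$animal_id)) {
    stop("an animal appears in more than one group", call. = FALSE)
  }
  if (any(table(g_of_animal$group) < 2)) {
    stop("insufficient data: need >= 2 animals per group", call. = FALSE)
  }

  d <- data.frame(
    animal = factor(samples$animal_id),
    group = factor(samples$group),
    period = factor(samples$period),
    value = samples$value
  )
  total_ss <- sum((d$value - mean(d$value))^2)
  zero_variance <- total_ss < .Machine$double.eps * max(1, sum(d$value^2))

  fit <- stats::aov(value ~ group + animal + period + group:period, data = d)
  ss <- summary(fit)[[1]]
  rn <- trimws(rownames(ss))
  get_row <- function(nm) ss[match(nm, rn), ]
  rows <- list(
    Group = get_row("group"),
    Block = get_row("animal"),
    Period = get_row("period"),
    `Period:Group` = get_row("group:period"),
    Residual = get_row("Residuals")
  )
  df <- vapply(rows, function(r) r[["Df"]], numeric(1))
  sumsq <- vapply(rows, function(r) r[["Sum Sq"]], numeric(1))
  meansq <- sumsq / df

  if (zero_variance) {
    statistic <- rep(NA_real_, 5)
    p_value <- rep(NA_real_, 5)
    warning("response is constant: F statistics undefined; Tukey p-values ",
            "reported as 1", call. = FALSE)
  } else {
    # Group vs block (animal-within-group) MS; Period and interaction vs residual
    statistic <- c(
      meansq[["Group"]] / meansq[["Block"]],
      NA_real_,
      meansq[["Period"]] / meansq[["Residual"]],
      meansq[["Period:Group"]] / meansq[["Residual"]],
      NA_real_
    )
    p_value <- c(
      stats::pf(statistic[1], df[["Group"]], df[["Block"]], lower.tail = FALSE),
      NA_real_,
      stats::pf(statistic[3], df[["Period"]], df[["Residual"]], lower.tail = FALSE),
      stats::pf(statistic[4], df[["Period:Group"]], df[["Residual"]], lower.tail = FALSE),
      NA_real_
    )
  }

  anova_tbl <- tibble::tibble(
    term = names(rows), df = as.integer(df), sumsq = sumsq,
    meansq = meansq, statistic = statistic, p_value = p_value
  )

  # Tukey on the Period x Group cell means, residual MS as the error term
  cells <- dplyr::summarise(
    dplyr::group_by(d, .data$group, .data$period),
    mean = mean(.data$value), n = dplyr::n(), .groups = "drop"
  )
  cells$cell <- paste(cells$group, cells$period, sep = ":")
  k <- nrow(cells)
  df_res <- df[["Residual"]]
  ms_res <- meansq[["Residual"]]
  pairs <- utils::combn(k, 2)
  tukey <- tibble::tibble(
    cell_1 = cells$cell[pairs[1, ]],
    cell_2 = cells$cell[pairs[2, ]],
    diff = cells$mean[pairs[2, ]] - cells$mean[pairs[1, ]],
    p_adj = NA_real_
  )
  if (zero_variance || ms_res <= 0) {
    tukey$p_adj <- 1
  } else {
    se <- sqrt(ms_res / 2 *
                 (1 / cells$n[pairs[1, ]] + 1 / cells$n[pairs[2, ]]))
    q <- abs(tukey$diff) / se
    tukey$p_adj <- stats::ptukey(q, nmeans = k, df = df_res, lower.tail = FALSE)
  }

  structure(
    list(anova = anova_tbl, tukey = tukey, cell_means = cells,
         zero_variance = zero_variance),
    class = "rcb_anova"
  )
}

#' @export
print.rcb_anova <- function(x, ...) {
  cat("<rcb_anova> randomized-complete-block ANOVA\n")
  print(as.data.frame(x$anova), row.names = FALSE)
  cat("Tukey-adjusted cell-mean comparisons:\n")
  print(as.data.frame(x$tukey), row.names = FALSE)
  invisible(x)
}

#' One-way ANOVA with Dunnett many-to-one contrasts
#'
#' Standard one-way decomposition followed by Dunnett's test of every treated
#' group against the control, with two-sided adjusted p-values from the
#' equicorrelated multivariate-t distribution (correlation 1/2 in balanced
#' designs).
#'
#' @param data tibble with columns `group` and `value`.
#' @param control label of the control group.
#' @return A list with `anova` (df, sumsq, statistic, p_value for the group
#'   term) and `dunnett` (contrast, estimate, statistic, p_unadj, p_adj).
#' @export
one_way_anova_dunnett <- function(data, control = "control") {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("group", "value") %in% names(data)))
  groups <- unique(data$group)
  if (!control %in% groups) {
    stop("contract error: control group '", control, "' not present",
         call. = FALSE)
  }
  if (length(groups) < 2 || any(table(data$group) < 2)) {
    stop("insufficient data: need >= 2 groups with >= 2 values each",
         call. = FALSE)
  }
  d <- data.frame(
    group = stats::relevel(factor(data$group), ref = control),
    value = data$value
  )
  total_ss <- sum((d$value - mean(d$value))^2)
  if (total_ss < .Machine$double.eps * max(1, sum(d$value^2))) {
    warning("response is constant: p-values reported as 1", call. = FALSE)
    others <- setdiff(levels(d$group), control)
    return(list(
      anova = tibble::tibble(df = length(groups) - 1L, sumsq = 0,
                             statistic = NA_real_, p_value = NA_real_),
      dunnett = tibble::tibble(
        contrast = paste(others, "-", control),
        estimate = 0, statistic = NA_real_, p_unadj = 1, p_adj = 1
      )
    ))
  }

  fit <- stats::aov(value ~ group, data = d)
  ss <- summary(fit)[[1]]
  anova_tbl <- tibble::tibble(
    df = ss[["Df"]][1],
    sumsq = ss[["Sum Sq"]][1],
    statistic = ss[["F value"]][1],
    p_value = ss[["Pr(>F)"]][1]
  )

  gh <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
  sm <- summary(gh)
  df_res <- stats::df.residual(fit)
  tstat <- unname(sm$test$tstat)
  dunnett <- tibble::tibble(
    contrast = names(sm$test$coefficients),
    estimate = unname(sm$test$coefficients),
    statistic = tstat,
    p_unadj = 2 * stats::pt(abs(tstat), df_res, lower.tail = FALSE),
    p_adj = unname(sm$test$pvalues)
  )
  list(anova = anova_tbl, dunnett = dunnett)
}

#' Apply a stereological correction factor to follicle counts
#'
#' When only one serial section out of every `factor` is counted, raw follicle
#' counts are multiplied by the sampling factor to estimate totals.
#'
#' @param raw tibble with at least a `raw_count` column (non-negative
#'   integers); typically also `animal_id`, `group`, `stage`.
#' @param factor integer correction factor (default 5: every fifth section
#'   kept).
#' @return The input with a `correction_factor` and `corrected_count` column.
#' @export
correct_counts <- function(raw, factor = 5L) {
  raw <- tibble::as_tibble(raw)
  stopifnot("raw_count" %in% names(raw), all(raw$raw_count >= 0),
            factor >= 1L)
  raw$correction_factor <- as.integer(factor)
  raw$corrected_count <- raw$raw_count * as.integer(factor)
  raw
}
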