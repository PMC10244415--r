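# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals.

# Brute-force iterative-exclusion baseline: recomputes the whole exclusion
# sequence from scratch at every step using a cumulative excluded index set.
oracle_baseline <- function(values, k = 1.5, mode = "sd_above_mean") {
  excluded <- integer(0)
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    idx <- setdiff(seq_along(values), excluded)
    m <- sum(values[idx]) / length(idx)
    s <- if (length(idx) > 1) {
      sqrt(sum((values[idx] - m)^2) / (length(idx) - 1))
    } else 0
    thr <- if (mode == "sd_above_mean") m + k * s else k * m
    newly <- idx[values[idx] > thr]
    if (length(newly) == 0) break
    excluded <- c(excluded, newly)
  }
  list(mean = m, sd = s, threshold = thr,
       n_retained = length(values) - length(excluded),
       n_iterations = iterations)
}

# All multisets of sizes n_min..n_max drawn from a value alphabet. The
# baseline procedure depends only on the multiset of values, so this covers
# every series over the alphabet.
enumerate_multisets <- function(alphabet, n_min = 3, n_max = 12) {
  out <- list()
  counts_of_size <- function(n, k) {
    if (k == 1) return(matrix(n, ncol = 1))
    do.call(rbind, lapply(0:n, function(i) {
      cbind(i, counts_of_size(n - i, k - 1))
    }))
  }
  for (n in n_min:n_max) {
    cc <- counts_of_size(n, length(alphabet))
    for (r in seq_len(nrow(cc))) {
      out[[length(out) + 1L]] <- rep(alphabet, cc[r, ])
    }
  }
  out
}

# Hand computation of the sequential (Group, Block-within-Group, Period,
# Period x Group, Residual) sums of squares for a balanced two-period layout
# with one observation per animal x period, using explicit mean contrasts.
oracle_rcb_ss <- function(d) {
  gm <- mean(d$value)
  n_periods <- length(unique(d$period))
  grp_means <- tapply(d$value, d$group, mean)
  grp_n <- tapply(d$value, d$group, length)
  ss_group <- sum(grp_n * (grp_means - gm)^2)
  animal_means <- tapply(d$value, d$animal_id, mean)
  animal_grp <- tapply(as.character(d$group), d$animal_id, `[`, 1)
  ss_block <- n_periods * sum((animal_means - grp_means[animal_grp])^2)
  per_means <- tapply(d$value, d$period, mean)
  per_n <- tapply(d$value, d$period, length)
  ss_period <- sum(per_n * (per_means - gm)^2)
  cell_means <- tapply(d$value, list(d$group, d$period), mean)
  cell_n <- tapply(d$value, list(d$group, d$period), length)
  ss_cells <- sum(cell_n * (cell_means - gm)^2)
  ss_int <- ss_cells - ss_group - ss_period
  ss_total <- sum((d$value - gm)^2)
  ss_resid <- ss_total - ss_group - ss_block - ss_period - ss_int
  list(group = ss_group, block = ss_block, period = ss_period,
       interaction = ss_int, residual = ss_resid, total = ss_total)
}

# tiny builders -------------------------------------------------------------

make_series <- function(days, values, animal = "A1", analyte = "E2_fecal",
                        units = "ng/g") {
  tibble::tibble(animal_id = animal, analyte = analyte,
                 day = as.integer(days), value = values, units = units)
}

# balanced 3-group x 2-period x n-block layout
make_rcb_data <- function(values, n_per_group = 3) {
  groups <- rep(c("control", "low_dose", "high_dose"), each = n_per_group)
  animals <- sprintf("A%02d", seq_along(groups))
  tibble::tibble(
    animal_id = rep(animals, each = 2),
    group = rep(groups, each = 2),
    period = rep(c("pre_treatment", "post_treatment"), times = length(animals)),
    value = values
  )
}
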