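---
title: "Methods: baseline estimation, phase calling and trial statistics for feline hormone monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: baseline estimation, phase calling and trial statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estrocycle)
```

## The analysis problem

The domestic cat is an induced ovulator: ovulation is normally triggered by
copulation, after which the corpus luteum sustains elevated progesterone for
several weeks whether or not fertilization occurred. Long-term contraception
studies in this species therefore monitor reproductive function
noninvasively, through estrogen (E2) and progestogen (P4) metabolites
measured in fecal samples collected a few times per week over months to
years. The questions such a study asks are longitudinal and event-based:

* is the animal still cycling (recurrent estrous phases, seen as E2
  elevations)?
* is it still ovulating (luteal phases, seen as sustained multi-week P4
  elevations)?
* during supervised mating trials, do breeding bouts lead to luteal phases,
  pregnancies and litters — and do those outcomes differ between treatment
  groups?

`estrocycle` implements this analysis chain as composable, tested functions:
per-animal baseline estimation, run-length phase calling, phase-frequency
normalization, period-comparison statistics, and mating-trial analysis, plus
a ground-truthed cohort simulator used to validate the detectors.

Time is handled as integer day offsets from the treatment day (day 0);
calendar dates are converted at the I/O boundary. "Months" are 30-day
blocks: the default study periods are a 180-day pre-treatment window
`[-180, 0)`, a 60-day transition `[0, 60)` and a 660-day post-treatment
window `[60, 720)`. All intervals in the package are half-open, which makes
period and exclusion arithmetic unambiguous.

## Iterative baseline estimation

For each animal and analyte, the non-elevated baseline is estimated on the
pre-treatment window by iterative exclusion (`fit_baseline()`): compute the
mean and sample SD (n − 1 denominator) of the retained samples, permanently
exclude every sample strictly greater than mean + k·SD (default k = 1.5),
and repeat until an iteration excludes nothing. The converged mean + k·SD is
then used as the detection threshold *for the entire series*, so treatment
periods are judged against the animal's own pre-treatment baseline. A
`fold_of_mean` mode (threshold = k × mean) is also provided, since both
threshold conventions circulate in the fecal-endocrinology literature; the
SD form is the default.

Choices worth making explicit:

* **Ties are baseline.** The rule is strictly "greater than"; a value equal
  to the threshold is retained.
* **Exclusion is permanent.** Points excluded in an earlier iteration are
  not re-tested; the procedure therefore terminates in at most n iterations.
* **At least three samples** are required in the baseline window; with fewer
  the fit aborts with an insufficient-data error rather than returning a
  meaningless SD.
* In SD mode with k > 0 the minimum can never exceed mean + k·SD, so the
  retained set can never empty itself; the degenerate possibility in fold
  mode with k < 1 is guarded explicitly.

### Where the threshold converges, and what that implies

A property of this estimator that users should understand: on *continuous*
unimodal baseline noise the iteration does not stop after trimming a few
outliers — it walks down to the fixed point t* of

t = mean(X | X ≤ t) + k · sd(X | X ≤ t).

For k = 1.5 and near-normal or lognormal noise, t* sits near the 75th
percentile of the baseline distribution, i.e. roughly a quarter of genuine
baseline samples end up above the converged threshold regardless of how
small the noise CV is. Two consequences:

* **The luteal rule (≥ 6 consecutive elevated samples) is robust**: runs of
  six spurious exceedances are rare (on the order of 10⁻³–10⁻⁴ per sample
  position for the noise levels simulated here), so luteal specificity stays
  high.
* **The estrous rule (≥ 2 consecutive elevated samples) is intrinsically
  liberal**: pairs of spurious exceedances occur at a rate of several
  percent per position, so short false estrous phases are expected from
  baseline noise alone. Its sample-level specificity is capped around
  0.8–0.9 by the mathematics of the threshold rule, not by implementation.
  This is tolerable for the study design because estrous *frequencies* are
  compared between periods within animal, and the false-call rate is the
  same in both periods.

A second boundary matters when elevations are large and noise is small: if
the data in the baseline window take essentially two levels (baseline and
f-fold elevation) with a fraction q of samples elevated, iteration 1
excludes the elevated cluster if and only if q < 1/(1 + k²) ≈ 0.31 for
k = 1.5 — otherwise the procedure converges immediately with the threshold
*above* the elevations and the detector is blind for that animal. Baseline
identifiability therefore requires that elevated samples not dominate the
baseline window. This drives two simulator defaults (below): the
spontaneous-ovulation probability is kept low so that the 180-day
pre-treatment window is not crowded with luteal elevations, and estrus
occupies ≈ 25 % of cycling time, safely under the bound.

## Phase calling and frequency normalization

`call_phases()` removes samples inside exclusion intervals (pregnancy,
lactation, suspended collection), segments the remaining samples at
exclusion boundaries, and emits every maximal run of ≥ `min_run` consecutive
samples strictly above the threshold as a phase call. Conventions:

* An estrous phase is ≥ 2 consecutive elevated E2 samples; a luteal phase is
  ≥ 6 consecutive elevated P4 samples. With thrice-weekly sampling, six
  samples correspond to roughly two weeks of sustained elevation —
  comfortably shorter than a true luteal phase (4–6 weeks) and comfortably
  longer than noise runs.
* "Consecutive" means adjacent in collection order, not adjacent calendar
  days; missing collection days do not break a run.
* Runs never span an exclusion interval, and runs separated by a single
  below-threshold sample are *not* merged.

`phase_frequency()` counts the calls whose **start day** lies in the query
window (a phase truncated by the window end still counts if it starts
inside) and normalizes by the effective days — the window length minus its
overlap with exclusion intervals:

normalized = n_phases / effective_days × norm_days,

with norm_days = 30 for estrous (phases per month) and 180 for luteal
(phases per six months). A window whose effective length is zero or negative
raises a degenerate-window error rather than returning an infinity.

`amh_threshold_compliance()` covers the serum AMH check used in such
studies: the fraction of post-treatment samples at or above a target
concentration (default 0.25 µg/ml) and whether every sample stayed above it.

## Period statistics

**Log-scale t tests** (`log_t_test()`): metabolite concentrations are
right-skewed, so two-period comparisons are performed on natural-log values
with a classical pooled-variance two-sided t test (Welch available behind a
flag). Zero pooled variance and non-positive values are hard errors. By
default every sample in a period enters the comparison; a per-animal mean
aggregation is available through `collect_period_samples(aggregate =
"mean")` for users who prefer one value per animal.

**Randomized-complete-block ANOVA** (`rcb_anova_tukey()`): phase frequencies
are compared between periods with Period, Group and Period×Group as fixed
effects and each animal as a block. Blocks enter the sequential
decomposition as a fixed additive term nested in group (order: Group, Block,
Period, Period×Group); with one observation per animal×period cell the F
tests coincide with the random-block formulation — the Group effect is
tested against the animal-within-group mean square, Period and the
interaction against the residual. Under a block-structured null the Group
test is exactly F-distributed, and the packaged calibration check (2,000
simulated null layouts) observes a type-I rate close to the nominal 5 %.
Tukey's studentized-range adjustment is applied to all pairwise Period×Group
cell-mean differences using the residual mean square. A constant response
makes every F undefined; the result is flagged, and Tukey p-values are
reported as 1 with a warning so that degenerate simulated cohorts do not
abort a pipeline.

**One-way ANOVA with Dunnett contrasts** (`one_way_anova_dunnett()`): for
endpoint measurements compared against a control group (for example
stereological follicle counts, to which `correct_counts()` applies the
every-nth-section multiplier, default ×5). The many-to-one adjustment uses
the equicorrelated multivariate-t distribution (through `multcomp`); the
packaged validation compares the adjusted p-values against a 10⁶-resample
Monte-Carlo oracle and observes agreement within a few × 10⁻⁴.

## Mating-trial analysis

`detect_bouts()` defines a breeding bout as a maximal run of consecutive
calendar days each containing at least one confirmed breeding (intromission)
event; recorded attempts never count. `link_luteal()` attributes a luteal
phase to a bout when the phase starts strictly after the bout's last day and
within `max_lag_days` of it (default 21 days — generous for the 1–3 day
post-coital ovulation lag plus the ~2-sample onset resolution of
thrice-weekly sampling; the value is configurable and recorded in the
output). Each luteal call credits at most one bout, the nearest preceding
one.

`build_trial_table()` aggregates, per group and trial window: females with
at least one bout, total bouts, bouts followed by a luteal phase, pregnant
females and kittens born. Each count row is tested with
`chisq_uniform()` — a goodness-of-fit of the per-group counts against a
uniform expected distribution (expected = total/g), with df = g − 1 and no
continuity correction. With three groups the p-value has the closed form
exp(−χ²/2); counts of (3, 0, 0) give χ² = 6 and p = 0.0498, and counts of
(10, 0, 0) give χ² = 20 and p ≈ 4.5 × 10⁻⁵. Rows with zero total are
reported as undefined with a note instead of aborting. The statistic is
discrete for fixed totals: its exact multinomial tail and the continuous
chi-square tail agree well at the decision-relevant values (at χ² = 6,
n = 9: 0.0504 exact vs 0.0498), but can differ substantially between
support points — small-count p-values near 0.05 should be read with that in
mind.

## The cohort simulator

`simulate_cohort()` generates a cohort with the statistical structure the
analysis assumes, plus ground-truth event windows, so every detector can be
validated against known truth. Per animal it runs a state machine:

* estrus recurs as a renewal process — an interestrous interval drawn
  uniformly from 14–21 days, then an estrus of 5–7 days — suspended during
  luteal, pregnant and lactating states;
* during an estrus that overlaps a mating-trial window, at most one breeding
  bout of 1–4 consecutive days occurs, with a per-group propensity;
* ovulation is induced (~2 days after the last coital act) with per-group
  probability, or spontaneous at estrus end with a low per-group
  probability; ovulation starts a 30–45 day luteal window;
* conception (probability 0.85 given a mated ovulation) leads to a 65-day
  gestation and 56-day lactation, and the corresponding exclusion intervals
  exactly cover pregnancy plus lactation; completed pregnancies produce
  litters of 2–4 kittens;
* fecal E2 and P4 series are sampled on three fixed weekdays per week;
  kinetics are piecewise-constant fold-changes (E2 ×6 during estrus, P4 ×8
  during luteal/pregnancy windows for untreated physiology) with
  multiplicative lognormal noise (sdlog 0.15 for both analytes, i.e. an
  assay-CV-dominated ~15 % noise level);
* treatment effects — suppressed ovulation probabilities and reduced luteal
  P4 amplitude in the dosed groups — act from day 0 (an optional linear
  onset ramp is available);
* each animal consumes an RNG substream derived from the master seed and its
  index, so cohorts are reproducible and enlarging a cohort does not
  reshuffle existing animals.

Two defaults deserve justification. The **spontaneous-ovulation probability**
per estrus (0.02 control, lower in dosed groups) is deliberately at the low
end of what is plausible for group-housed cats; colony rates vary widely and
are rarely quantified. The low default keeps the expected pre-treatment
luteal load under one window per animal, which the identifiability bound
above requires for the baseline threshold to be estimable from the
pre-treatment window — a cohort simulated with frequent spontaneous
ovulation would defeat any threshold-based luteal detector, not just this
one. The **noise level** (sdlog 0.15) likewise reflects the regime in which
the run-length method is designed to operate; at sdlog ≳ 0.3 the fixed-point
threshold sits so deep in the baseline distribution that six-sample false
runs become common and luteal specificity degrades below 0.9.

### What the simulator does not emulate

No seasonality or photoperiod effects; no pharmacokinetic rise/decay shapes
(elevations are rectangular); no assay detection floor or censoring; no
autocorrelated baseline drift; no male or behavioural model beyond bout
counts. Passing detector validation on simulated cohorts therefore
demonstrates the *logic* of the pipeline — thresholding, run detection,
exclusion handling, counting, statistics — under the stated noise model; it
does not certify performance on real data with assay artifacts or seasonal
baselines.

One structural subtlety: because the pregnancy exclusion starts at the
conception day, the luteal elevation of a *conceiving* ovulation is hidden
inside the exclusion and cannot be detected — the detector validation masks
such windows (along with any window holding fewer than `min_run` analysable
samples, e.g. truncated by the study end) as undetectable by construction.
In a real study the post-bout P4 rise is typically observed before pregnancy
is confirmed, so bout→luteal linkage in simulated *conceiving* females
undercounts relative to field scoring.

## Detector validation

`validate_detector()` runs the full baseline + phase-calling chain on a
simulated cohort and scores each analysable sample (scheduled day outside
exclusions, not in a masked window) as truth/call positive or negative,
pooling confusion counts across animals. With noise switched off the
detectors are exact (sensitivity = specificity = 1 for both phase types);
at the default noise level, luteal sensitivity and specificity stay above
0.9 (typically ≈ 1.0 and ≈ 0.97–0.99 over a 51-animal cohort), and estrous
sensitivity stays at 1 while estrous specificity sits lower for the
structural reason discussed above.

## Problem sizes and numerical conventions

The packaged validation uses problem sizes chosen to give tight Monte-Carlo
error at interactive runtimes: exhaustive baseline-oracle comparison over
all multisets of length ≤ 12 from a 4-value alphabet (1,805 series); a
9-animal, 900-day cohort for exact (noise-free) detector checks and a
51-animal cohort for noisy checks; 2,000 null replicates for ANOVA type-I
calibration; 10⁵ multinomial draws for chi-square calibration; 10⁶
resamples for the Dunnett oracle. Sample SDs use the n − 1 denominator
throughout; intervals are half-open; phase starts decide window membership;
CSV outputs are written deterministically so a rerun with the same seed and
inputs is byte-identical.
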