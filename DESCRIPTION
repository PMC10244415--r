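Package: estrocycle
Title: Longitudinal Reproductive Endocrinology of an Induced Ovulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal, noninvasively collected
    reproductive-hormone monitoring in the domestic cat and similar induced
    ovulators. Estimates per-animal hormone baselines by iterative exclusion of
    values above mean + k standard deviations, calls estrous and luteal phases
    as run-length events in irregularly sampled fecal estrogen and progestogen
    metabolite series, normalizes phase frequencies to fixed-length reporting
    windows, compares treatment periods with randomized-complete-block ANOVA
    (Tukey), log-scale t tests, and one-way ANOVA with Dunnett contrasts, and
    analyzes mating-trial outcomes (breeding-bout detection, bout-to-luteal
    linkage, chi-square tests against a uniform null). Includes a stochastic
    simulator of a feline estrous-cycle cohort with ground-truth events for
    validating the detectors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    multcomp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
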