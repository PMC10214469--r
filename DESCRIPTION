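Package: metstress
Title: Multi-Environment Trial Analysis of Heat and Drought Stress
    Tolerance in Wheat
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-environment wheat field trials that
    contrast optimum, terminal-heat and combined heat-drought stress
    environments. Provides a validated long-format data model for plot-level
    phenotypes, descriptive statistics, fixed-effects factorial ANOVA for
    alpha-lattice trials with variance components and broad-sense
    heritability, LSD and Tukey post-hoc tests, per-genotype percent
    reductions under stress, per-environment trait correlations and
    single-predictor yield regressions, and the stress-tolerance indices
    STI, SSI, MP, TOL, MSTI and GMP with genotype ranking and selection.
    Includes a seeded generator of study-shaped synthetic trials with known
    ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
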