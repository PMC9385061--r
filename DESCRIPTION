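Package: metstab
Title: Multi-Environment Trial Stability Analysis with AMMI and GGE Biplots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing genotype-by-environment interaction in
    multi-environment trials (METs). Provides a combined fixed-effects ANOVA
    partition for alpha-lattice trials, the additive main effects and
    multiplicative interaction (AMMI) decomposition with Gollob tests, AMMI
    stability values (ASV) and the yield stability index (YSI), GGE biplot
    analysis (which-won-where polygon, average-environment coordination,
    discriminativeness and representativeness of test sites), and a synthetic
    MET generator with known ground truth for validating every stage. All
    user-facing functions take and return data frames, so analyses compose
    with the pipe.
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
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
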