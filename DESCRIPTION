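Package: enterochron
Title: Longitudinal Fecal Microbiome and Antimicrobial Resistance Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal analysis of the developing gut microbiome
    and of antimicrobial resistance in cohort studies sampled on a fixed age
    grid, motivated by female-pig cohorts followed from weaning to first
    parity. Implements Dirichlet-multinomial mixture enterotyping with
    Laplace-approximation model selection and per-subject enterotype
    trajectories; a rank-based microbiome maturation score built from genus
    first-appearance ages, Kendall's coefficient of concordance and a
    median-rank consensus order; cumulative sum scaling normalization, alpha
    diversity, Bray-Curtis dissimilarity, beta-dispersion and
    strata-restricted PERMANOVA; random-intercept linear mixed models and a
    per-genus differential-abundance scan with Benjamini-Hochberg false
    discovery control; and penalized-spline trend models with continuous-time
    AR(1) errors whose first-derivative confidence bands yield windows of
    significant change for resistant-bacteria plate counts and resistance-gene
    copy numbers. A synthetic cohort generator with known ground truth mirrors
    the study design so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    lme4,
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
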