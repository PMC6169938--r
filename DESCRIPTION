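Package: combrisk
Title: Combined Clinical and Polygenic Breast Cancer Risk Assessment
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A coefficient-agnostic pipeline for combining a normalized
    polygenic risk score (PRS) with Gail-model (BCRAT-style) absolute risk
    projections of invasive breast cancer. Computes a 75-SNP multiplicative
    risk score normalized by each SNP's Hardy-Weinberg population-average
    risk, projects 5-year and lifetime (to age 90) absolute risks under
    piecewise-constant incidence and competing-mortality hazards, multiplies
    the two into a combined score, and evaluates the gain by the odds ratio
    per age-adjusted standard deviation (OPERA), DeLong AUC comparison,
    Hosmer-Lemeshow calibration, and guideline-threshold reclassification
    with the two-category net reclassification improvement (NRI). Ships a
    seeded synthetic case-control cohort generator with known ground-truth
    effects so every stage is testable without study data, and a command-line
    interface over the full pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
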