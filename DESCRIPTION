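Package: otispath
Title: Protein Intake, the Plasma Metabolome, and Infant Growth Path Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Secondary-analysis toolkit for a randomized complementary-feeding
    trial testing the Early Protein Hypothesis. Provides a synthetic cohort
    generator calibrated to the trial's published standardized path
    coefficients, cumulative nutrient-intake construction by trapezoidal AUC
    over the visit schedule, plasma metabolome group testing (generalized log
    transform, principal component analysis, Canberra-distance PERMANOVA with
    a dispersion-homogeneity check, Mann-Whitney U tests with
    Benjamini-Hochberg correction and Wilcoxon effect sizes), and a
    covariance-based structural equation modeling engine for observed-variable
    path models with robust maximum likelihood estimation, sandwich standard
    errors, scaled test statistics, goodness-of-fit indices and modification
    indices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vegan
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
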