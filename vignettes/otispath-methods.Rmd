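---
title: "Methods: simulation design, estimators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation design, estimators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otispath)
```

This vignette documents the statistical machinery of `otispath`: what the
synthetic cohort generator emulates and why its defaults are what they are,
how the covariance-based SEM engine estimates and corrects its models, how
the metabolome tests are constructed, and which numerical and design
choices were made where more than one defensible option existed.

## 1. The scientific setting

The package targets secondary analyses of randomized complementary-feeding
trials built around the Early Protein Hypothesis: protein intake above
physiological need raises circulating branched-chain amino acids (BCAAs),
which stimulate IGF-1 and insulin secretion, accelerating infant weight
gain. The reference design is an OTIS-style trial: 125 infants per diet
group (a protein-reduced Nordic diet versus conventional feeding), 5-day
dietary records around the 6-, 9-, 12- and 18-month visits, a 52-metabolite
targeted ¹H-NMR plasma panel at 12 and 18 months, plasma IGF-1, insulin,
glucose and folate, anthropometry, and maternal/neonatal covariates.

Two confirmatory path models formalise the hypothesis: body weight (or
BMI) regressed on z-scored cumulative protein intake, the ln
insulin-to-glucose ratio, ln IGF-1 and the covariates (birth weight,
gestational weight gain, prepregnancy BMI, exclusive-breastfeeding
duration, formula use, sex, age category); ln IGF-1 and ln
insulin-to-glucose each regressed on the protein variables plus sex and
age. All variables are observed; there are no latent constructs.

## 2. The synthetic cohort generator

### What it emulates

`otis_preset()` encodes the generating truth: the published standardized
path coefficients (e.g. protein AUC to IGF-1 0.40, protein AUC to weight
0.36, birth weight to weight 0.39, age to BMI −0.40), exogenous moments
from the trial's baseline table (birth weight 3620 ± 460 g, maternal
prepregnancy BMI 24 ± 3.8 kg/m², gestational weight gain 14 ± 5 kg,
exclusive breastfeeding 4.1 ± 1.4 months, 45% girls), group-specific intake
trajectories whose Nordic protein reduction is 26/29/17% at 9/12/18 months
(waning adherence), per-visit any-breastfeeding probabilities
0.71/0.39/0.20/0.05, metabolite group shifts expressed as Wilcoxon
effect-size classes, and a dropout model calibrated to 24% versus 12%
attrition driven by maternal BMI (+), maternal age (−), breastfeeding at
enrollment (−).

Simulation proceeds causally: covariates → group → intake trajectories →
BCAAs from recent protein → IGF-1 and insulin/glucose → weight and BMI →
remaining metabolites → dropout. Infant length is derived from weight and
BMI so the identity BMI = weight/(length/100)² holds on every row.

### Exact standardized truth

The published coefficients are *standardized*. To make them the exact
generating values rather than values-up-to-noise, endogenous variables are
built in standardized space: each equation's residual is drawn, then
orthogonalised against the realised design matrix and rescaled so the
generated variable has sample variance exactly one (the same idea as
`MASS::mvrnorm(empirical = TRUE)`). The residual variance is
1 − bᵀĈb with Ĉ the realised covariance of the regressors — the
path-tracing solution of `solve_error_variances()` evaluated at the sample
rather than the assumed moments. A fitted, correctly specified SEM
therefore recovers each coefficient up to the (small) coupling induced by
over-identification, not up to Monte-Carlo error. `solve_error_variances()`
also provides the preset-level solution under the assumed exogenous
correlations, rejecting any preset whose explained variance reaches 1.

### Specific calibration choices

* **Mediator coefficients.** The trial reports slightly different mediator
  estimates in its two model fits (protein→IGF-1 0.40 in the weight-based
  model, 0.43 in the BMI-based one — same data, different outcome
  equation). One cohort cannot embody both; the preset uses the
  weight-based values, since that model is the better-fitting primary.
* **Unprinted paths** default to zero and are overridable via the
  `structural` argument. One exception: the sex effect on IGF-1 is
  reported significant (boys lower) without a magnitude; it is set to
  −0.15, a moderate effect detectable at the trial's size. No target
  quantity depends on it.
* **Protein→BCAA link.** The trial reports r > 0.32 between recent protein
  intake and total BCAA; the preset sets the generating link to r = 0.45
  (a preset field, not a constant). The three BCAAs load on a common
  factor with loading 0.98, giving pairwise correlations near 0.96,
  inside the reported "> 0.93". The *group* difference in BCAAs is not an
  additive shift: it emerges mechanically from the protein trajectories
  through this link, and lands in the moderate Wilcoxon class — consistent
  with the reported volcano.
* **Metabolite shifts.** Non-BCAA effects are parameterized as target
  Wilcoxon r and converted to log-scale shifts via
  δ = √2 Φ⁻¹(1/2 + r/√3) σ_log (the large-sample mapping between the
  rank-test Z and a normal location shift). Within-class values sit at the
  upper-middle of each band (moderate 0.35, small 0.28 at 12 months,
  halved at 18 months): the signature *was* detected at the trial's sample
  size, so the generating truth must be detectably inside its class.
* **Dropout.** Logit coefficients act on standardized covariates; the
  group-specific intercept is solved by `uniroot` so the expected
  attrition over the realised cohort equals the target rate exactly. With
  all coefficients zero the intercept reduces to logit(rate).
* **Intake scale.** Conventional-group protein means 14/26/33/38 g/d at
  6/9/12/18 months with ~22% lognormal spread (55% of log-variance at the
  infant level), energy 700–1100 kcal/d, fat at 35% of energy: typical
  Northern-European complementary-feeding values. Weight is centred at
  10.8 ± 1.2 kg and BMI at 16.8 ± 1.4 kg/m² over the pooled 12/18-month
  rows.

### What it does not emulate

No raw NMR spectra or dietary-diary text (values arrive already
quantified); no seasonal or daycare effects; no within-infant correlation
in the *residuals* of the endogenous variables across 12 and 18 months
(the two rows share their exogenous covariates and intake propensity but
the model treats rows as independent, mirroring the analysis model); no
age trend in weight under the default preset (the trial prints no
significant age→weight path, so it defaults to zero; consequently the 6/9
month weights come from a separate growth curve and the 12/18-month means
coincide). Passing tests on this generator therefore certify the
*estimators* under the hypothesised data-generating process, not the
behaviour of real cohort data with its messier dependence structure.

## 3. Cumulative intake

The AUC uses the trapezoid rule on the *nominal* visit ages (6, 9, 12, 18
months), not observed ages, since the cumulative-exposure variable is
defined at schedule level. Only infants with records at all four visits
contribute — exclusion, never interpolation. The z-scoring of the protein
AUC is performed over the pooled analysis sample (both interval lengths
together), matching how the variable enters the SEM; because z-scoring is
affine, the standardized SEM coefficients are invariant to this choice.
Protein energy percent uses the 4 kcal/g Atwater factor
(`protein_flags(kcal_per_g = )`); the source convention is not stated, so
the factor is a configurable constant. The 15 E% threshold is strict
(exactly 15.0 E% does not exceed), the 1.05 g/kg/d requirement inclusive.

## 4. Metabolome testing

The generalized log glog(y) = ln(y + √(y² + λ)) with λ = 1 (concentration²
units) stabilises variance and handles zeros. PCA runs on the combined
12/18-month glog panel, centred and unit-scaled; the contribution of
variable j to component k is 100·loading²ⱼₖ (loadings are unit-norm), and
the reference line is the expected mean contribution 100/p. The 95% score
ellipses scale the 2-D score covariance by the bivariate-t (Hotelling)
quantile 2(n−1)/(n−2)·F₀.₉₅(2, n−2), with the χ²₂ quantile as the
large-n/small-n fallback.

The Canberra distance follows the plain sum Σ|xⱼ−yⱼ|/(|xⱼ|+|yⱼ|) with 0/0
terms skipped and *no* rescaling by the number of contributing terms; on
strictly positive data this equals `dist(method = "canberra")`, and common
rescaled variants differ only by a factor that cancels from the PERMANOVA
F ratio. PERMANOVA permutes labels freely (one-factor design, no strata)
and reports p = (1 + #{F^π ≥ F})/(1 + n_perm); an exhaustive mode
enumerates all distinct relabellings for small n. The dispersion check is
the classic principal-coordinate/centroid-distance ANOVA (via
`vegan::betadisper`).

Mann-Whitney tests use the tie-corrected normal approximation with
continuity correction (the common statistics-package default) with an
exact mode for small samples; BH correction is applied across the
52-metabolite family within a timepoint. Because the test is rank-based,
glog cannot change its p-values — asserted as a property test — so
concentrations are reported untransformed. Effect sizes r = |Z|/√n are
classed small/moderate/large at 0.1/0.3/0.5.

## 5. The SEM engine

Models are observed-variable RAM specifications: path matrix B, residual
(co)variance matrix Ψ, implied covariance Σ(θ) = (I−B)⁻¹Ψ(I−B)⁻ᵀ. The
sample covariance uses the n−1 divisor and the test statistic is
T = (n−1)·F_ML (the dominant convention). Estimation minimises F_ML by
BFGS with the analytic gradient tr[(Σ⁻¹ − Σ⁻¹SΣ⁻¹) ∂Σ], started from
per-equation least squares, then polished by damped Newton steps on the
expected information 0.5·tr(Σ⁻¹∂Σⱼ Σ⁻¹∂Σₖ) until the gradient ∞-norm
falls below 10⁻⁶ (configurable). For recursive just-identified models the
least-squares start is already the exact optimum — the engine's primary
correctness oracle is that every path estimate equals its per-equation
OLS coefficient to 10⁻⁶. Non-positive-definite trial points are handled by
assigning a large discrepancy; a non-PD implied covariance at the reported
optimum raises an error rather than returning garbage.

Naive standard errors come from the inverse expected information divided
by n−1. The robust adjustment is the standard sandwich/scaled-statistic
construction for complete data on the vech scale: with Δ = ∂vech(Σ)/∂θ,
V = ½D′(Σ⁻¹⊗Σ⁻¹)D (D the duplication matrix) and Γ the empirical
covariance of vech((xᵢ−x̄)(xᵢ−x̄)′),

* robust covariance: (Δ′VΔ)⁻¹ Δ′VΓVΔ (Δ′VΔ)⁻¹ / (n−1),
* scaling constant: c = tr(UΓ)/df with U = V − VΔ(Δ′VΔ)⁻¹Δ′V,
* scaled statistic: T_scaled = T/c.

Under multivariate normality VΓV → V, so robust and naive standard errors
coincide and c → 1; both limits are asserted in the tests, and a
scale-mixture (heavy multivariate kurtosis) construction checks that the
scaled statistic restores nominal χ² calibration where the raw T
over-rejects.

Fit indices follow the standard closed forms (CFI, TLI, NFI, IFI from the
independence baseline, whose ML solution diag(S) is available in closed
form; GFI/AGFI from the weighted residual quadratic form; RMSEA with its
90% noncentrality-inversion CI; SRMR as the RMS standardized residual
including the diagonal). Robust CFI/TLI/RMSEA substitute the scaled
statistics of the fitted and baseline models. A saturated model reports
incremental indices of 1, RMSEA 0, SRMR 0 and a `saturated` flag.

Modification indices are univariate score statistics: for a parameter γ
fixed at zero, MI = (n−1)·g²/(4H̃) and the expected parameter change is
−g/(2H̃), where g is the gradient of F_ML in γ and H̃ the expected
information of γ partialed for the free parameters (the factor 4 follows
from the Hessian of F_ML being twice the expected information near the
optimum). The tests verify both that an omitted path carries the top MI
and that freeing it drops T by approximately the MI.

Standardized coefficients multiply each path by the model-implied SD ratio
of predictor to outcome; their delta-method standard errors propagate the
robust parameter covariance through a numerically differentiated
standardization map. Significance bands are the conventional ones
(*** p<0.001, ** p<0.01, * p<0.05, † p<0.1).

## 6. The trial models

`build_frame()` applies the published transforms: ln total BCAA (sum of
leucine, isoleucine, valine in µM), ln IGF-1, ln insulin/glucose, pooled
z-scoring of the protein AUC, birth weight in kg (so the covariance matrix
is not dominated by gram-scale variance), and listwise deletion. Binary
covariates enter as numeric 0/1 columns whose variances are model-implied
like any exogenous variable; the 12- and 18-month rows of an infant are
treated as independent with age as a covariate, mirroring the published
analysis — the within-infant clustering is a documented limitation, not
corrected here.

Where the published diagram leaves the model incompletely specified, the
defaults are: the direct IGF-1→outcome path is estimated freely (the
diagram places IGF-1 adjacent to the outcome; `include_igf1_outcome =
FALSE` drops it), and the protein→insulin/glucose path is included because
the results discuss its (non-significant) estimate (`include_prot_insglu =
FALSE` drops it). Exogenous covariates covary freely. Prepregnancy BMI and
formula use sit on the growth equation only, with sex and age on the
mediator equations, as the results text describes. With these defaults
both models have 12 observed variables, 66 free parameters and 12 degrees
of freedom.

Residual diagnostics are simulation-based quantile residuals on the
per-equation Gaussian fits: each observation's randomised rank among
`n_sim` (default 250, minimum 50) simulated responses, followed by a KS
uniformity test, a two-sided dispersion comparison against the simulated
variance distribution, and an exact binomial outlier test on the count of
observations outside the simulation envelope. The published analysis used
mixed-model diagnostics with a random intercept; the fixed-effects version
here is the deliberate, documented substitute consistent with the SEM's
independence treatment of rows.

`group_compare()` implements the trial's comparison conventions, with the
ambiguous "exact binomial test" defaulting to the conditional exact
(hypergeometric) test and a literal one-sample binomial behind
`binary_method = "binomial"`.

## 7. Determinism and problem sizes

A single user-visible seed drives every stage through named substreams
(`stage_seed`), so cohorts, permutation tests and bundles are reproducible
bit for bit; `run_all()` writes the full configuration into the bundle's
provenance block. The test suite exercises parameter recovery on one
cohort of 5000 infants per group; type-I-error calibration with 200
null-panel replicates (Mann-Whitney/BH) and 500 relabelled PERMANOVA runs
at n = 40; engine calibration with 300 χ² simulations at n = 200 and 100
random just-identified models; and clean-fit behaviour of the effect-free
preset over 100 replicates of 200 infants per group — sizes chosen so the
full suite completes in about a minute while keeping Monte-Carlo error
well inside the asserted tolerances.

## 8. Known limitations

* Rows are treated as independent across the two plasma timepoints; no
  cluster-robust or mixed-model correction is applied (matching the
  analysis being reproduced). Robust-ML standard errors address
  non-normality, not clustering.
* The generator's exact-moment construction removes sampling noise from
  the generating coefficients; it is ideal for estimator validation but
  makes the model χ² slightly conservative on generated cohorts.
* The BMI-based mediator coefficients of the reference analysis (0.43 /
  0.17 / 0.16) are not separately embodied; the weight-based values
  generate both outcomes.
* No WHO growth z-scores: absolute weight and BMI are modelled with age
  and sex as covariates, so external reference tables are unnecessary.
* The exact test used for small binary outcomes is conditional on the
  margins; the literal one-sample binomial variant is available but not
  the default.
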