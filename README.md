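# otispath

Protein intake during complementary feeding, the infant plasma metabolome,
and growth: an analysis toolkit around the *Early Protein Hypothesis* — the
proposal that protein intake above physiological need in infancy raises
circulating branched-chain amino acids (BCAAs) and IGF-1, accelerating
weight gain and later obesity risk.

The package is written for nutrition researchers analysing OTIS-style
randomized complementary-feeding trials (two diet groups, 5-day dietary
records at 6/9/12/18 months, a 52-metabolite targeted NMR plasma panel at 12
and 18 months, anthropometry and maternal/neonatal covariates). Because such
cohort data are typically shareable only on request, the package ships a
calibrated synthetic cohort generator so that every analysis stage is
runnable, testable and reproducible without any external data.

## What is implemented

**Synthetic cohort generator** (`otis_preset()`, `null_preset()`,
`solve_error_variances()`, `generate_cohort()`, `apply_dropout()`).
Simulates infants along the hypothesised causal diagram: exogenous
covariates, randomized diet group, per-visit intake trajectories (the
Nordic-diet protein reduction strongest at 12 months, attenuated at 18),
BCAAs driven by recent protein intake, IGF-1 / insulin-to-glucose / weight /
BMI from standardized structural equations, the remaining metabolites as
lognormals with effect-size-classed group shifts, and informative dropout
(~24% vs ~12%). Standardized path coefficients are the *exact* generating
truth: endogenous variables are simulated in standardized space with
residuals orthogonalised against each equation's design, then rescaled to
natural units.

**Cumulative intake** (`cumulative_auc()`, `cumulative_intake()`,
`breastmilk_grams()`, `protein_flags()`). Trapezoid-rule AUC of mean daily
intake over the nominal visit schedule (complete cases only, no
imputation), breastmilk feeds converted at 102 g per meal / 25 g per snack,
and flags against the 1.05 g/kg/d and 15 E% protein recommendations.

**Metabolome group testing** (`glog()`, `pca_combined()`,
`canberra_matrix()`, `permanova()`, `dispersion_homogeneity()`,
`mw_fdr_panel()`). Generalized log transform ln(y + sqrt(y² + λ)); PCA of
the combined 12-/18-month panel with per-variable contributions and 95%
t-ellipses; Canberra-distance PERMANOVA

&nbsp;&nbsp;SS_total = (1/n) Σ_{i&lt;j} d²_ij, F = (SS_between/(g−1)) / (SS_within/(n−g)), p = (1 + #{F^π ≥ F}) / (1 + n_perm)

with a dispersion-homogeneity check; Mann-Whitney U tests (tie-corrected
normal approximation with continuity correction, exact mode for small
samples) with Benjamini-Hochberg correction and Wilcoxon effect sizes
r = |Z|/√n classed small (0.1–0.3) / moderate (0.3–0.5) / large (>0.5).

**Covariance-based SEM engine** (`parse_model()`, `implied_covariance()`,
`fit_ml()`, `robust_adjust()`, `fit_indices()`, `modification_indices()`,
`standardized_solution()`). Observed-variable path models in RAM form,
Σ(θ) = (I−B)⁻¹ Ψ (I−B)⁻ᵀ, fitted by minimising

&nbsp;&nbsp;F_ML(θ) = ln|Σ(θ)| + tr(S Σ(θ)⁻¹) − ln|S| − p

with analytic gradients (quasi-Newton plus Newton polishing). Robust ML:
sandwich standard errors from the empirical fourth-moment matrix and the
scaled statistic T/c with c = tr(UΓ)/df. Fit indices: CFI, TLI, NFI, IFI,
GFI, AGFI, RMSEA with 90% CI, SRMR, and robust variants. Modification
indices as univariate score statistics with expected parameter changes.

**Trial models** (`build_frame()`, `weight_model_spec()`,
`bmi_model_spec()`, `run_sem_pipeline()`, `residual_diagnostics()`,
`group_compare()`, `proxy_validation()`, `run_all()`). The two growth SEMs
(body weight / BMI as outcome; cumulative protein AUC, ln total BCAA, ln
IGF-1, ln insulin-to-glucose, and maternal/neonatal covariates), simulated
quantile-residual diagnostics, the trial's group-comparison conventions,
and a single `run_all()` driver producing a deterministic CSV/TSV/JSON/DOT
bundle.

## Worked example

```r
library(otispath)
preset <- solve_error_variances(otis_preset(n_per_group = 125))
cohort <- apply_dropout(generate_cohort(preset, seed = 2026), preset, seed = 2026)
run_sem_pipeline(cohort, "weight")
```

```
Growth SEM (weight outcome): 440 rows, 220 infants
chi2(12) = 17.693  baseline chi2(66) = 1053.703
CFI 0.994  TLI 0.968  NFI 0.983  IFI 0.995  GFI 0.993  AGFI 0.957
RMSEA 0.033 [0.000, 0.063]  SRMR 0.0202
robust: CFI 0.995  TLI 0.970  RMSEA 0.032 (scaling c = 1.016)
standardized paths:
  weight ~ z_prot_auc          +0.332 [+0.185, +0.478] ***
  weight ~ ln_ins_glu          +0.147 [+0.076, +0.218] ***
  weight ~ birth_weight        +0.388 [+0.316, +0.460] ***
  weight ~ gwg                 -0.103 [-0.182, -0.025] *
  weight ~ excl_bf             -0.143 [-0.228, -0.058] ***
  ln_igf1 ~ z_prot_auc         +0.369 [+0.196, +0.542] ***
  ln_igf1 ~ ln_bcaa            +0.165 [+0.078, +0.252] ***
  ...
```

At the trial's own sample size the fitted cohort reproduces the expected
picture: cumulative protein intake raises IGF-1 (β ≈ 0.37) and, after
accounting for the metabolite-mediated paths, still raises body weight
(β ≈ 0.33); birth weight (β ≈ 0.39) and the insulin-to-glucose ratio
(β ≈ 0.15) contribute positively, gestational weight gain and
breastfeeding duration negatively. The metabolome side behaves likewise:

```r
rows12 <- subset(cohort, visit_age == 12 & !is.na(m_leucine))
D <- canberra_matrix(glog(as.matrix(rows12[, grep("^m_", names(rows12))])))
pm <- permanova(D, rows12$group, n_perm = 999, seed = 2026)
pm$dispersion_p <- dispersion_homogeneity(D, rows12$group)
pm
```

```
PERMANOVA: pseudo-F = 5.951, R2 = 0.0247, p = 0.001 (999 permutations)
  dispersion homogeneity p = 0.925
```

a small but clearly significant 12-month group separation with homogeneous
dispersion, and `mw_fdr_panel(...)` flags the BCAAs, urea, their
catabolites and dimethyl sulfone as lower — and betaine, glycine and
dimethylamine as higher — under the reduced-protein diet.

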