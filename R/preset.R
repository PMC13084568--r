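#' Plasma metabolite panel schema
#'
#' The 52 polar metabolites quantified in infant plasma by targeted 1H-NMR,
#' with typical plasma concentrations (micromolar), lognormal spreads, and
#' the diet-group effect programmed into the synthetic cohort at each
#' timepoint. Directions are coded relative to the Nordic (reduced-protein)
#' group: \code{-1} = lower under the Nordic diet, \code{+1} = higher,
#' \code{0} = no group effect. Effect magnitudes are expressed as target
#' Wilcoxon effect sizes r (see \code{\link{mw_fdr_panel}} for the class
#' boundaries) and converted to log-scale location shifts at generation time.
#' The three branched-chain amino acids carry \code{NA} effects here: their
#' group difference is not an additive shift but emerges mechanically from
#' the protein-intake trajectories through the protein-to-BCAA link.
#'
#' @return A data.frame with one row per metabolite: \code{name},
#'   \code{column} (sanitised cohort column name), \code{mean_uM},
#'   \code{sdlog}, \code{dir12}, \code{r12}, \code{dir18}, \code{r18}.
#' @export
metabolite_schema <- function() {
  nm <- c("leucine", "isoleucine", "valine", "alanine", "glycine", "serine",
          "threonine", "lysine", "methionine", "histidine", "phenylalanine",
          "tyrosine", "tryptophan", "asparagine", "aspartate", "glutamine",
          "glutamate", "arginine", "proline", "ornithine", "citrulline",
          "taurine", "creatine", "creatinine", "carnitine", "acetylcarnitine",
          "betaine", "choline", "dimethylamine", "dimethylglycine",
          "dimethyl sulfone", "sarcosine", "urea", "glucose", "lactate",
          "pyruvate", "citrate", "succinate", "fumarate", "formate",
          "acetate", "acetone", "3-hydroxybutyrate", "2-hydroxybutyrate",
          "3-hydroxyisobutyrate", "2-ketoisovalerate", "2-ketoisocaproate",
          "3-methyl-2-oxovalerate", "myo-inositol", "mannose", "galactose",
          "hypoxanthine")
  stopifnot(length(nm) == 52L)
  mean_uM <- c(110, 55, 210, 350, 230, 120, 130, 160, 25, 80, 60, 70, 60,
               50, 15, 550, 60, 80, 180, 60, 30, 60, 40, 40, 35, 8, 40, 10,
               3, 3, 4, 2, 4500, 4800, 1800, 70, 110, 6, 2, 25, 40, 20, 60,
               30, 15, 12, 25, 15, 25, 40, 60, 5)
  schema <- data.frame(
    name = nm,
    column = paste0("m_", gsub("[^a-z0-9]+", "_", tolower(nm))),
    mean_uM = mean_uM,
    sdlog = 0.25,
    dir12 = 0, r12 = 0, dir18 = 0, r18 = 0,
    stringsAsFactors = FALSE
  )
  bcaa <- c("leucine", "isoleucine", "valine")
  # BCAA group difference arises through the protein -> BCAA link
  schema[schema$name %in% bcaa, c("dir12", "r12", "dir18", "r18")] <- NA
  lower_mod <- "urea"
  lower_small <- c("dimethyl sulfone", "lysine", "threonine",
                   "2-ketoisovalerate", "2-ketoisocaproate",
                   "2-hydroxybutyrate", "3-hydroxyisobutyrate", "carnitine")
  higher_small <- c("glycine", "betaine", "dimethylamine")
  set_eff <- function(s, names, dir, r12, r18) {
    i <- s$name %in% names
    s$dir12[i] <- dir; s$r12[i] <- r12
    s$dir18[i] <- dir; s$r18[i] <- r18
    s
  }
  # within-class effect sizes sit at the upper-middle of each band: the
  # signature was detected at the trial's sample size, so the generating
  # truth must be detectably inside its class
  schema <- set_eff(schema, lower_mod, -1, 0.35, 0.17)
  schema <- set_eff(schema, lower_small, -1, 0.28, 0.14)
  schema <- set_eff(schema, higher_small, +1, 0.28, 0.14)
  schema
}

#' Trial-calibrated generative preset
#'
#' Builds the synthetic-cohort "truth": standardized structural path
#' coefficients equal to the published SEM estimates of the OTIS
#' complementary-feeding trial, exogenous moments matching the trial's
#' baseline table, group-specific protein/energy/fruit-and-vegetable
#' trajectories (with the Nordic reduction strongest at 12 mo and attenuated
#' at 18 mo, mirroring waning adherence), metabolite group shifts by Wilcoxon
#' effect-size class, and a dropout model reproducing the reported 24% vs 12%
#' attrition.
#'
#' Standardized coefficients are the generating truth: endogenous variables
#' are simulated in standardized space and affinely rescaled to natural
#' units, so a correctly specified SEM recovers the printed betas.
#' Paths the trial reported as non-significant without printing a magnitude
#' default to zero; the sex effect on IGF-1 (reported significant, boys
#' lower, magnitude unprinted) is set to -0.15. All structural coefficients
#' can be overridden through \code{structural}.
#'
#' @param n_per_group infants per diet group (trial: 125).
#' @param seed default RNG seed carried by the preset.
#' @param structural optional named numeric vector overriding individual
#'   structural coefficients (names like \code{"z_prot_auc->ln_igf1"}).
#' @return An object of class \code{otis_preset}.
#' @seealso \code{\link{null_preset}}, \code{\link{solve_error_variances}},
#'   \code{\link{generate_cohort}}
#' @export
otis_preset <- function(n_per_group = 125, seed = 20250601, structural = NULL) {
  coefs <- c(
    # IGF-1 equation (weight-based model values; see vignette)
    "z_prot_auc->ln_igf1"  = 0.40,
    "ln_bcaa->ln_igf1"     = 0.16,
    "sex->ln_igf1"         = -0.15,
    "age18->ln_igf1"       = 0,
    # insulin-to-glucose equation
    "ln_bcaa->ln_ins_glu"    = 0.15,
    "z_prot_auc->ln_ins_glu" = 0,
    "sex->ln_ins_glu"        = 0,
    "age18->ln_ins_glu"      = 0,
    # weight outcome
    "z_prot_auc->weight"   = 0.36,
    "ln_ins_glu->weight"   = 0.13,
    "ln_igf1->weight"      = 0,
    "birth_weight->weight" = 0.39,
    "gwg->weight"          = -0.11,
    "excl_bf->weight"      = -0.16,
    "maternal_bmi->weight" = 0,
    "any_formula->weight"  = 0,
    "sex->weight"          = 0,
    "age18->weight"        = 0,
    # BMI outcome
    "z_prot_auc->bmi"   = 0,
    "ln_ins_glu->bmi"   = 0.14,
    "ln_igf1->bmi"      = 0,
    "birth_weight->bmi" = 0.32,
    "gwg->bmi"          = 0,
    "excl_bf->bmi"      = 0,
    "maternal_bmi->bmi" = 0,
    "any_formula->bmi"  = 0,
    "sex->bmi"          = 0,
    "age18->bmi"        = -0.40
  )
  if (!is.null(structural)) {
    unknown <- setdiff(names(structural), names(coefs))
    if (length(unknown))
      stop("unknown structural coefficient(s): ", paste(unknown, collapse = ", "))
    coefs[names(structural)] <- structural
  }
  preset <- structure(list(
    n_per_group = as.integer(n_per_group),
    seed = as.integer(seed),
    structural_coefficients = coefs,
    # assumed exogenous correlation between cumulative-protein z and ln BCAA
    # used by the preset-level variance solver (the generator recomputes the
    # realised value); everything else exogenous is uncorrelated by design.
    prot_bcaa_cor = 0.40,
    # link between recent (same-visit) protein and the shared BCAA factor
    bcaa_protein_r = 0.45,
    # common-factor loading giving pairwise BCAA correlations ~ rho^2
    bcaa_intercor_rho = 0.98,
    bcaa_sdlog = 0.18,
    exogenous_moments = list(
      birth_weight_g  = c(mean = 3620, sd = 460),
      maternal_bmi    = c(mean = 24, sd = 3.8),
      maternal_age    = c(mean = 31, sd = 4.7),
      gwg_kg          = c(mean = 14, sd = 5),
      excl_bf_months  = c(mean = 4.1, sd = 1.4),
      p_female        = 0.45,
      p_any_formula   = 0.30,
      p_bf_at_enroll  = 0.77,
      enroll_age_mo   = c(mean = 4.5, sd = 0.5)
    ),
    protein_trajectory = list(
      visits = c(6, 9, 12, 18),
      conventional = c(14, 26, 33, 38),              # g/d
      nordic_ratio = c(1, 0.74, 0.71, 0.83),         # 26/29/17% reductions
      sdlog = 0.22,          # between-record spread on the log scale
      infant_share = 0.55    # share of log-variance at the infant level
    ),
    energy_trajectory = list(mean = c(700, 850, 980, 1100), sdlog = 0.13),
    fruit_veg_trajectory = list(
      conventional = c(40, 90, 120, 130),
      nordic = c(90, 180, 225, 170),
      sdlog = 0.35
    ),
    fat_energy_share = 0.35,
    breastfeeding = list(
      visits = c(6, 9, 12, 18),
      p_any = list(nordic = c(0.71, 0.39, 0.20, 0.08),
                   conventional = c(0.71, 0.39, 0.20, 0.02)),
      meal_lambda = c(3, 2, 1, 0.5),
      snack_lambda = c(1.5, 1, 0.5, 0.25)
    ),
    scales = list(
      weight   = c(mean = 10.8, sd = 1.2),     # kg, 12/18 mo pooled
      bmi      = c(mean = 16.8, sd = 1.4),     # kg/m^2
      igf1     = c(meanlog = log(55), sdlog = 0.35),   # ng/mL
      ins_glu  = c(meanlog = log(1.25), sdlog = 0.45), # ratio
      glucose  = c(meanlog = log(4.8), sdlog = 0.08),  # mmol/L
      folate   = list(nordic = c(meanlog = log(22), sdlog = 0.30),
                      conventional = c(meanlog = log(17), sdlog = 0.30)),
      weight_early = c(7.9, 9.1),   # 6 and 9 mo means, kg
      bmi_early    = c(17.2, 17.4),
      fmi          = c(mean = 3.8, sd = 0.9),  # kg/m^2
      ffm          = c(mean = 8.3, sd = 0.9),  # kg
      fm           = c(mean = 2.6, sd = 0.8)   # kg
    ),
    body_comp_cor = list(fmi_bmi = 0.70, ffm_prot = c(`12` = 0.20, `18` = 0.05),
                         fm_prot = c(`12` = 0.00, `18` = 0.19)),
    metabolites = metabolite_schema(),
    dropout_logit = list(
      coef = c(maternal_bmi = 0.40, maternal_age = -0.40, bf_at_enroll = -0.50),
      rate = c(nordic = 0.24, conventional = 0.12)
    ),
    error_variances = NULL
  ), class = "otis_preset")
  validate_preset(preset)
  preset
}

#' Null (effect-free) generative preset
#'
#' Same machinery as \code{\link{otis_preset}} with every group effect and
#' every structural coefficient except the protein-to-BCAA link removed:
#' identical diet trajectories in both groups, no metabolite shifts, no
#' folate or breastfeeding group difference, no structural paths, and a
#' group-blind dropout model. Used for type-I-error and fit-index
#' calibration.
#'
#' @inheritParams otis_preset
#' @param keep_bcaa_link keep the recent-protein to BCAA correlation
#'   (default \code{TRUE}; it is not a group effect).
#' @return An object of class \code{otis_preset}.
#' @export
null_preset <- function(n_per_group = 125, seed = 20250601,
                        keep_bcaa_link = TRUE) {
  p <- otis_preset(n_per_group = n_per_group, seed = seed)
  p$structural_coefficients[] <- 0
  p$prot_bcaa_cor <- if (keep_bcaa_link) 0.40 else 0
  if (!keep_bcaa_link) p$bcaa_protein_r <- 0
  p$protein_trajectory$nordic_ratio <- rep(1, 4)
  p$fruit_veg_trajectory$nordic <- p$fruit_veg_trajectory$conventional
  p$breastfeeding$p_any$nordic <- p$breastfeeding$p_any$conventional
  p$scales$folate$nordic <- p$scales$folate$conventional
  m <- p$metabolites
  m[, c("dir12", "r12", "dir18", "r18")] <- 0
  bcaa <- m$name %in% c("leucine", "isoleucine", "valine")
  m[bcaa, c("dir12", "r12", "dir18", "r18")] <- NA
  p$metabolites <- m
  p$dropout_logit$rate <- c(nordic = 0.18, conventional = 0.18)
  validate_preset(p)
  p
}

validate_preset <- function(preset) {
  co <- preset$structural_coefficients
  if (any(abs(co) >= 1))
    stop(infeasible_preset("standardized structural coefficients must lie in (-1, 1)"))
  if (!is.null(preset$error_variances) && any(preset$error_variances < 0))
    stop(infeasible_preset("negative residual variance in preset"))
  r <- preset$dropout_logit$rate
  if (any(r < 0 | r > 1)) stop("dropout rates must lie in [0, 1]")
  stopifnot(nrow(preset$metabolites) == 52L)
  invisible(preset)
}

# named list: for each endogenous variable, the named coefficient vector of
# its structural parents (zeros kept so the generator can orthogonalise
# residuals against the full equation).
structural_equations <- function(preset) {
  co <- preset$structural_coefficients
  out <- list()
  for (nm in names(co)) {
    parts <- strsplit(nm, "->", fixed = TRUE)[[1]]
    out[[parts[2]]] <- c(out[[parts[2]]], stats::setNames(co[[nm]], parts[1]))
  }
  out[c("ln_igf1", "ln_ins_glu", "weight", "bmi")]
}

#' Solve standardized residual variances of the preset
#'
#' Path-traces the recursive structural system in standardized space and
#' sets each endogenous residual variance so that the marginal variance of
#' every endogenous variable equals 1. Exogenous variables are standardized
#' with the correlation structure assumed by the preset (only the
#' cumulative-protein / ln-BCAA correlation is non-zero by default); an
#' explicit correlation matrix over the structural regressors can be
#' supplied instead, which is what \code{\link{generate_cohort}} does with
#' the realised sample correlations.
#'
#' @param preset an \code{otis_preset}.
#' @param exog_cor optional correlation matrix over the exogenous structural
#'   regressors (dimnames must name them).
#' @return The preset with \code{error_variances} filled in (named numeric,
#'   one entry per endogenous variable). Errors with condition class
#'   \code{otispath_infeasible_preset} if any residual variance would be
#'   negative.
#' @export
solve_error_variances <- function(preset, exog_cor = NULL) {
  stopifnot(inherits(preset, "otis_preset"))
  eqs <- structural_equations(preset)
  exog <- unique(unlist(lapply(eqs, names)))
  exog <- setdiff(exog, names(eqs))
  if (is.null(exog_cor)) {
    exog_cor <- diag(length(exog))
    dimnames(exog_cor) <- list(exog, exog)
    if (all(c("z_prot_auc", "ln_bcaa") %in% exog)) {
      exog_cor["z_prot_auc", "ln_bcaa"] <-
        exog_cor["ln_bcaa", "z_prot_auc"] <- preset$prot_bcaa_cor
    }
  }
  stopifnot(all(exog %in% rownames(exog_cor)))
  C <- exog_cor[exog, exog, drop = FALSE]
  psi <- numeric(0)
  for (y in names(eqs)) {
    b <- eqs[[y]]
    pa <- names(b)
    stopifnot(all(pa %in% rownames(C)))
    expl <- drop(t(b) %*% C[pa, pa, drop = FALSE] %*% b)
    if (expl >= 1)
      stop(infeasible_preset(sprintf(
        "explained variance of '%s' is %.3f >= 1", y, expl)))
    psi[y] <- 1 - expl
    # extend the traced covariance with the new endogenous variable
    cov_y <- drop(C[, pa, drop = FALSE] %*% b)
    C <- rbind(cbind(C, cov_y), c(cov_y, 1))
    rownames(C)[nrow(C)] <- colnames(C)[ncol(C)] <- y
  }
  preset$error_variances <- psi
  validate_preset(preset)
  preset
}

#' @export
print.otis_preset <- function(x, ...) {
  co <- x$structural_coefficients
  cat("OTIS-style generative preset\n")
  cat("  infants per group:", x$n_per_group, " seed:", x$seed, "\n")
  cat("  non-zero structural coefficients:\n")
  nz <- co[co != 0]
  for (nm in names(nz)) cat(sprintf("    %-24s %+.2f\n", nm, nz[[nm]]))
  n_eff <- sum(x$metabolites$r12 > 0, na.rm = TRUE)
  cat("  metabolites with a 12-mo group shift:", n_eff,
      "(+ 3 BCAAs via the protein link)\n")
  if (!is.null(x$error_variances)) {
    cat("  solved residual variances:\n")
    for (nm in names(x$error_variances))
      cat(sprintf("    %-12s %.3f\n", nm, x$error_variances[[nm]]))
  }
  invisible(x)
}
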