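# Convert a target Wilcoxon effect size r into a log-scale location shift.
# For two equal normal samples shifted by delta*sigma the rank-test Z grows
# like (AUC - 1/2)*sqrt(3N) with AUC = Phi(delta/sqrt(2)), so
# r = |Z|/sqrt(N) = sqrt(3) * (AUC - 1/2).
r_to_shift <- function(r, sdlog) {
  stopifnot(all(r >= 0 & r < sqrt(3) / 2))
  auc <- 0.5 + r / sqrt(3)
  sqrt(2) * stats::qnorm(auc) * sdlog
}

rtruncnorm1 <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

# Residual draw made exactly orthogonal to the design and rescaled so the
# generated standardized endogenous variable has sample variance exactly 1
# (exact-moment simulation; same spirit as mvrnorm(empirical = TRUE)).
orthogonal_residual <- function(X, psi, n) {
  e <- stats::rnorm(n)
  e <- stats::lm.fit(cbind(1, X), e)$residuals
  e / stats::sd(e) * sqrt(psi)
}

# Generate one standardized endogenous column from its structural equation.
# X holds the realised standardized parents (all candidate regressors of the
# equation, zero coefficients included so the residual is orthogonal to the
# full design and every generating coefficient -- including the zeros -- is
# the exact in-sample truth).
gen_endogenous <- function(b, X) {
  C <- stats::cov(X)
  expl <- drop(t(b) %*% C %*% b)
  if (expl >= 1)
    stop(infeasible_preset(sprintf("explained variance %.3f >= 1", expl)))
  drop(X %*% b) + orthogonal_residual(X, 1 - expl, nrow(X))
}

#' Simulate an OTIS-like cohort
#'
#' Generates a complete synthetic cohort under a generative preset: one row
#' per infant and scheduled visit (6, 9, 12, 18 mo), with enrollment
#' covariates carried on every row. Simulation proceeds causally: exogenous
#' covariates, randomized diet group, per-visit dietary trajectories (the
#' Nordic protein reduction strongest at 12 mo, attenuated at 18 mo),
#' branched-chain amino acids driven by recent protein intake, then IGF-1,
#' insulin-to-glucose ratio, weight and BMI from the standardized structural
#' equations, and finally the remaining metabolites as lognormals with
#' group shifts. Endogenous variables are simulated with exact sample
#' moments (residuals orthogonalised against each equation's design), so the
#' preset's standardized coefficients are the exact generating truth.
#'
#' @param preset an \code{\link{otis_preset}} (solved or unsolved; residual
#'   variances are recomputed from the realised regressor covariances).
#' @param seed integer seed; defaults to the preset's seed. Two calls with
#'   the same preset and seed return identical tables.
#' @return A data.frame of class \code{otis_cohort}; see the column
#'   dictionary in the package vignette. Plasma variables are only measured
#'   at the 12- and 18-mo visits (\code{NA} elsewhere).
#' @export
generate_cohort <- function(preset, seed = NULL) {
  stopifnot(inherits(preset, "otis_preset"))
  seed <- seed %||% preset$seed
  n <- 2L * preset$n_per_group
  em <- preset$exogenous_moments

  ## -- infants and enrollment covariates ---------------------------------
  set.seed(stage_seed(seed, "infants"))
  inf <- data.frame(
    infant_id = seq_len(n),
    group = rep(c("nordic", "conventional"), each = preset$n_per_group),
    sex = ifelse(stats::runif(n) < em$p_female, "female", "male"),
    enroll_age_mo = round(rtruncnorm1(n, em$enroll_age_mo["mean"],
                                      em$enroll_age_mo["sd"], 3.5, 6), 1),
    birth_weight_g = round(rtruncnorm1(n, em$birth_weight_g["mean"],
                                       em$birth_weight_g["sd"], 2500, 5500)),
    maternal_bmi = round(rtruncnorm1(n, em$maternal_bmi["mean"],
                                     em$maternal_bmi["sd"], 16, 45), 1),
    maternal_age = round(rtruncnorm1(n, em$maternal_age["mean"],
                                     em$maternal_age["sd"], 18, 48), 1),
    gwg_kg = round(rtruncnorm1(n, em$gwg_kg["mean"], em$gwg_kg["sd"], 0, 35), 1),
    excl_bf_months = round(rtruncnorm1(n, em$excl_bf_months["mean"],
                                       em$excl_bf_months["sd"], 0, 6), 1),
    stringsAsFactors = FALSE
  )
  # formula use is more likely after short exclusive breastfeeding
  p_formula <- stats::plogis(stats::qlogis(em$p_any_formula) -
                               0.8 * zscore(inf$excl_bf_months))
  inf$any_formula <- as.integer(stats::runif(n) < p_formula)
  inf$bf_at_enroll <- as.integer(stats::runif(n) < em$p_bf_at_enroll)

  ## -- dietary trajectories ----------------------------------------------
  set.seed(stage_seed(seed, "diet"))
  tr <- preset$protein_trajectory
  visits <- tr$visits
  nv <- length(visits)
  P_i <- stats::rnorm(n)                      # infant-level intake propensity
  lam <- tr$infant_share
  long <- data.frame(
    infant_id = rep(inf$infant_id, each = nv),
    visit_age = rep(visits, times = n)
  )
  long <- merge(long, inf, by = "infant_id", sort = TRUE)
  long <- long[order(long$infant_id, long$visit_age), ]
  rownames(long) <- NULL
  vi <- match(long$visit_age, visits)
  base <- ifelse(long$group == "nordic",
                 tr$conventional[vi] * tr$nordic_ratio[vi],
                 tr$conventional[vi])
  Pl <- rep(P_i, each = nv)
  eps <- stats::rnorm(n * nv)
  long$protein_g <- base * exp(tr$sdlog * (sqrt(lam) * Pl + sqrt(1 - lam) * eps))
  et <- preset$energy_trajectory
  E_i <- 0.5 * P_i + sqrt(0.75) * stats::rnorm(n)
  long$energy_kcal <- et$mean[vi] *
    exp(et$sdlog * (sqrt(lam) * rep(E_i, each = nv) +
                      sqrt(1 - lam) * stats::rnorm(n * nv)))
  fat_kcal <- preset$fat_energy_share * long$energy_kcal *
    exp(0.10 * stats::rnorm(n * nv))
  long$fat_g <- fat_kcal / 9
  long$carb_g <- pmax((long$energy_kcal - 4 * long$protein_g - fat_kcal) / 4,
                      5)
  fv <- preset$fruit_veg_trajectory
  fv_base <- ifelse(long$group == "nordic", fv$nordic[vi], fv$conventional[vi])
  long$fruit_veg_g <- fv_base * exp(fv$sdlog * stats::rnorm(n * nv))

  ## -- breastfeeding ------------------------------------------------------
  set.seed(stage_seed(seed, "breastmilk"))
  bf <- preset$breastfeeding
  u_wean <- stats::runif(n)                # one latent weaning draw -> monotone
  p_any <- ifelse(long$group == "nordic",
                  unlist(bf$p_any["nordic"])[vi],
                  unlist(bf$p_any["conventional"])[vi])
  any_bf <- rep(u_wean, each = nv) < p_any
  long$bm_meals <- ifelse(any_bf, stats::rpois(n * nv, bf$meal_lambda[vi]), 0L)
  long$bm_snacks <- ifelse(any_bf, stats::rpois(n * nv, bf$snack_lambda[vi]), 0L)
  long$any_bf <- as.integer(any_bf | long$bm_meals + long$bm_snacks > 0)

  ## -- cumulative intake and structural regressors -----------------------
  auc12 <- cumulative_auc(long, "protein_g", 12)
  auc18 <- cumulative_auc(long, "protein_g", 18)
  plasma <- long$visit_age %in% c(12, 18)
  idx12 <- which(long$visit_age == 12)
  idx18 <- which(long$visit_age == 18)
  auc_row <- numeric(nrow(long))
  auc_row[idx12] <- auc12$auc[match(long$infant_id[idx12], auc12$infant_id)]
  auc_row[idx18] <- auc18$auc[match(long$infant_id[idx18], auc18$infant_id)]
  rows <- which(plasma)
  z_prot <- zscore(auc_row[rows])          # pooled over the analysis rows
  z_recent <- zscore(log(long$protein_g[rows]))
  nr <- length(rows)

  ## -- branched-chain amino acids ----------------------------------------
  set.seed(stage_seed(seed, "bcaa"))
  a <- preset$bcaa_protein_r
  f <- a * z_recent + sqrt(1 - a^2) * stats::rnorm(nr)
  rho <- preset$bcaa_intercor_rho
  sb <- preset$bcaa_sdlog
  sch <- preset$metabolites
  bcaa_names <- c("leucine", "isoleucine", "valine")
  bcaa <- sapply(bcaa_names, function(b) {
    mu <- log(sch$mean_uM[sch$name == b])
    exp(mu + sb * (rho * f + sqrt(1 - rho^2) * stats::rnorm(nr)))
  })
  ln_bcaa <- zscore(log(rowSums(bcaa)))

  ## -- structural equations (standardized space) -------------------------
  set.seed(stage_seed(seed, "structural"))
  sx <- zscore(as.integer(long$sex[rows] == "male"))
  ag <- zscore(as.integer(long$visit_age[rows] == 18))
  bw <- zscore(long$birth_weight_g[rows])
  gw <- zscore(long$gwg_kg[rows])
  mb <- zscore(long$maternal_bmi[rows])
  eb <- zscore(long$excl_bf_months[rows])
  fo <- zscore(long$any_formula[rows])
  eqs <- structural_equations(preset)
  reg <- list(z_prot_auc = z_prot, ln_bcaa = ln_bcaa, sex = sx, age18 = ag,
              birth_weight = bw, gwg = gw, maternal_bmi = mb,
              excl_bf = eb, any_formula = fo)
  endo <- list()
  for (y in names(eqs)) {
    b <- eqs[[y]]
    X <- do.call(cbind, c(reg, endo)[names(b)])
    endo[[y]] <- gen_endogenous(b, X)
  }

  ## -- natural units ------------------------------------------------------
  set.seed(stage_seed(seed, "anthropometry"))
  sc <- preset$scales
  long$igf1_ngml <- NA_real_
  long$igf1_ngml[rows] <- exp(sc$igf1["meanlog"] + sc$igf1["sdlog"] * endo$ln_igf1)
  glucose <- exp(sc$glucose["meanlog"] + sc$glucose["sdlog"] * stats::rnorm(nr))
  ins_glu <- exp(sc$ins_glu["meanlog"] + sc$ins_glu["sdlog"] * endo$ln_ins_glu)
  long$glucose_mmoll <- NA_real_; long$glucose_mmoll[rows] <- glucose
  long$insulin_miul <- NA_real_; long$insulin_miul[rows] <- ins_glu * glucose
  fol <- sc$folate
  fol_ml <- ifelse(long$group[rows] == "nordic",
                   fol$nordic["meanlog"], fol$conventional["meanlog"])
  long$folate_nmoll <- NA_real_
  long$folate_nmoll[rows] <- exp(fol_ml + fol$nordic["sdlog"] * stats::rnorm(nr))

  long$weight_kg <- NA_real_
  long$bmi <- NA_real_
  long$weight_kg[rows] <- sc$weight["mean"] + sc$weight["sd"] * endo$weight
  long$bmi[rows] <- sc$bmi["mean"] + sc$bmi["sd"] * endo$bmi
  early <- which(!plasma)
  ei <- match(long$visit_age[early], c(6, 9))
  long$weight_kg[early] <- sc$weight_early[ei] *
    exp(0.08 * (0.6 * rep(zscore(inf$birth_weight_g), each = nv)[early] +
                  0.8 * stats::rnorm(length(early))))
  long$bmi[early] <- sc$bmi_early[ei] + 1.3 * stats::rnorm(length(early))
  long$length_cm <- 100 * sqrt(long$weight_kg / long$bmi)

  ## -- body composition (measurement subset proxies) ---------------------
  set.seed(stage_seed(seed, "bodycomp"))
  bc <- preset$body_comp_cor
  age_chr <- as.character(long$visit_age[rows])
  r_ffm <- unname(bc$ffm_prot[age_chr])
  r_fm <- unname(bc$fm_prot[age_chr])
  # body-composition correlations are reported per timepoint, so the protein
  # driver is standardized within each visit stratum
  z_prot_tp <- stats::ave(auc_row[rows], age_chr, FUN = zscore)
  long$fmi <- NA_real_
  long$fmi[rows] <- sc$fmi["mean"] + sc$fmi["sd"] *
    (bc$fmi_bmi * endo$bmi + sqrt(1 - bc$fmi_bmi^2) * stats::rnorm(nr))
  long$fat_free_mass_kg <- NA_real_
  long$fat_free_mass_kg[rows] <- sc$ffm["mean"] + sc$ffm["sd"] *
    (r_ffm * z_prot_tp + sqrt(1 - r_ffm^2) * stats::rnorm(nr))
  long$fat_mass_kg <- NA_real_
  long$fat_mass_kg[rows] <- sc$fm["mean"] + sc$fm["sd"] *
    (r_fm * z_prot_tp + sqrt(1 - r_fm^2) * stats::rnorm(nr))

  ## -- metabolite panel ---------------------------------------------------
  set.seed(stage_seed(seed, "metabolites"))
  M <- matrix(NA_real_, nrow(long), nrow(sch),
              dimnames = list(NULL, sch$column))
  M[rows, paste0("m_", bcaa_names)] <- bcaa
  nordic <- long$group[rows] == "nordic"
  at18 <- long$visit_age[rows] == 18
  for (k in seq_len(nrow(sch))) {
    if (sch$name[k] %in% bcaa_names) next
    dir <- ifelse(at18, sch$dir18[k], sch$dir12[k])
    r <- ifelse(at18, sch$r18[k], sch$r12[k])
    shift <- ifelse(nordic, dir * r_to_shift(r, sch$sdlog[k]), 0)
    M[rows, sch$column[k]] <-
      exp(log(sch$mean_uM[k]) + shift + sch$sdlog[k] * stats::rnorm(nr))
  }
  long <- cbind(long, as.data.frame(M))

  long$dropped_out <- 0L
  long$dropout_visit <- NA_real_
  structure(long, class = c("otis_cohort", "data.frame"),
            preset_seed = seed)
}

#' Apply informative dropout to a cohort
#'
#' Marks infants lost to follow-up through a logistic model on maternal BMI
#' (higher risk), maternal age (lower), breastfeeding at enrollment (lower)
#' and diet group, with group-specific intercepts calibrated so the expected
#' attrition matches the preset's target rates (trial: 24\% Nordic, 12\%
#' conventional). All measurement columns after the dropout visit are set to
#' \code{NA}; enrollment covariates are retained.
#'
#' @param cohort an \code{otis_cohort}.
#' @param preset the generating preset (its \code{dropout_logit} element is
#'   used).
#' @param seed integer seed.
#' @return The cohort with \code{dropped_out} and \code{dropout_visit}
#'   filled in and post-dropout measurements blanked.
#' @export
apply_dropout <- function(cohort, preset, seed = NULL) {
  stopifnot(inherits(cohort, "otis_cohort"))
  seed <- seed %||% preset$seed
  set.seed(stage_seed(seed, "dropout"))
  dl <- preset$dropout_logit
  inf <- cohort[!duplicated(cohort$infant_id), ]
  co <- dl$coef
  eta <- co["maternal_bmi"] * zscore(inf$maternal_bmi) +
    co["maternal_age"] * zscore(inf$maternal_age) +
    co["bf_at_enroll"] * (inf$bf_at_enroll - mean(inf$bf_at_enroll))
  drop_p <- numeric(nrow(inf))
  for (g in unique(inf$group)) {
    target <- dl$rate[[g]]
    i <- inf$group == g
    b0 <- if (all(co == 0)) stats::qlogis(target) else
      stats::uniroot(function(b) mean(stats::plogis(b + eta[i])) - target,
                     c(-15, 15))$root
    drop_p[i] <- stats::plogis(b0 + eta[i])
  }
  dropped <- stats::runif(nrow(inf)) < drop_p
  dv <- sample(c(9, 12, 18), nrow(inf), replace = TRUE,
               prob = c(0.3, 0.4, 0.3))
  inf_drop <- inf$infant_id[dropped]
  cohort$dropped_out <- as.integer(cohort$infant_id %in% inf_drop)
  cohort$dropout_visit <- ifelse(cohort$dropped_out == 1L,
                                 dv[match(cohort$infant_id, inf$infant_id)],
                                 NA_real_)
  meas <- c("protein_g", "carb_g", "fat_g", "energy_kcal", "fruit_veg_g",
            "bm_meals", "bm_snacks", "any_bf", "weight_kg", "length_cm",
            "bmi", "igf1_ngml", "insulin_miul", "glucose_mmoll",
            "folate_nmoll", "fmi", "fat_free_mass_kg", "fat_mass_kg",
            grep("^m_", names(cohort), value = TRUE))
  gone <- cohort$dropped_out == 1L & cohort$visit_age > cohort$dropout_visit
  cohort[gone, meas] <- NA
  cohort
}

#' @export
print.otis_cohort <- function(x, ...) {
  cat("Synthetic complementary-feeding cohort:",
      length(unique(x$infant_id)), "infants x",
      length(unique(x$visit_age)), "visits\n")
  cat("  groups:", paste(sprintf("%s=%d", names(table(x$group[!duplicated(x$infant_id)])),
                                 table(x$group[!duplicated(x$infant_id)])), collapse = ", "), "\n")
  cat("  dropped out:", sum(x$dropped_out[!duplicated(x$infant_id)]), "infants\n")
  cat("  columns:", ncol(x), "(", sum(grepl("^m_", names(x))), "metabolites )\n")
  invisible(x)
}
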