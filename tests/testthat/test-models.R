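test_that("the analysis frame applies the documented transforms", {
  co <- trial_cohort(n_per_group = 80)
  fr <- build_frame(co)
  expect_s3_class(fr, "otis_frame")
  expect_setequal(unique(fr$age), c(12, 18))
  i <- 1
  row <- co[co$infant_id == fr$infant_id[i] & co$visit_age == fr$age[i], ]
  expect_equal(fr$ln_bcaa[i],
               log(row$m_leucine + row$m_isoleucine + row$m_valine))
  expect_equal(fr$ln_igf1[i], log(row$igf1_ngml))
  expect_equal(fr$ln_ins_glu[i],
               log(row$insulin_miul / row$glucose_mmoll))
  expect_equal(fr$birth_weight[i], row$birth_weight_g / 1000)
  expect_equal(mean(fr$z_prot_auc), 0, tolerance = 1e-12)
  expect_equal(sd(fr$z_prot_auc), 1, tolerance = 1e-12)
})

test_that("infants with incomplete diet records are excluded from the frame", {
  co <- trial_cohort(n_per_group = 40)
  victim <- co$infant_id[1]
  co2 <- co[!(co$infant_id == victim & co$visit_age == 9), ]
  class(co2) <- class(co)
  fr <- build_frame(co2)
  expect_false(victim %in% fr$infant_id)
  expect_equal(nrow(fr), (2 * 40 - 1) * 2)
})

test_that("model specifications differ only in the outcome and are over-identified", {
  w <- weight_model_spec()
  b <- bmi_model_spec()
  expect_length(w$variables, 12L)   # 11 regressors plus the outcome
  expect_length(b$variables, 12L)
  expect_setequal(setdiff(w$variables, b$variables), "weight")
  expect_setequal(setdiff(b$variables, w$variables), "bmi")
  relabel <- function(x) gsub("(?<!_)weight", "OUT", gsub("\\bbmi\\b", "OUT", x),
                              perl = TRUE)
  expect_setequal(relabel(w$free$label), relabel(b$free$label))
  for (spec in list(w, b)) {
    p <- length(spec$variables)
    df <- p * (p + 1) / 2 - nrow(spec$free)
    expect_gt(df, 0)
    expect_silent(otispath:::check_acyclic(spec))
  }
  # optional-path switches change the parameter count
  expect_equal(nrow(weight_model_spec(FALSE, FALSE)$free), nrow(w$free) - 2)
})

test_that("the full SEM pipeline is deterministic and well formed", {
  co <- trial_cohort(n_per_group = 150)
  r1 <- run_sem_pipeline(co, "weight")
  r2 <- run_sem_pipeline(co, "weight")
  expect_identical(r1$paths, r2$paths)
  expect_identical(r1$indices$chi2, r2$indices$chi2)
  expect_true(r1$fit$converged)
  expect_true(all(c("est", "std", "std_lower", "std_upper", "stars") %in%
                    names(r1$paths)))
  expect_true(all(r1$mod_indices$mi >= 0))
  expect_match(r1$dot, "digraph")
  expect_match(r1$dot, "z_prot_auc")
})

test_that("group comparison reproduces the attrition table and edge cases", {
  attrition <- matrix(c(30, 95, 14, 111), nrow = 2, byrow = TRUE)
  out <- group_compare(attrition, method = "chisq")
  expect_equal(round(out$p[out$method == "chisq_yates"], 3), 0.013)
  # no association
  flat <- group_compare(matrix(c(5, 5, 5, 5), 2), method = "chisq")
  expect_equal(flat$p[1], 1)
  # identical continuous groups: t = 0, p = 1
  w <- group_compare(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3),
                     method = "welch")
  expect_equal(w$statistic, 0)
  expect_equal(w$p, 1)
  # binary methods
  tab <- matrix(c(7, 91, 2, 108), 2, byrow = TRUE)
  cond <- group_compare(tab, method = "binary")
  expect_equal(cond$method, "conditional_exact")
  bin <- group_compare(tab, method = "binary", binary_method = "binomial")
  expect_true(bin$p <= 1 && bin$p >= 0)
  # small expected counts add the exact test to the chisq output
  small <- group_compare(matrix(c(3, 1, 1, 3), 2), method = "chisq")
  expect_true("fisher_exact" %in% small$method)
})

test_that("residual diagnostics are calibrated and catch constructed outliers", {
  co <- trial_cohort(n_per_group = 100)
  fr <- build_frame(co)
  dg <- residual_diagnostics(fr, "weight", n_sim = 200, seed = 2)
  for (eq in c("outcome", "ln_igf1", "ln_ins_glu")) {
    u <- dg[[eq]]$quantile_residuals
    expect_true(all(u >= 0 & u <= 1))
    expect_gt(dg[[eq]]$ks_p, 0.001)   # correctly specified Gaussian
  }
  expect_error(residual_diagnostics(fr, "weight", n_sim = 10), "at least 50")
  # corrupt the outcome with gross outliers: outlier test reacts
  fr2 <- fr
  fr2$weight[1:12] <- fr2$weight[1:12] + 60
  dg2 <- residual_diagnostics(fr2, "weight", n_sim = 200, seed = 2)
  expect_lt(dg2$outcome$outlier_p, 0.01)
})

test_that("proxy validation reports the documented correlation structure", {
  co <- trial_cohort(n_per_group = 300)
  pv <- proxy_validation(co)
  cors <- pv$correlations
  get_r <- function(chk) cors$r[cors$check == chk]
  expect_gt(get_r("leucine_vs_isoleucine"), 0.93)
  expect_gt(get_r("isoleucine_vs_valine"), 0.93)
  expect_gt(get_r("recent_protein_vs_total_bcaa"), 0.32)
  expect_gt(get_r("weight_vs_length"), 0.68)
  expect_gt(get_r("bmi_vs_fat_mass_index"), 0.62)
  expect_equal(get_r("protein_auc_vs_fat_free_mass_12mo"), 0.20,
               tolerance = 0.1)
  expect_true(all(c("(Intercept)", "auc", "sex", "auc:sex") %in%
                    rownames(pv$ffm_regression)))
  # degenerate correlation sanity through the same cor machinery
  expect_equal(cor(c(1, 2, 3), c(3, 2, 1)), -1)
})

test_that("run_all produces a deterministic, complete bundle", {
  cfg <- run_config(n_per_group = 60, seed = 9, n_perm = 99,
                    n_sim_residuals = 60)
  d1 <- file.path(tempdir(), "bundle1")
  d2 <- file.path(tempdir(), "bundle2")
  b1 <- run_all(cfg, out_dir = d1)
  b2 <- run_all(cfg, out_dir = d2)
  expect_s3_class(b1, "otis_bundle")
  files <- c("cohort.csv", "cumulative_intake.tsv", "protein_flags.csv",
             "volcano_12.tsv", "volcano_18.tsv", "permanova_12.json",
             "estimates_weight.tsv", "estimates_bmi.tsv",
             "indices_weight.json", "mod_indices_weight.tsv",
             "diagram_weight.dot", "diagnostics_weight.json",
             "provenance.json")
  for (f in files) expect_true(file.exists(file.path(d1, f)), label = f)
  # byte-identical bundles under the same configuration
  for (f in files)
    expect_identical(readBin(file.path(d1, f), "raw", 2e6),
                     readBin(file.path(d2, f), "raw", 2e6), label = f)
  prov <- jsonlite::read_json(file.path(d1, "provenance.json"))
  expect_equal(prov$config$seed, 9)
  expect_equal(prov$config$glog_lambda, 1)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("cohort CSV round-trips through the writers", {
  co <- trial_cohort(n_per_group = 20)
  f <- tempfile(fileext = ".csv")
  write_cohort(co, f)
  back <- read_cohort(f)
  expect_equal(nrow(back), nrow(co))
  expect_equal(back$protein_g, co$protein_g, tolerance = 1e-12)
  unlink(f)
})
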