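test_that("model syntax parses into the expected free-parameter structure", {
  spec <- parse_model("y ~ x")
  f <- spec$free
  expect_equal(sum(f$matrix == "B"), 1L)
  expect_equal(sum(f$matrix == "Psi" & f$row == f$col), 2L)
  expect_equal(spec$endogenous, "y")
  expect_equal(spec$exogenous, "x")
  # fixed exogenous variance option
  spec2 <- parse_model("y ~ x", fixed_exog_var = c(x = 1))
  expect_equal(sum(spec2$free$matrix == "Psi"), 1L)
  expect_equal(spec2$Psi["x", "x"], 1)
  # fixed coefficient
  spec3 <- parse_model("y ~ 0.5*x")
  expect_equal(spec3$B["y", "x"], 0.5)
  expect_equal(sum(spec3$free$matrix == "B"), 0L)
})

test_that("parser rejects cycles, self-loops, duplicates and unknowns", {
  expect_error(parse_model("y ~ y"), class = "otispath_cycle")
  expect_error(parse_model("y ~ x\nx ~ y"), class = "otispath_cycle")
  expect_error(parse_model("y ~ x\ny ~ x"), "duplicate")
  expect_error(parse_model("y ~ x + z", variables = c("y", "x")), "unknown")
})

test_that("implied covariance follows the RAM identity", {
  spec <- parse_model("y ~ x", fixed_exog_var = c(x = 1))
  # theta order: b, psi_y
  Sg <- implied_covariance(spec, c(0.8, 0.5))
  expect_equal(Sg["x", "x"], 1)
  expect_equal(Sg["y", "x"], 0.8)
  expect_equal(Sg["y", "y"], 0.8^2 + 0.5)
  spec0 <- parse_model("a ~~ a\nb ~~ b\na ~~ b")
  Sg0 <- implied_covariance(spec0, c(2, 3, 0.5))
  expect_equal(unname(Sg0), matrix(c(2, 0.5, 0.5, 3), 2))  # B = 0 -> Psi
  set.seed(1)
  spec2 <- parse_model("m ~ x\ny ~ m + x")
  th <- rnorm(otispath:::n_free(spec2))
  th[otispath:::n_free(spec2) - 2:0] <- abs(th[otispath:::n_free(spec2) - 2:0]) + 1
  Sg2 <- implied_covariance(spec2, th)
  expect_equal(Sg2, t(Sg2))
})

test_that("just-identified recursive fits reproduce per-equation OLS exactly", {
  for (s in 1:12) {
    rm_ <- random_recursive_model(p = sample(3:5, 1), n = 150, seed = s)
    fit <- fit_ml(rm_$spec, rm_$data)
    expect_lt(fit$F_ml, 1e-10)
    expect_equal(fit$T, 0, tolerance = 1e-7)
    fb <- rm_$spec$free[rm_$spec$free$matrix == "B", ]
    for (y in unique(fb$row)) {
      yv <- rm_$spec$variables[y]
      xs <- rm_$spec$variables[fb$col[fb$row == y]]
      ols <- coef(lm(stats::reformulate(xs, yv), data = rm_$data))[xs]
      est <- coef(fit)[paste(yv, "~", xs)]
      expect_equal(unname(est), unname(ols), tolerance = 1e-6)
    }
  }
})

test_that("saturated models report perfect fit", {
  rm_ <- random_recursive_model(p = 4, n = 120, seed = 99)
  fit <- fit_ml(rm_$spec, rm_$data)
  idx <- fit_indices(fit)
  expect_equal(idx$chi2, 0, tolerance = 1e-7)
  expect_equal(idx$CFI, 1)
  expect_equal(idx$RMSEA, 0)
  expect_equal(idx$SRMR, 0, tolerance = 1e-7)
  expect_true(idx$saturated)
})

test_that("simulation from a known chain recovers parameters within 3 SE", {
  set.seed(21)
  n <- 5000
  x <- rnorm(n)
  m <- 0.5 * x + rnorm(n, sd = sqrt(0.75))
  y <- 0.6 * m + rnorm(n, sd = sqrt(0.64))
  d <- data.frame(x = x, m = m, y = y)
  fit <- fit_ml(parse_model("m ~ x\ny ~ m"), d)   # over-identified (df = 1)
  expect_equal(fit$df, 1)
  est <- coef(fit)
  expect_lt(abs(est["m ~ x"] - 0.5), 3 * fit$se_naive["m ~ x"])
  expect_lt(abs(est["y ~ m"] - 0.6), 3 * fit$se_naive["y ~ m"])
})

test_that("naive standard errors match the regression oracle", {
  set.seed(4)
  d <- data.frame(x = rnorm(400))
  d$y <- 0.5 * d$x + rnorm(400)
  fit <- fit_ml(parse_model("y ~ x"), d)
  lm_se <- summary(lm(y ~ x, d))$coefficients["x", "Std. Error"]
  expect_equal(unname(fit$se_naive["y ~ x"]), lm_se, tolerance = 0.02)
})

test_that("scale equivariance: unstandardized rescale, standardized invariant", {
  set.seed(6)
  d <- data.frame(x = rnorm(300))
  d$m <- 0.4 * d$x + rnorm(300)
  d$y <- 0.5 * d$m + 0.2 * d$x + rnorm(300)
  spec <- parse_model("m ~ x\ny ~ m + x")
  f1 <- robust_adjust(fit_ml(spec, d), d)
  d2 <- d; d2$x <- 10 * d$x
  f2 <- robust_adjust(fit_ml(spec, d2), d2)
  expect_equal(unname(coef(f2)["m ~ x"]), unname(coef(f1)["m ~ x"]) / 10,
               tolerance = 1e-6)
  s1 <- standardized_solution(f1); s2 <- standardized_solution(f2)
  expect_equal(s1$std[s1$op == "~"], s2$std[s2$op == "~"], tolerance = 1e-8)
})

test_that("robust and naive SEs coincide under normality, diverge under t5", {
  set.seed(31)
  n <- 5000
  d <- data.frame(x = rnorm(n))
  d$y <- 0.5 * d$x + rnorm(n)
  fit <- robust_adjust(fit_ml(parse_model("y ~ x"), d), d)
  ratio <- fit$robust$se / fit$se_naive
  expect_equal(unname(ratio[names(ratio) == "y ~ x"]), 1, tolerance = 0.06)
  # heavy-tailed errors inflate the sandwich SE of the residual variance
  d2 <- data.frame(x = rnorm(n))
  d2$y <- 0.5 * d2$x + rt(n, df = 5)
  fit2 <- robust_adjust(fit_ml(parse_model("y ~ x"), d2), d2)
  expect_gt(unname(fit2$robust$se["y ~~ y"] / fit2$se_naive["y ~~ y"]), 1.2)
})

test_that("scaled statistic corrects kurtosis in an over-identified model", {
  set.seed(32)
  n <- 4000
  # common scale mixture: heavy multivariate kurtosis, model still correct
  w <- sqrt(5 / rchisq(n, 5))
  x <- rnorm(n); m <- 0.5 * x + rnorm(n) * sqrt(0.75)
  y <- 0.6 * m + rnorm(n) * sqrt(0.64)
  d <- data.frame(x = w * x, m = w * m, y = w * y)
  fit <- robust_adjust(fit_ml(parse_model("m ~ x\ny ~ m"), d), d)
  expect_gt(fit$robust$c, 1.5)  # excess kurtosis inflates T; c shrinks it back
  expect_equal(fit$robust$T_scaled, fit$T / fit$robust$c)
  # normal data: c near 1
  dn <- data.frame(x = x, m = m, y = y)
  fitn <- robust_adjust(fit_ml(parse_model("m ~ x\ny ~ m"), dn), dn)
  expect_gt(fitn$robust$c, 0)
  expect_equal(fitn$robust$c, 1, tolerance = 0.1)
})

test_that("fit indices match a closed-form misspecification oracle", {
  # model: y ~ x with z unrelated; truth has cov(z, y) != 0. The ML
  # solution zeroes the z row/column, so F, T and every index follow in
  # closed form from the sample covariance alone.
  set.seed(41)
  n <- 500
  x <- rnorm(n); y <- 0.5 * x + rnorm(n); z <- 0.4 * y + rnorm(n)
  d <- data.frame(x = x, y = y, z = z)
  spec <- parse_model("y ~ x\nz ~~ z", variables = c("x", "y", "z"),
                      exog_cov = FALSE)
  fit <- fit_ml(spec, d)
  S <- cov(d)
  Sg_or <- S; Sg_or["z", c("x", "y")] <- 0; Sg_or[c("x", "y"), "z"] <- 0
  F_or <- log(det(Sg_or)) + sum(diag(S %*% solve(Sg_or))) - log(det(S)) - 3
  expect_equal(fit$F_ml, F_or, tolerance = 1e-8)
  T_or <- (n - 1) * F_or
  df_or <- 6 - 4
  F0 <- sum(log(diag(S))) - log(det(S))
  T0 <- (n - 1) * F0
  idx <- fit_indices(fit)
  expect_equal(idx$chi2, T_or, tolerance = 1e-6)
  expect_equal(idx$df, df_or)
  expect_equal(idx$CFI, 1 - max(T_or - df_or, 0) /
                 max(T0 - 3, T_or - df_or, 0), tolerance = 1e-8)
  expect_equal(idx$NFI, (T0 - T_or) / T0, tolerance = 1e-8)
  expect_equal(idx$IFI, (T0 - T_or) / (T0 - df_or), tolerance = 1e-8)
  expect_equal(idx$TLI, ((T0 / 3) - (T_or / df_or)) / ((T0 / 3) - 1),
               tolerance = 1e-8)
  expect_equal(idx$RMSEA, sqrt(max(T_or - df_or, 0) / (df_or * (n - 1))),
               tolerance = 1e-8)
  res <- (S - Sg_or) / tcrossprod(sqrt(diag(S)))
  expect_equal(idx$SRMR, sqrt(mean(res[lower.tri(res, diag = TRUE)]^2)),
               tolerance = 1e-8)
  expect_true(idx$RMSEA >= idx$RMSEA_ci["lower"] - 1e-12 &&
                idx$RMSEA <= idx$RMSEA_ci["upper"] + 1e-12)
})

test_that("T = df gives RMSEA exactly zero", {
  expect_equal(otispath:::rmsea_ci(5, 5, 100)[["lower"]], 0)
  # direct formula check via the public surface
  set.seed(44)
  d <- data.frame(x = rnorm(80)); d$m <- d$x + rnorm(80); d$y <- d$m + rnorm(80)
  fit <- fit_ml(parse_model("m ~ x\ny ~ m"), d)
  idx <- fit_indices(fit)
  if (idx$chi2 <= idx$df) expect_equal(idx$RMSEA, 0)
})

test_that("modification indices locate an omitted path and predict the T drop", {
  set.seed(51)
  n <- 2000
  x <- rnorm(n)
  m <- 0.5 * x + rnorm(n)
  y <- 0.5 * m + 0.4 * x + rnorm(n)   # direct x -> y omitted from the model
  d <- data.frame(x = x, m = m, y = y)
  fit0 <- fit_ml(parse_model("m ~ x\ny ~ m"), d)
  mi <- modification_indices(fit0)
  expect_true(all(mi$mi >= 0))
  # the omitted path sits at the top (ties with its covariance-equivalent
  # candidates allowed)
  expect_gte(mi$mi[mi$label == "y ~ x"], 0.999 * max(mi$mi))
  expect_true(mi$flag[mi$label == "y ~ x"])
  # freeing the top path recovers approximately the MI in T
  fit1 <- fit_ml(parse_model("m ~ x\ny ~ m + x"), d)
  drop_T <- fit0$T - fit1$T
  expect_equal(mi$mi[mi$label == "y ~ x"], drop_T, tolerance = 0.15 * drop_T)
  # and the freed estimate is near the expected parameter change
  expect_equal(mi$epc[mi$label == "y ~ x"], unname(coef(fit1)["y ~ x"]),
               tolerance = 0.1)
})

test_that("the test statistic is chi-square calibrated under a true model", {
  set.seed(61)
  n <- 200
  rej <- vapply(1:300, function(i) {
    x <- rnorm(n)
    m <- 0.5 * x + rnorm(n)
    y <- 0.6 * m + rnorm(n)
    fit <- fit_ml(parse_model("m ~ x\ny ~ m"),
                  data.frame(x = x, m = m, y = y))
    fit$T > qchisq(0.95, df = fit$df)
  }, TRUE)
  # 0.05 within its binomial 3 SE band over 300 simulations
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("listwise deletion and guard rails behave as documented", {
  set.seed(71)
  d <- data.frame(x = rnorm(50))
  d$y <- 0.5 * d$x + rnorm(50)
  d$y[1:5] <- NA
  fit <- fit_ml(parse_model("y ~ x"), d)
  expect_equal(fit$n, 45)
  expect_error(fit_ml(parse_model("y ~ x"), d[1:2, ]), "more complete")
  dd <- data.frame(x = rnorm(30))
  dd$z <- dd$x                      # perfectly collinear
  expect_error(fit_ml(parse_model("x ~~ z"), dd),
               class = "otispath_nonpd_sample")
})
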