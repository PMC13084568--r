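#' Simulation-based residual diagnostics for the structural equations
#'
#' Checks the Gaussian regression assumptions of each structural equation
#' with simulated quantile residuals: every equation is refit as a linear
#' model, \code{n_sim} response vectors are simulated from the fitted
#' Gaussian, and each observation's quantile residual is its (randomised)
#' rank among its simulated counterparts, uniform on (0, 1) under a correct
#' model. Three tests summarise the residuals per equation: a
#' Kolmogorov-Smirnov test of uniformity, a dispersion test comparing the
#' observed residual variance with the simulated distribution of variances
#' (two-sided permutation-style p), and an outlier test (exact binomial on
#' the count of observations outside the simulation envelope).
#'
#' @param frame an analysis frame from \code{\link{build_frame}}.
#' @param model \code{"weight"} or \code{"bmi"}.
#' @param n_sim simulations per observation (at least 50).
#' @param seed RNG seed.
#' @return List of class \code{otis_diagnostics}: per equation, the
#'   quantile residuals and \code{ks_p}, \code{dispersion_p},
#'   \code{dispersion_ratio}, \code{outlier_p}, \code{n_outliers}.
#' @export
residual_diagnostics <- function(frame, model = c("weight", "bmi"),
                                 n_sim = 250, seed = 1) {
  model <- match.arg(model)
  if (n_sim < 50) stop("n_sim must be at least 50")
  set.seed(stage_seed(seed, "diagnostics"))
  eqs <- list(
    outcome = stats::reformulate(
      c("z_prot_auc", "ln_ins_glu", "ln_igf1", "birth_weight", "gwg",
        "maternal_bmi", "excl_bf", "any_formula", "sex", "age18"),
      response = model),
    ln_igf1 = ln_igf1 ~ z_prot_auc + ln_bcaa + sex + age18,
    ln_ins_glu = ln_ins_glu ~ ln_bcaa + z_prot_auc + sex + age18
  )
  out <- lapply(eqs, function(fm) {
    lmfit <- stats::lm(fm, data = frame)
    mu <- stats::fitted(lmfit)
    sg <- stats::sigma(lmfit)
    y <- stats::model.response(stats::model.frame(lmfit))
    n <- length(y)
    sims <- matrix(stats::rnorm(n * n_sim, mean = mu, sd = sg), n, n_sim)
    below <- rowSums(sims < y)
    ties <- rowSums(sims == y)
    u <- (below + stats::runif(n) * (1 + ties)) / (n_sim + 1)
    ks <- suppressWarnings(stats::ks.test(u, "punif"))
    v_obs <- stats::var(y - mu)
    v_sim <- apply(sims - mu, 2, stats::var)
    p_disp <- 2 * min(mean(v_sim <= v_obs), mean(v_sim >= v_obs)) +
      1 / (n_sim + 1)
    p_disp <- min(1, p_disp)
    n_out <- sum(y < apply(sims, 1, min) | y > apply(sims, 1, max))
    bt <- stats::binom.test(n_out, n, p = 2 / (n_sim + 1))
    list(quantile_residuals = u, ks_p = ks$p.value,
         dispersion_ratio = v_obs / mean(v_sim), dispersion_p = p_disp,
         n_outliers = n_out, outlier_p = bt$p.value)
  })
  structure(c(out, list(model = model, n_sim = n_sim)),
            class = "otis_diagnostics")
}

#' @export
print.otis_diagnostics <- function(x, ...) {
  cat("Simulated-residual diagnostics (", x$model, " model, ",
      x$n_sim, " sims)\n", sep = "")
  for (eq in setdiff(names(x), c("model", "n_sim"))) {
    e <- x[[eq]]
    cat(sprintf("  %-10s KS p = %.3f  dispersion %.2f (p = %.3f)  outliers %d (p = %.3f)\n",
                eq, e$ks_p, e$dispersion_ratio, e$dispersion_p,
                e$n_outliers, e$outlier_p))
  }
  invisible(x)
}
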