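# independence (baseline) model: variances free, everything else zero
baseline_spec <- function(variables) {
  parse_model(paste(variables, "~~", variables, collapse = "\n"),
              variables = variables, exog_cov = FALSE)
}

rmsea_ci <- function(T, df, n, level = 0.90) {
  if (df <= 0) return(c(lower = 0, upper = 0))
  lo_tail <- (1 + level) / 2    # 0.95
  up_tail <- (1 - level) / 2    # 0.05
  find_ncp <- function(target) {
    f <- function(l) stats::pchisq(T, df, ncp = l) - target
    if (f(0) < 0) return(0)
    upper <- max(T * 2, df * 2, 10)
    while (f(upper) > 0) upper <- upper * 2
    stats::uniroot(f, c(0, upper))$root
  }
  c(lower = sqrt(find_ncp(lo_tail) / (df * (n - 1))),
    upper = sqrt(find_ncp(up_tail) / (df * (n - 1))))
}

#' Goodness-of-fit indices
#'
#' Computes the standard covariance-structure fit indices from the fitted
#' and baseline (independence) test statistics: CFI, TLI, NFI, IFI, GFI,
#' AGFI, RMSEA with a 90\% CI, and SRMR, plus robust variants of CFI, TLI
#' and RMSEA in which the scaled statistics of the fitted and baseline
#' models replace the plain ones. A saturated model (df = 0) reports the
#' incremental indices as 1, RMSEA 0 and SRMR 0 with a \code{saturated}
#' flag.
#'
#' @param fit a converged \code{\link{fit_ml}} result; if it carries a
#'   \code{robust} element (see \code{\link{robust_adjust}}) and \code{data}
#'   is supplied, robust variants are computed.
#' @param data optional data (needed only for the robust variants, to scale
#'   the baseline statistic).
#' @return Object of class \code{fit_indices} (a named list).
#' @export
fit_indices <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "sem_fit"))
  n <- fit$n; p <- fit$p
  S <- fit$S; Sigma <- fit$Sigma
  T <- fit$T; df <- fit$df
  # baseline by closed form: Sigma0 = diag(S) at the ML optimum
  F0 <- sum(log(diag(S))) - determinant(S, logarithm = TRUE)$modulus[1]
  T0 <- (n - 1) * max(F0, 0)
  df0 <- p * (p - 1) / 2
  sat <- df == 0
  clip01 <- function(x) min(max(x, 0), 1)
  cfi_of <- function(T, df, T0, df0) {
    den <- max(T0 - df0, T - df, 0)
    if (den == 0) 1 else clip01(1 - max(T - df, 0) / den)
  }
  tli_of <- function(T, df, T0, df0) {
    if (df == 0 || df0 == 0) return(1)
    r0 <- T0 / df0
    if (abs(r0 - 1) < 1e-12) return(1)
    ((r0 - T / df) / (r0 - 1))
  }
  CFI <- if (sat) 1 else cfi_of(T, df, T0, df0)
  TLI <- if (sat) 1 else tli_of(T, df, T0, df0)
  NFI <- if (T0 > 0) clip01((T0 - T) / T0) else 1
  IFI <- if (sat) 1 else if (T0 - df > 0) (T0 - T) / (T0 - df) else 1
  Sinv_res <- fit$Sinv %*% (S - Sigma)
  GFI <- clip01(1 - sum(Sinv_res * t(Sinv_res)) /
                  sum((fit$Sinv %*% S) * t(fit$Sinv %*% S)))
  AGFI <- if (df > 0) 1 - (p * (p + 1) / (2 * df)) * (1 - GFI) else NA_real_
  RMSEA <- if (sat) 0 else sqrt(max(T - df, 0) / (df * (n - 1)))
  ci <- if (sat) c(lower = 0, upper = 0) else rmsea_ci(T, df, n)
  sd_ <- sqrt(diag(S))
  res_std <- (S - Sigma) / tcrossprod(sd_)
  SRMR <- sqrt(mean(res_std[lower.tri(res_std, diag = TRUE)]^2))
  out <- list(chi2 = T, df = df, chi2_baseline = T0, df_baseline = df0,
              CFI = CFI, TLI = TLI, NFI = NFI, IFI = IFI, GFI = GFI,
              AGFI = AGFI, RMSEA = RMSEA, RMSEA_ci = ci, SRMR = SRMR,
              saturated = sat, n = n)
  if (!is.null(fit$robust) && !is.null(data) && !sat) {
    b0 <- fit_ml(baseline_spec(fit$spec$variables), data)
    b0 <- robust_adjust(b0, data)
    Ts <- fit$robust$T_scaled
    T0s <- b0$robust$T_scaled
    out$chi2_scaled <- Ts
    out$chi2_baseline_scaled <- T0s
    out$scaling_c <- fit$robust$c
    out$CFI_robust <- cfi_of(Ts, df, T0s, df0)
    out$TLI_robust <- tli_of(Ts, df, T0s, df0)
    out$RMSEA_robust <- sqrt(max(Ts - df, 0) / (df * (n - 1)))
    out$RMSEA_robust_ci <- rmsea_ci(Ts, df, n)
    out$SRMR_robust <- SRMR
  }
  structure(out, class = "fit_indices")
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf("chi2(%d) = %.3f  baseline chi2(%d) = %.3f\n",
              x$df, x$chi2, x$df_baseline, x$chi2_baseline))
  cat(sprintf("CFI %.3f  TLI %.3f  NFI %.3f  IFI %.3f  GFI %.3f  AGFI %.3f\n",
              x$CFI, x$TLI, x$NFI, x$IFI, x$GFI, x$AGFI))
  cat(sprintf("RMSEA %.3f [%.3f, %.3f]  SRMR %.4f\n",
              x$RMSEA, x$RMSEA_ci["lower"], x$RMSEA_ci["upper"], x$SRMR))
  if (!is.null(x$CFI_robust))
    cat(sprintf("robust: CFI %.3f  TLI %.3f  RMSEA %.3f (scaling c = %.3f)\n",
                x$CFI_robust, x$TLI_robust, x$RMSEA_robust, x$scaling_c))
  invisible(x)
}

#' Modification indices
#'
#' Univariate score statistics for every parameter fixed at zero (candidate
#' paths and residual covariances): the expected drop in the test statistic
#' T from freeing that single parameter, on the chi-square(1) scale, with
#' the corresponding expected parameter change. Rows with \code{p_mi}
#' below \code{alpha} are flagged.
#'
#' @param fit converged, over-identified \code{\link{fit_ml}} result.
#' @param alpha flag threshold for \code{p_mi}.
#' @return data.frame: \code{label}, \code{matrix}, \code{mi}, \code{p_mi},
#'   \code{epc}, \code{flag}, sorted by decreasing \code{mi}.
#' @export
modification_indices <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "sem_fit"))
  spec <- fit$spec
  p <- fit$p; n <- fit$n
  d <- sem_derivs(spec, fit$theta)
  W <- fit$Sinv - fit$Sinv %*% fit$S %*% fit$Sinv
  Tm <- lapply(d$dSigma, function(x) fit$Sinv %*% x)
  free_keys <- paste(spec$free$matrix, spec$free$row, spec$free$col)
  cand <- list()
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i != j && !(paste("B", i, j) %in% free_keys) && spec$B[i, j] == 0)
      cand[[length(cand) + 1L]] <- list(mat = "B", i = i, j = j)
  }
  for (i in seq_len(p)) for (j in seq_len(i - 1L)) {
    if (!(paste("Psi", i, j) %in% free_keys) && spec$Psi[i, j] == 0)
      cand[[length(cand) + 1L]] <- list(mat = "Psi", i = i, j = j)
  }
  if (!length(cand))
    return(data.frame(label = character(0), matrix = character(0),
                      mi = numeric(0), p_mi = numeric(0), epc = numeric(0),
                      flag = logical(0)))
  q <- length(fit$theta)
  rows <- lapply(cand, function(cc) {
    dSg <- if (cc$mat == "B") {
      M <- tcrossprod(d$A[, cc$i], d$Sigma[cc$j, ])
      M + t(M)
    } else {
      tcrossprod(d$A[, cc$i], d$A[, cc$j]) +
        tcrossprod(d$A[, cc$j], d$A[, cc$i])
    }
    g <- sum(W * dSg)
    Tg <- fit$Sinv %*% dSg
    Hgg <- 0.5 * sum(Tg * t(Tg))
    Hgt <- vapply(Tm, function(tm) 0.5 * sum(Tg * t(tm)), 0)
    Htilde <- Hgg - drop(t(Hgt) %*% solve(fit$H, Hgt))
    mi <- if (Htilde > 1e-12) (n - 1) * g^2 / (4 * Htilde) else 0
    epc <- if (Htilde > 1e-12) -g / (2 * Htilde) else 0
    lab <- if (cc$mat == "B")
      paste(spec$variables[cc$i], "~", spec$variables[cc$j])
    else paste(spec$variables[cc$j], "~~", spec$variables[cc$i])
    data.frame(label = lab, matrix = cc$mat, mi = mi,
               p_mi = stats::pchisq(mi, 1, lower.tail = FALSE), epc = epc)
  })
  out <- do.call(rbind, rows)
  out$flag <- out$p_mi < alpha
  out[order(-out$mi), ]
}

star_band <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", ifelse(p < 0.1, "†", ""))))
}

#' Standardized parameter solution
#'
#' Standardized path coefficients (unstandardized estimate times the
#' model-implied SD ratio of predictor to outcome) and standardized
#' residual (co)variances, with delta-method standard errors and 95\%
#' confidence intervals propagated through the standardization map from the
#' robust (if present) or naive parameter covariance. Significance stars
#' follow the conventional bands (*** p<0.001, ** p<0.01, * p<0.05,
#' \eqn{\dagger} p<0.1).
#'
#' @param fit a \code{\link{fit_ml}} result (ideally after
#'   \code{\link{robust_adjust}}).
#' @param level CI level.
#' @return data.frame: \code{label}, \code{lhs}, \code{op}, \code{rhs},
#'   \code{est}, \code{se}, \code{z}, \code{p}, \code{std}, \code{std_se},
#'   \code{std_lower}, \code{std_upper}, \code{stars}.
#' @export
standardized_solution <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "sem_fit"))
  spec <- fit$spec
  vc <- if (!is.null(fit$robust)) fit$robust$vcov else fit$vcov_naive
  se <- sqrt(pmax(diag(vc), 0))
  std_map <- function(theta) {
    Sg <- implied_covariance(spec, theta)
    sd_ <- sqrt(diag(Sg))
    f <- spec$free
    vapply(seq_len(nrow(f)), function(k) {
      i <- f$row[k]; j <- f$col[k]
      if (f$matrix[k] == "B") theta[k] * sd_[j] / sd_[i]
      else if (i == j) theta[k] / Sg[i, i]
      else theta[k] / (sd_[i] * sd_[j])
    }, 0)
  }
  std <- std_map(fit$theta)
  # numeric Jacobian of the standardization map
  q <- length(fit$theta)
  J <- matrix(0, q, q)
  h <- pmax(abs(fit$theta), 1) * 1e-6
  for (k in seq_len(q)) {
    tp <- tm <- fit$theta
    tp[k] <- tp[k] + h[k]; tm[k] <- tm[k] - h[k]
    J[, k] <- (std_map(tp) - std_map(tm)) / (2 * h[k])
  }
  std_se <- sqrt(pmax(diag(J %*% vc %*% t(J)), 0))
  zc <- stats::qnorm(1 - (1 - level) / 2)
  f <- spec$free
  z <- ifelse(se > 0, fit$theta / se, NA_real_)
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(
    label = f$label,
    lhs = spec$variables[f$row],
    op = ifelse(f$matrix == "B", "~", "~~"),
    rhs = spec$variables[f$col],
    est = unname(fit$theta), se = se, z = z, p = p,
    std = std, std_se = std_se,
    std_lower = std - zc * std_se, std_upper = std + zc * std_se,
    stars = star_band(p),
    stringsAsFactors = FALSE
  )
}
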