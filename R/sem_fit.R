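# Derivative matrices of Sigma with respect to each free parameter, at the
# current point. For a path cell B[i,j]: dSigma = M + M' with
# M = A e_i e_j' Sigma (A = (I-B)^{-1}); for a Psi cell: A(E_ij + E_ji)A'.
sem_derivs <- function(spec, theta) {
  m <- theta_to_mats(spec, theta)
  p <- length(spec$variables)
  A <- solve(diag(p) - m$B)
  Sigma <- A %*% m$Psi %*% t(A)
  Sigma <- (Sigma + t(Sigma)) / 2
  f <- spec$free
  dS <- vector("list", nrow(f))
  for (k in seq_len(nrow(f))) {
    i <- f$row[k]; j <- f$col[k]
    if (f$matrix[k] == "B") {
      M <- tcrossprod(A[, i], Sigma[j, ])
      dS[[k]] <- M + t(M)
    } else if (i == j) {
      dS[[k]] <- tcrossprod(A[, i])
    } else {
      dS[[k]] <- tcrossprod(A[, i], A[, j]) + tcrossprod(A[, j], A[, i])
    }
  }
  list(A = A, Sigma = Sigma, B = m$B, Psi = m$Psi, dSigma = dS)
}

fml_value <- function(Sigma, S, logdetS) {
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Sinv <- chol2inv(ch)
  ld <- 2 * sum(log(diag(ch)))
  list(F = ld + sum(Sinv * S) - logdetS - nrow(S), Sinv = Sinv)
}

# expected-information matrix H_jk = 0.5 tr(Sigma^-1 dS_j Sigma^-1 dS_k)
expected_info <- function(Sinv, dS) {
  q <- length(dS)
  Tm <- lapply(dS, function(d) Sinv %*% d)
  H <- matrix(0, q, q)
  for (j in seq_len(q)) for (k in j:q) {
    H[j, k] <- H[k, j] <- 0.5 * sum(Tm[[j]] * t(Tm[[k]]))
  }
  H
}

ols_start <- function(spec, S) {
  p <- length(spec$variables)
  f <- spec$free
  theta <- numeric(nrow(f))
  # regression starts per endogenous row
  for (y in unique(f$row[f$matrix == "B"])) {
    kk <- which(f$matrix == "B" & f$row == y)
    pa <- f$col[kk]
    co <- tryCatch(solve(S[pa, pa, drop = FALSE], S[pa, y]),
                   error = function(e) rep(0, length(pa)))
    theta[kk] <- co
  }
  bm <- theta_to_mats(spec, theta)$B
  for (k in which(f$matrix == "Psi")) {
    i <- f$row[k]; j <- f$col[k]
    vi <- spec$variables[i]
    if (i == j) {
      if (vi %in% spec$endogenous) {
        b <- bm[i, ]
        theta[k] <- max(S[i, i] - 2 * sum(b * S[i, ]) +
                          drop(t(b) %*% S %*% b), 0.05 * S[i, i])
      } else theta[k] <- S[i, i]
    } else {
      both_exog <- all(spec$variables[c(i, j)] %in% spec$exogenous)
      theta[k] <- if (both_exog) S[i, j] else 0
    }
  }
  theta
}

#' Fit a path model by maximum likelihood
#'
#' Minimises the ML discrepancy
#' \eqn{F(\theta) = \ln|\Sigma(\theta)| + tr(S\Sigma^{-1}) - \ln|S| - p}
#' over the free parameters by quasi-Newton (BFGS with analytic gradient)
#' from least-squares starting values, followed by Newton polishing with
#' the expected information until the gradient infinity-norm falls below
#' \code{tol}. The sample covariance uses the n-1 divisor; rows with any
#' missing model variable are removed (listwise deletion, no imputation).
#' Reports the test statistic \eqn{T = (n-1) F_{ML}} with
#' \eqn{df = p(p+1)/2 - q} and naive standard errors from the inverse
#' expected information.
#'
#' @param spec a \code{sem_spec}.
#' @param data data.frame containing the model variables.
#' @param tol convergence tolerance on the gradient infinity-norm.
#' @param max_iter BFGS iteration cap.
#' @return Object of class \code{sem_fit}: estimates (\code{theta},
#'   labelled), \code{S}, \code{Sigma}, \code{F_ml}, \code{T}, \code{df},
#'   \code{n}, \code{vcov_naive}, \code{se_naive}, \code{converged}, plus
#'   internals reused by \code{\link{robust_adjust}},
#'   \code{\link{fit_indices}} and \code{\link{modification_indices}}.
#' @examples
#' set.seed(1)
#' d <- data.frame(x = rnorm(200))
#' d$y <- 0.5 * d$x + rnorm(200)
#' fit <- fit_ml(parse_model("y ~ x"), d)
#' coef(fit)
#' @export
fit_ml <- function(spec, data, tol = 1e-6, max_iter = 500) {
  stopifnot(inherits(spec, "sem_spec"))
  X <- as.matrix(data[, spec$variables, drop = FALSE])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more complete observations than variables")
  S <- stats::cov(X)
  chS <- tryCatch(chol(S), error = function(e)
    stop(structure(class = c("otispath_nonpd_sample", "error", "condition"),
                   list(message = "sample covariance is not positive definite",
                        call = NULL))))
  logdetS <- 2 * sum(log(diag(chS)))
  q <- n_free(spec)
  df <- p * (p + 1) / 2 - q
  if (df < 0) stop("model has more free parameters than covariance moments")

  fn <- function(theta) {
    d <- tryCatch(sem_derivs(spec, theta), error = function(e) NULL)
    if (is.null(d)) return(1e10)
    v <- fml_value(d$Sigma, S, logdetS)
    if (is.null(v) || !is.finite(v$F)) return(1e10)
    v$F
  }
  gr <- function(theta) {
    d <- tryCatch(sem_derivs(spec, theta), error = function(e) NULL)
    if (is.null(d)) return(rep(0, q))
    v <- fml_value(d$Sigma, S, logdetS)
    if (is.null(v)) return(rep(0, q))
    W <- v$Sinv - v$Sinv %*% S %*% v$Sinv
    vapply(d$dSigma, function(dS) sum(W * dS), 0)
  }
  theta <- ols_start(spec, S)
  opt <- stats::optim(theta, fn, gr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-14))
  theta <- opt$par
  # Newton polish with the expected information
  for (it in seq_len(100)) {
    g <- gr(theta)
    if (max(abs(g)) < tol) break
    d <- sem_derivs(spec, theta)
    v <- fml_value(d$Sigma, S, logdetS)
    H <- expected_info(v$Sinv, d$dSigma)
    step <- tryCatch(solve(2 * H, g), error = function(e) NULL)
    if (is.null(step)) break
    fcur <- v$F
    lam <- 1
    repeat {
      cand <- theta - lam * step
      if (fn(cand) <= fcur + 1e-12) { theta <- cand; break }
      lam <- lam / 2
      if (lam < 1e-8) break
    }
    if (lam < 1e-8) break
  }
  g <- gr(theta)
  converged <- max(abs(g)) < tol
  if (!converged)
    warning(sprintf("gradient norm %.2e above tolerance %.0e", max(abs(g)), tol))
  d <- sem_derivs(spec, theta)
  v <- fml_value(d$Sigma, S, logdetS)
  if (is.null(v))
    stop(structure(class = c("otispath_nonpd_sample", "error", "condition"),
                   list(message = "implied covariance is not positive definite at the optimum (degenerate sample?)",
                        call = NULL)))
  H <- expected_info(v$Sinv, d$dSigma)
  vcov_naive <- tryCatch(solve(H) / (n - 1), error = function(e)
    matrix(NA_real_, q, q))
  dimnames(vcov_naive) <- list(spec$free$label, spec$free$label)
  F_ml <- max(v$F, 0)
  names(theta) <- spec$free$label
  structure(list(spec = spec, theta = theta, S = S, Sigma = d$Sigma,
                 Psi = d$Psi, B = d$B, A = d$A, Sinv = v$Sinv, H = H,
                 F_ml = F_ml, T = (n - 1) * F_ml, df = df, n = n, p = p,
                 vcov_naive = vcov_naive,
                 se_naive = sqrt(pmax(diag(vcov_naive), 0)),
                 grad_norm = max(abs(g)), converged = converged,
                 robust = NULL),
            class = "sem_fit")
}

#' @export
coef.sem_fit <- function(object, ...) object$theta

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("Path model fit: %d variables, %d free parameters, n = %d\n",
              x$p, length(x$theta), x$n))
  cat(sprintf("  F_ML = %.6f, T = %.3f, df = %d%s\n", x$F_ml, x$T, x$df,
              if (!is.null(x$robust))
                sprintf(", scaled T = %.3f (c = %.3f)",
                        x$robust$T_scaled, x$robust$c) else ""))
  if (!x$converged) cat("  WARNING: not converged\n")
  invisible(x)
}

# duplication matrix: vec(M) = D %*% vech(M) for symmetric M
duplication_matrix <- function(p) {
  s <- p * (p + 1) / 2
  D <- matrix(0, p * p, s)
  k <- 0
  for (j in seq_len(p)) for (i in j:p) {
    k <- k + 1
    D[(j - 1) * p + i, k] <- 1
    if (i != j) D[(i - 1) * p + j, k] <- 1
  }
  D
}

vech <- function(M) M[lower.tri(M, diag = TRUE)]

#' Robust (sandwich) standard errors and scaled test statistic
#'
#' Adjusts a converged ML fit for non-normality: sandwich standard errors
#' built from the empirical fourth-moment matrix of the data, and the
#' classic scaled test statistic \eqn{T_{scaled} = T / c} where the scaling
#' constant \eqn{c = tr(U\Gamma)/df} contrasts the model's residual weight
#' matrix \eqn{U} with the data's fourth moments \eqn{\Gamma}. Under
#' multivariate normality the robust and naive standard errors coincide
#' asymptotically and \eqn{c \to 1}.
#'
#' @param fit a converged \code{\link{fit_ml}} object.
#' @param data the data used for the fit (same listwise-deletion rule is
#'   applied).
#' @return The fit with a \code{robust} element: \code{vcov},
#'   \code{se}, \code{c}, \code{T_scaled}, \code{Gamma}, \code{U}.
#' @export
robust_adjust <- function(fit, data) {
  stopifnot(inherits(fit, "sem_fit"))
  if (!fit$converged) stop("robust adjustment requires a converged fit")
  X <- as.matrix(data[, fit$spec$variables, drop = FALSE])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  stopifnot(nrow(X) == fit$n)
  n <- fit$n; p <- fit$p
  Xc <- sweep(X, 2, colMeans(X))
  idx <- which(lower.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  Sm <- Xc[, idx[, 1], drop = FALSE] * Xc[, idx[, 2], drop = FALSE]
  Gamma <- stats::cov(Sm) * (n - 1) / n    # divisor n
  Dp <- duplication_matrix(p)
  Kr <- fit$Sinv %x% fit$Sinv
  V <- 0.5 * t(Dp) %*% Kr %*% Dp
  d <- sem_derivs(fit$spec, fit$theta)
  Delta <- vapply(d$dSigma, vech, numeric(p * (p + 1) / 2))
  H <- t(Delta) %*% V %*% Delta
  bread <- tryCatch(solve(H), error = function(e)
    stop(structure(class = c("otispath_rank_deficient", "error", "condition"),
                   list(message = "rank-deficient score matrix", call = NULL))))
  meat <- t(Delta) %*% V %*% Gamma %*% V %*% Delta
  vc <- bread %*% meat %*% bread / (n - 1)
  dimnames(vc) <- list(fit$spec$free$label, fit$spec$free$label)
  U <- V - V %*% Delta %*% bread %*% t(Delta) %*% V
  cc <- if (fit$df > 0) sum(U * t(Gamma)) / fit$df else NA_real_
  fit$robust <- list(vcov = vc, se = sqrt(pmax(diag(vc), 0)), c = cc,
                     T_scaled = if (fit$df > 0) fit$T / cc else 0,
                     Gamma = Gamma, V = V, Delta = Delta, U = U)
  fit
}
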