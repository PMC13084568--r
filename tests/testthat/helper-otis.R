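# shared fixtures, built once per test run
.fixture_env <- new.env(parent = emptyenv())

# cached cohort under the trial-calibrated preset
trial_cohort <- function(n_per_group = 300, seed = 42) {
  key <- sprintf("trial_%d_%d", n_per_group, seed)
  if (is.null(.fixture_env[[key]])) {
    p <- solve_error_variances(otis_preset(n_per_group = n_per_group))
    .fixture_env[[key]] <- generate_cohort(p, seed = seed)
  }
  .fixture_env[[key]]
}

# random fully-recursive just-identified path model plus matching data
random_recursive_model <- function(p, n, seed) {
  set.seed(seed)
  vars <- paste0("v", seq_len(p))
  lines <- vapply(2:p, function(i)
    paste(vars[i], "~", paste(vars[seq_len(i - 1)], collapse = " + ")), "")
  spec <- parse_model(paste(lines, collapse = "\n"), variables = vars)
  L <- diag(p)
  L[lower.tri(L)] <- stats::rnorm(p * (p - 1) / 2, sd = 0.5)
  X <- matrix(stats::rnorm(n * p), n, p) %*% t(L * sample(c(1, 2), 1))
  colnames(X) <- vars
  list(spec = spec, data = as.data.frame(X))
}

# brute-force exact two-sided Mann-Whitney p by label enumeration
mw_exact_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  z <- c(x, y)
  r <- rank(z)
  u_of <- function(idx) sum(r[idx]) - nx * (nx + 1) / 2
  u_obs <- u_of(seq_len(nx))
  combs <- utils::combn(nx + ny, nx)
  us <- apply(combs, 2, u_of)
  m <- nx * ny
  mean(pmin(us, m - us) <= min(u_obs, m - u_obs) + 1e-9)
}
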