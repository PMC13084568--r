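# Derive a reproducible 31-bit sub-seed for a named simulation stage from a
# single user-visible seed, so stages draw from independent streams.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + h * 16807) %% (2^31 - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# standardize to mean 0, sd 1 (sd with n-1 divisor); constant input errors
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot z-score a constant variable")
  (x - mean(x)) / s
}

is_binary01 <- function(x) all(x %in% c(0, 1))

# condition constructors used across modules
infeasible_preset <- function(msg) {
  structure(class = c("otispath_infeasible_preset", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}
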