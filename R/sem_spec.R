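#' Parse a path-model specification
#'
#' Builds an observed-variable covariance-structure model from a compact
#' text syntax: one statement per line (or separated by \code{;}), with
#' \code{y ~ x1 + x2} declaring regressions and \code{a ~~ b} declaring a
#' free (co)variance. A numeric premultiplier fixes a parameter
#' (\code{y ~ 0.5*x}, \code{e ~~ 1*e}). Comments start with \code{#}.
#'
#' Every variable receives a free variance unless fixed explicitly;
#' variables never appearing on the left of \code{~} are exogenous and, by
#' default, covary freely with each other. The model is stored in RAM form:
#' a path matrix \code{B} (rows = dependents) and a symmetric residual
#' (co)variance matrix \code{Psi}, from which the implied covariance is
#' \eqn{\Sigma = (I-B)^{-1} \Psi (I-B)^{-T}}.
#'
#' @param text model syntax.
#' @param variables optional character vector declaring (and ordering) the
#'   observed variables; mentions of anything else raise an error.
#' @param exog_cov free the covariances among exogenous variables
#'   (default \code{TRUE}).
#' @param fixed_exog_var fix exogenous variances at the value supplied
#'   instead of freeing them (named numeric vector), mostly for tests.
#' @return An object of class \code{sem_spec}: \code{variables}, \code{B},
#'   \code{Psi} (numeric matrices of fixed values), \code{free} (data.frame
#'   of free cells: matrix/row/col/label), \code{endogenous},
#'   \code{exogenous}.
#' @export
parse_model <- function(text, variables = NULL, exog_cov = TRUE,
                        fixed_exog_var = NULL) {
  lines <- unlist(strsplit(text, "[\n;]"))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  stmts <- list()
  for (ln in lines) {
    op <- if (grepl("~~", ln, fixed = TRUE)) "~~" else if
    (grepl("~", ln, fixed = TRUE)) "~" else
      stop("cannot parse statement: ", ln)
    parts <- strsplit(ln, if (op == "~~") "~~" else "(?<![~])~(?![~])",
                      perl = (op == "~"), fixed = (op == "~~"))[[1]]
    if (length(parts) != 2) stop("cannot parse statement: ", ln)
    lhs <- trimws(parts[1])
    terms <- trimws(unlist(strsplit(parts[2], "+", fixed = TRUE)))
    for (tm in terms) {
      fix <- NA_real_
      var <- tm
      if (grepl("*", tm, fixed = TRUE)) {
        bits <- trimws(strsplit(tm, "*", fixed = TRUE)[[1]])
        fix <- suppressWarnings(as.numeric(bits[1]))
        if (is.na(fix)) stop("non-numeric premultiplier in: ", tm)
        var <- bits[2]
      }
      stmts[[length(stmts) + 1L]] <- list(op = op, lhs = lhs, rhs = var,
                                          fix = fix)
    }
  }
  seen <- unique(unlist(lapply(stmts, function(s) c(s$lhs, s$rhs))))
  if (is.null(variables)) variables <- seen
  unknown <- setdiff(seen, variables)
  if (length(unknown))
    stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  p <- length(variables)
  B <- Psi <- matrix(0, p, p, dimnames = list(variables, variables))
  free <- data.frame(matrix = character(0), row = integer(0),
                     col = integer(0), label = character(0),
                     stringsAsFactors = FALSE)
  seen_path <- character(0)
  add_free <- function(mat, i, j, label) {
    free <<- rbind(free, data.frame(matrix = mat, row = i, col = j,
                                    label = label, stringsAsFactors = FALSE))
  }
  endo <- unique(vapply(Filter(function(s) s$op == "~", stmts),
                        `[[`, "", "lhs"))
  for (s in stmts) {
    i <- match(s$lhs, variables); j <- match(s$rhs, variables)
    if (s$op == "~") {
      if (s$lhs == s$rhs)
        stop(structure(class = c("otispath_cycle", "error", "condition"),
                       list(message = paste0("cycle detected: ", s$lhs,
                                             " ~ ", s$rhs), call = NULL)))
      key <- paste(s$lhs, "~", s$rhs)
      if (key %in% seen_path) stop("duplicate path: ", key)
      seen_path <- c(seen_path, key)
      if (is.na(s$fix)) add_free("B", i, j, key) else B[i, j] <- s$fix
    } else {
      key <- paste(min(s$lhs, s$rhs), "~~", max(s$lhs, s$rhs))
      if (key %in% seen_path) stop("duplicate (co)variance: ", key)
      seen_path <- c(seen_path, key)
      if (is.na(s$fix)) add_free("Psi", max(i, j), min(i, j), key)
      else Psi[i, j] <- Psi[j, i] <- s$fix
    }
  }
  exog <- setdiff(variables, endo)
  # default variances
  for (v in variables) {
    i <- match(v, variables)
    mentioned <- any(free$matrix == "Psi" & free$row == i & free$col == i) ||
      Psi[i, i] != 0
    if (mentioned) next
    if (v %in% names(fixed_exog_var %||% c())) {
      Psi[i, i] <- fixed_exog_var[[v]]
    } else {
      add_free("Psi", i, i, paste(v, "~~", v))
    }
  }
  # free exogenous covariances
  if (exog_cov && length(exog) > 1) {
    ex <- match(exog, variables)
    for (a in seq_along(ex)) for (b in seq_len(a - 1L)) {
      i <- max(ex[a], ex[b]); j <- min(ex[a], ex[b])
      key <- paste(min(variables[i], variables[j]), "~~",
                   max(variables[i], variables[j]))
      if (!key %in% seen_path) add_free("Psi", i, j, key)
    }
  }
  spec <- structure(list(variables = variables, B = B, Psi = Psi,
                         free = free, endogenous = endo, exogenous = exog),
                    class = "sem_spec")
  check_acyclic(spec)
  spec
}

# topological-sort cycle check over the union of free and fixed B cells
check_acyclic <- function(spec) {
  p <- length(spec$variables)
  adj <- spec$B != 0
  fb <- spec$free[spec$free$matrix == "B", ]
  adj[cbind(fb$row, fb$col)] <- TRUE
  indeg <- rowSums(adj)
  order <- integer(0)
  active <- rep(TRUE, p)
  repeat {
    src <- which(active & indeg == 0)
    if (!length(src)) break
    order <- c(order, src)
    active[src] <- FALSE
    indeg <- as.numeric(adj %*% as.numeric(active))
  }
  if (any(active))
    stop(structure(class = c("otispath_cycle", "error", "condition"),
                   list(message = paste("cycle detected among:",
                                        paste(spec$variables[active],
                                              collapse = ", ")), call = NULL)))
  invisible(rev(order))
}

n_free <- function(spec) nrow(spec$free)

# fill B and Psi with a free-parameter vector
theta_to_mats <- function(spec, theta) {
  stopifnot(length(theta) == n_free(spec))
  B <- spec$B; Psi <- spec$Psi
  f <- spec$free
  for (k in seq_len(nrow(f))) {
    if (f$matrix[k] == "B") B[f$row[k], f$col[k]] <- theta[k]
    else {
      Psi[f$row[k], f$col[k]] <- theta[k]
      Psi[f$col[k], f$row[k]] <- theta[k]
    }
  }
  list(B = B, Psi = Psi)
}

#' Model-implied covariance matrix
#'
#' \eqn{\Sigma(\theta) = (I-B)^{-1} \Psi (I-B)^{-T}}, with exogenous
#' variances and covariances housed in \eqn{\Psi}.
#'
#' @param spec a \code{\link{parse_model}} specification.
#' @param theta free-parameter vector (length \code{nrow(spec$free)}).
#' @return The implied covariance matrix (p x p).
#' @export
implied_covariance <- function(spec, theta) {
  m <- theta_to_mats(spec, theta)
  p <- length(spec$variables)
  IB <- diag(p) - m$B
  A <- tryCatch(solve(IB), error = function(e)
    stop(structure(class = c("otispath_singular", "error", "condition"),
                   list(message = "(I - B) is singular", call = NULL))))
  Sigma <- A %*% m$Psi %*% t(A)
  dimnames(Sigma) <- list(spec$variables, spec$variables)
  (Sigma + t(Sigma)) / 2
}

#' @export
print.sem_spec <- function(x, ...) {
  cat("Path-model specification:", length(x$variables), "observed variables,",
      n_free(x), "free parameters\n")
  cat("  endogenous:", paste(x$endogenous, collapse = ", "), "\n")
  cat("  exogenous: ", paste(x$exogenous, collapse = ", "), "\n")
  invisible(x)
}
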