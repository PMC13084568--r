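#' Generalized log transform
#'
#' Variance-stabilising transform for concentration data, defined for zero
#' values: \eqn{glog(y) = \ln(y + \sqrt{y^2 + \lambda})}. With the default
#' \eqn{\lambda = 1}, \code{glog(0) == 0}.
#'
#' @param y non-negative concentrations (vector or matrix).
#' @param lambda positive offset parameter (concentration squared units).
#' @return Transformed values, same shape as \code{y}.
#' @examples
#' glog(0)          # 0
#' glog(3)          # log(3 + sqrt(10))
#' @export
glog <- function(y, lambda = 1) {
  stopifnot(lambda > 0)
  if (any(y < 0, na.rm = TRUE)) stop("glog expects non-negative concentrations")
  log(y + sqrt(y^2 + lambda))
}

#' PCA of the combined metabolite panel
#'
#' Principal component analysis of the glog-transformed panel over the
#' combined 12- and 18-mo samples, each variable centred and scaled by its
#' standard deviation (i.e. an eigendecomposition of the correlation
#' structure). Returns scores stratifiable by timepoint, per-variable
#' contributions to each component, and 95\% confidence ellipses per group
#' on the first two components.
#'
#' @param panel numeric matrix, samples x metabolites (raw concentrations;
#'   glog is applied internally unless \code{transform = FALSE}).
#' @param groups factor-like group labels per sample.
#' @param timepoints optional per-sample timepoint labels carried into the
#'   score table.
#' @param lambda glog parameter.
#' @param transform apply \code{\link{glog}} before PCA.
#' @return List of class \code{otis_pca}: \code{scores} (data.frame with
#'   group/timepoint), \code{explained} (variance fractions),
#'   \code{contributions} (percent, columns sum to 100),
#'   \code{expected_mean_contribution} (100/p), \code{ellipses} (per group:
#'   center, axis half-lengths, angle), \code{rotation}, \code{center},
#'   \code{scale}, \code{dropped} (constant variables removed).
#' @export
pca_combined <- function(panel, groups, timepoints = NULL, lambda = 1,
                         transform = TRUE) {
  panel <- as.matrix(panel)
  stopifnot(nrow(panel) >= 3, !anyNA(panel))
  X <- if (transform) glog(panel, lambda) else panel
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant variable(s): ", paste(dropped, collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  contrib <- 100 * sweep(pc$rotation^2, 2, colSums(pc$rotation^2), "/")
  scores <- as.data.frame(pc$x)
  scores$group <- as.character(groups)
  if (!is.null(timepoints)) scores$timepoint <- timepoints
  ell <- if (ncol(X) >= 2) {
    lapply(split(seq_len(nrow(scores)), scores$group), function(i) {
      s <- as.matrix(scores[i, c("PC1", "PC2")])
      score_ellipse(s, level = 0.95)
    })
  } else list()
  structure(list(scores = scores, explained = expl, contributions = contrib,
                 expected_mean_contribution = 100 / ncol(X),
                 ellipses = ell, rotation = pc$rotation, center = pc$center,
                 scale = pc$scale, dropped = dropped),
            class = "otis_pca")
}

# 95% confidence ellipse of 2-D scores from their covariance, scaled by the
# bivariate t (Hotelling) quantile; normal-quantile fallback for large n.
score_ellipse <- function(s, level = 0.95) {
  n <- nrow(s)
  ctr <- colMeans(s)
  V <- stats::cov(s)
  r2 <- if (n <= 3) stats::qchisq(level, 2) else if (n < 500)
    2 * (n - 1) / (n - 2) * stats::qf(level, 2, n - 2) else
      stats::qchisq(level, 2)
  e <- eigen(V, symmetric = TRUE)
  list(center = ctr, axes = sqrt(pmax(e$values, 0) * r2),
       angle = atan2(e$vectors[2, 1], e$vectors[1, 1]), n = n)
}

#' Canberra distance matrix
#'
#' \eqn{d(x, y) = \sum_j |x_j - y_j| / (|x_j| + |y_j|)}, with terms whose
#' numerator and denominator are both zero skipped. No rescaling by the
#' number of contributing terms is applied, so on strictly positive data
#' the result equals \code{dist(method = "canberra")}.
#'
#' @param X numeric matrix, samples x variables, non-negative entries.
#' @return A symmetric \code{samples x samples} matrix with zero diagonal.
#' @export
canberra_matrix <- function(X) {
  X <- as.matrix(X)
  if (any(X < 0, na.rm = TRUE)) stop("Canberra distance expects non-negative data")
  n <- nrow(X)
  D <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    num <- abs(outer(x, x, "-"))
    den <- outer(abs(x), abs(x), "+")
    term <- ifelse(den == 0, 0, num / den)
    D <- D + term
  }
  D
}

#' Distance-based permutational multivariate ANOVA
#'
#' Partitions the squared inter-sample distances into between- and
#' within-group components and tests the pseudo-F statistic by free
#' permutation of the group labels (one-factor design, no strata):
#' \eqn{SS_{total} = \frac{1}{n}\sum_{i<j} d_{ij}^2},
#' \eqn{SS_{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2},
#' \eqn{F = \frac{SS_{between}/(g-1)}{SS_{within}/(n-g)}}, and
#' \eqn{p = (1 + \#\{F^\pi \ge F\}) / (1 + n_{perm})}.
#'
#' @param D distance matrix (square symmetric matrix or \code{dist}).
#' @param groups group labels, at least two groups with two members each.
#' @param n_perm number of label permutations (trial analysis: 999), or
#'   \code{"exhaustive"} to enumerate every distinct relabelling (small n
#'   only).
#' @param seed optional seed for the permutation stream.
#' @return List of class \code{otis_permanova}: \code{pseudo_F}, \code{R2},
#'   \code{p_perm}, \code{n_perm}, \code{SS_total}, \code{SS_between},
#'   \code{SS_within}, \code{df}, \code{dispersion_p} (\code{NA}; filled by
#'   \code{\link{dispersion_homogeneity}} callers).
#' @export
permanova <- function(D, groups, n_perm = 999, seed = NULL) {
  D <- as.matrix(D)
  n <- nrow(D)
  groups <- as.factor(groups)
  stopifnot(length(groups) == n, n == ncol(D))
  if (nlevels(droplevels(groups)) < 2 || any(table(groups) < 2))
    stop("need at least two groups with at least two members each")
  groups <- droplevels(groups)
  g <- nlevels(groups)
  D2 <- D^2
  ss_total <- sum(D2[upper.tri(D2)]) / n
  Z <- stats::model.matrix(~ groups - 1)          # n x g indicators
  ss_within_of <- function(Z) {
    # sum_g (1/n_g) sum_{i<j in g} d2 = sum_g z'D2z / (2 n_g)
    quad <- colSums(Z * (D2 %*% Z))
    sum(quad / (2 * colSums(Z)))
  }
  ssw <- ss_within_of(Z)
  ssb <- ss_total - ssw
  Fobs <- (ssb / (g - 1)) / (ssw / (n - g))
  if (identical(n_perm, "exhaustive")) {
    stopifnot(g == 2)
    n1 <- sum(groups == levels(groups)[1])
    combs <- utils::combn(n, n1)
    Fs <- apply(combs, 2, function(idx) {
      z <- matrix(0, n, 2); z[idx, 1] <- 1; z[-idx, 2] <- 1
      ssw_p <- ss_within_of(z)
      ((ss_total - ssw_p) / (g - 1)) / (ssw_p / (n - g))
    })
    p <- mean(Fs >= Fobs - 1e-12)   # observed labelling is one of them
    np <- ncol(combs)
  } else {
    if (!is.null(seed)) set.seed(seed)
    # all permutations at once: one BLAS product per group block
    P <- replicate(n_perm, sample.int(n))
    ssw_p <- numeric(n_perm)
    ng <- colSums(Z)
    for (k in seq_len(g)) {
      Gk <- matrix(Z[, k][P], n, n_perm)
      ssw_p <- ssw_p + colSums(Gk * (D2 %*% Gk)) / (2 * ng[k])
    }
    Fs <- ((ss_total - ssw_p) / (g - 1)) / (ssw_p / (n - g))
    p <- (1 + sum(Fs >= Fobs - 1e-12)) / (1 + n_perm)
    np <- n_perm
  }
  structure(list(pseudo_F = Fobs, R2 = ssb / ss_total, p_perm = p,
                 n_perm = np, SS_total = ss_total, SS_between = ssb,
                 SS_within = ssw, df = c(between = g - 1, within = n - g),
                 dispersion_p = NA_real_),
            class = "otis_permanova")
}

#' @export
print.otis_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.4f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$R2, x$p_perm, x$n_perm))
  if (!is.na(x$dispersion_p))
    cat(sprintf("  dispersion homogeneity p = %.3f\n", x$dispersion_p))
  invisible(x)
}

#' Homogeneity of multivariate dispersion
#'
#' Assumption check for PERMANOVA: embeds the distance matrix by principal
#' coordinates, measures each sample's distance to its group centroid in
#' that space, and tests equality of mean dispersion across groups with a
#' one-way ANOVA F-test (a non-significant result supports the homogeneity
#' assumption). Backed by \code{vegan::betadisper}.
#'
#' @inheritParams permanova
#' @return The ANOVA p-value.
#' @export
dispersion_homogeneity <- function(D, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2 || any(table(groups) < 2))
    stop("need at least two groups with at least two members each")
  bd <- vegan::betadisper(stats::as.dist(D), droplevels(groups),
                          type = "centroid")
  stats::anova(bd)[["Pr(>F)"]][1]
}

# Tie-corrected normal-approximation Z for the Mann-Whitney U statistic,
# with continuity correction (the classic wilcox.test construction).
mw_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 * ((n1 + n2 + 1) -
                            sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  if (sig2 <= 0) return(list(U = U, Z = 0))
  d <- U - mu
  cc <- sign(d) * 0.5
  list(U = U, Z = (d - cc) / sqrt(sig2))
}

#' Mann-Whitney panel test with BH correction and effect sizes
#'
#' Two-sided Mann-Whitney U tests per metabolite between two diet groups,
#' Benjamini-Hochberg adjustment across the panel (one timepoint = one
#' family by default), and Wilcoxon effect sizes \eqn{r = |Z|/\sqrt{n}}
#' classed small (0.1-0.3), moderate (0.3-0.5) or large (>0.5). The default
#' test is the tie-corrected normal approximation with continuity
#' correction; \code{exact = TRUE} switches to the exact distribution
#' (small samples, no ties). Because the test is rank-based, glog or any
#' monotone transform leaves p unchanged; concentrations are therefore
#' reported untransformed.
#'
#' @param panel numeric matrix or data.frame, samples x metabolites.
#' @param groups two-level group labels per sample.
#' @param alpha FDR threshold used for the \code{significant} flag.
#' @param exact use the exact U distribution (via \code{wilcox.test}).
#' @return data.frame of class \code{otis_volcano}: one row per metabolite
#'   with \code{U}, \code{p_raw}, \code{q_bh}, \code{effect_size_r},
#'   \code{size_class}, \code{direction} (group with the higher median),
#'   \code{significant}.
#' @export
mw_fdr_panel <- function(panel, groups, alpha = 0.05, exact = FALSE) {
  panel <- as.data.frame(panel)
  groups <- as.factor(groups)
  stopifnot(nlevels(droplevels(groups)) == 2)
  groups <- droplevels(groups)
  lv <- levels(groups)
  rows <- lapply(names(panel), function(m) {
    v <- panel[[m]]
    ok <- !is.na(v)
    x <- v[ok & groups == lv[1]]
    y <- v[ok & groups == lv[2]]
    n <- length(x) + length(y)
    if (length(unique(c(x, y))) == 1L) {
      return(data.frame(metabolite = m, U = length(x) * length(y) / 2,
                        p_raw = 1, effect_size_r = 0,
                        direction = NA_character_))
    }
    z <- mw_z(x, y)
    p <- if (exact)
      suppressWarnings(
        stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)$p.value)
    else
      min(1, 2 * stats::pnorm(-abs(z$Z)))
    data.frame(metabolite = m, U = z$U, p_raw = p,
               effect_size_r = abs(z$Z) / sqrt(n),
               direction = if (z$U == length(x) * length(y) / 2) NA_character_
               else if (z$U > length(x) * length(y) / 2) lv[1] else lv[2])
  })
  out <- do.call(rbind, rows)
  out$q_bh <- stats::p.adjust(out$p_raw, method = "BH")
  out$size_class <- cut(out$effect_size_r, c(-Inf, 0.1, 0.3, 0.5, Inf),
                        labels = c("negligible", "small", "moderate", "large"))
  out$significant <- out$q_bh < alpha
  out <- out[, c("metabolite", "U", "p_raw", "q_bh", "effect_size_r",
                 "size_class", "direction", "significant")]
  class(out) <- c("otis_volcano", "data.frame")
  out
}
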