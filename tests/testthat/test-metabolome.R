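test_that("generalized log transform matches its closed form", {
  expect_equal(glog(0), 0)
  expect_equal(glog(3), log(3 + sqrt(10)))          # 1.818446...
  expect_equal(glog(3), 1.81845, tolerance = 1e-5)
  y <- seq(0, 10, by = 0.25)
  expect_true(all(diff(glog(y)) > 0))               # strictly increasing
  expect_equal(glog(2, lambda = 4), log(2 + sqrt(8)))
  expect_error(glog(-1), "non-negative")
  expect_error(glog(1, lambda = 0))
})

test_that("PCA contributions and reconstruction behave as specified", {
  set.seed(2)
  x <- rexp(10)
  panel <- cbind(a = x, b = 2 * x, c = rexp(10))
  res <- pca_combined(panel, groups = rep(c("g1", "g2"), 5))
  # two perfectly correlated variables: PC1 of the pair explains all of it
  r2 <- pca_combined(cbind(a = x, b = 2 * x),
                     groups = rep(c("g1", "g2"), 5), transform = FALSE)
  expect_equal(r2$explained[1], 1, tolerance = 1e-10)
  expect_equal(unname(colSums(res$contributions)),
               rep(100, ncol(res$contributions)), tolerance = 1e-9)
  expect_equal(res$expected_mean_contribution, 100 / 3)
  # scores times loadings reproduce the centred/scaled data
  X <- scale(glog(panel))
  scores <- as.matrix(res$scores[, c("PC1", "PC2", "PC3")])
  expect_equal(unname(scores %*% t(res$rotation)), unname(X),
               ignore_attr = TRUE, tolerance = 1e-10)
  # ellipse parameters are well formed
  expect_true(all(vapply(res$ellipses, function(e) all(e$axes >= 0), TRUE)))
})

test_that("constant variables are dropped from the PCA with a warning", {
  panel <- cbind(a = rexp(8), b = rep(2, 8))
  expect_warning(res <- pca_combined(panel, groups = rep(c("x", "y"), 4)),
                 "constant")
  expect_equal(res$dropped, "b")
})

test_that("Canberra distance matches hand computation", {
  expect_equal(canberra_matrix(rbind(c(1, 0), c(0, 1)))[1, 2], 2)
  X <- rbind(c(1, 2, 0), c(2, 0, 1), c(0, 1, 1))
  D <- canberra_matrix(X)
  expect_equal(D[1, 2], 1 / 3 + 1 + 1)
  expect_equal(D[1, 3], 1 + 1 / 3 + 1)
  expect_equal(D[2, 3], 1 + 1 + 0)
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 3))
  # agrees with dist() on strictly positive data
  Y <- matrix(rexp(40) + 0.1, 8)
  expect_equal(canberra_matrix(Y)[lower.tri(diag(8))],
               as.numeric(dist(Y, method = "canberra")), tolerance = 1e-12)
})

test_that("PERMANOVA partitions match vegan and its invariances hold", {
  set.seed(5)
  X <- matrix(rexp(26 * 6), 26)
  g <- rep(c("a", "b"), 13)
  D <- canberra_matrix(X)
  pm <- permanova(D, g, n_perm = 199, seed = 1)
  ad <- vegan::adonis2(as.dist(D) ~ g, permutations = 199)
  expect_equal(pm$pseudo_F, ad$F[1], tolerance = 1e-10)
  expect_equal(pm$R2, ad$R2[1], tolerance = 1e-10)
  expect_equal(pm$SS_total, ad$SumOfSqs[3], tolerance = 1e-10)  # Total row
  expect_equal(pm$R2, pm$SS_between / pm$SS_total)
  expect_gte(pm$p_perm, 1 / 200)
  # invariant to sample reordering
  o <- sample(26)
  pm2 <- permanova(D[o, o], g[o], n_perm = 199, seed = 1)
  expect_equal(pm2$R2, pm$R2, tolerance = 1e-10)
  expect_equal(pm2$pseudo_F, pm$pseudo_F, tolerance = 1e-10)
  # F invariant to scaling the distances
  pm3 <- permanova(5 * D, g, n_perm = 99, seed = 1)
  expect_equal(pm3$pseudo_F, pm$pseudo_F, tolerance = 1e-10)
})

test_that("identical duplicated groups give R2 = 1", {
  X <- rbind(c(1, 2), c(1, 2), c(5, 9), c(5, 9))
  D <- canberra_matrix(X)
  pm <- permanova(D, c("a", "a", "b", "b"), n_perm = 23, seed = 1)
  expect_equal(pm$R2, 1)
  expect_equal(pm$SS_within, 0)
})

test_that("degenerate groupings are rejected", {
  D <- canberra_matrix(matrix(rexp(12), 4))
  expect_error(permanova(D, c("a", "a", "a", "a"), 99), "two groups")
  expect_error(permanova(D, c("a", "a", "a", "b"), 99), "two groups")
  expect_error(dispersion_homogeneity(D, rep("a", 4)), "two groups")
})

test_that("dispersion homogeneity test separates constructed cases", {
  set.seed(8)
  base <- matrix(rexp(15 * 4), 15)
  # one group five times more spread out
  ctr <- colMeans(base)
  wide <- sweep(sweep(base, 2, ctr), 1:2, 5, "*")
  wide <- sweep(wide, 2, ctr, "+") + 6    # keep positive
  X <- rbind(base + 6, wide)
  g <- rep(c("tight", "wide"), each = 15)
  p_het <- dispersion_homogeneity(canberra_matrix(X), g)
  expect_lt(p_het, 0.01)
  # symmetric case: same internal geometry, translated apart
  Y <- rbind(base, base + matrix(rep(c(50, 0, 0, 0), each = 15), 15))
  p_hom <- dispersion_homogeneity(as.matrix(dist(Y)), g)
  expect_gt(p_hom, 0.9)
  expect_true(p_het >= 0 && p_het <= 1)
})

test_that("Mann-Whitney panel matches exact enumeration and hand BH", {
  v <- mw_fdr_panel(data.frame(m = c(1, 2, 3, 4)), c("a", "a", "b", "b"),
                    exact = TRUE)
  expect_true(v$U %in% c(0, 4))
  expect_equal(v$p_raw, 1 / 3, tolerance = 1e-12)
  expect_equal(v$direction, "b")
  # identical groups
  vi <- mw_fdr_panel(data.frame(m = rep(1, 6)), rep(c("a", "b"), 3))
  expect_equal(vi$p_raw, 1)
  expect_equal(vi$effect_size_r, 0)
  # BH on (0.01, 0.02, 0.03, 0.04) flattens to 0.04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  panel <- data.frame(a = c(1, 2, 3, 9, 10, 11), b = c(5, 6, 4, 5, 6, 4),
                      c = c(1, 5, 2, 6, 3, 7), d = c(2, 1, 3, 8, 9, 10))
  g <- rep(c("x", "y"), each = 3)
  out <- mw_fdr_panel(panel, g, exact = TRUE)
  oracle <- vapply(names(panel), function(m)
    mw_exact_oracle(panel[[m]][g == "x"], panel[[m]][g == "y"]), 0)
  no_ties <- vapply(names(panel), function(m)
    !any(duplicated(panel[[m]])), TRUE)
  expect_equal(out$p_raw[no_ties], unname(oracle[no_ties]),
               tolerance = 1e-12)
})

test_that("normal-approximation p agrees with wilcox.test and effect sizes class correctly", {
  set.seed(9)
  x <- rnorm(30); y <- rnorm(30) + 0.8
  out <- mw_fdr_panel(data.frame(m = c(x, y)),
                      rep(c("a", "b"), each = 30))
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(out$p_raw, ref$p.value, tolerance = 1e-10)
  expect_true(out$size_class %in% c("small", "moderate", "large"))
  expect_equal(as.character(cut(c(0.05, 0.2, 0.4, 0.7),
                                c(-Inf, 0.1, 0.3, 0.5, Inf),
                                labels = c("negligible", "small",
                                           "moderate", "large"))),
               c("negligible", "small", "moderate", "large"))
})

test_that("rank-based tests are invariant to the glog transform", {
  set.seed(10)
  panel <- matrix(rexp(40 * 5), 40)
  colnames(panel) <- paste0("m", 1:5)
  g <- rep(c("a", "b"), 20)
  raw <- mw_fdr_panel(panel, g)
  trans <- mw_fdr_panel(glog(panel), g)
  expect_equal(raw$p_raw, trans$p_raw, tolerance = 1e-12)
  expect_equal(raw$U, trans$U)
})

test_that("trial-preset panel flags the reported metabolites at 12 mo", {
  # the reported 12-mo signature at roughly the trial's sample size
  p <- solve_error_variances(otis_preset(n_per_group = 100))
  sch <- metabolite_schema()
  down <- sch$column[!is.na(sch$dir12) & sch$dir12 == -1]
  down <- c(down, paste0("m_", c("leucine", "isoleucine", "valine")))
  up <- sch$column[!is.na(sch$dir12) & sch$dir12 == +1]
  hits <- sapply(1:10, function(i) {
    co <- generate_cohort(p, seed = 600 + i)
    rows <- co[co$visit_age == 12, ]
    v <- mw_fdr_panel(rows[, grep("^m_", names(rows))], rows$group)
    lower <- v$metabolite[v$significant & v$direction == "conventional"]
    higher <- v$metabolite[v$significant & v$direction == "nordic"]
    c(mean(down %in% lower), mean(up %in% higher))
  })
  # the reported signature is recovered, with its direction, in >= 90% of
  # metabolite-replicate pairs
  expect_gte(mean(hits[1, ]), 0.9)
  expect_gte(mean(hits[2, ]), 0.9)
})
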