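rot <- function(angle) {
  matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
}

test_that("trait fits recover exact linear structure in the score plane", {
  set.seed(21)
  scores <- matrix(rnorm(120 * 2), 120, 2,
                   dimnames = list(sprintf("sp%03d", 1:120), c("PC1", "PC2")))
  # trait equal to PC1: direction (1, 0), r2 = 1
  f1 <- trait_fit(scores, stats::setNames(scores[, 1], rownames(scores)),
                  n_perm = 99, seed = 1, trait_name = "pc1_copy")
  expect_equal(f1$direction, c(1, 0), tolerance = 1e-6)
  expect_equal(f1$r_squared, 1, tolerance = 1e-6)
  expect_true(f1$significant)
  # trait = PC1 + PC2: the diagonal
  f2 <- trait_fit(scores, stats::setNames(scores[, 1] + scores[, 2],
                                          rownames(scores)),
                  n_perm = 99, seed = 1, trait_name = "diag")
  expect_equal(f2$direction, c(1, 1) / sqrt(2), tolerance = 1e-6)
  expect_error(trait_fit(scores, stats::setNames(rep(1, 120), rownames(scores)),
                         trait_name = "flat"), "constant")
  expect_error(trait_fit(scores[1:4, ], stats::setNames(rnorm(4), rownames(scores)[1:4])),
               "fewer than 5")
})

test_that("trait r2 equals an independent normal-equations solve", {
  set.seed(22)
  scores <- matrix(rnorm(80 * 2), 80, 2,
                   dimnames = list(sprintf("sp%02d", 1:80), NULL))
  trait <- stats::setNames(0.6 * scores[, 1] - 0.2 * scores[, 2] + rnorm(80),
                           rownames(scores))
  fit <- trait_fit(scores, trait, n_perm = 99, seed = 2, trait_name = "tr")
  X <- cbind(1, scores)
  beta <- solve(t(X) %*% X, t(X) %*% trait)
  pred <- X %*% beta
  r2 <- 1 - sum((trait - pred)^2) / sum((trait - mean(trait))^2)
  expect_equal(fit$r_squared, r2, tolerance = 1e-10)
  expect_equal(fit$direction, as.numeric(beta[2:3]) / sqrt(sum(beta[2:3]^2)),
               tolerance = 1e-10)
})

test_that("right-skewed positive traits are log-transformed before fitting", {
  set.seed(23)
  scores <- matrix(rnorm(60 * 2), 60, 2,
                   dimnames = list(sprintf("s%02d", 1:60), NULL))
  trait <- stats::setNames(exp(scores[, 1] * 2 + rnorm(60, sd = 0.1)),
                           rownames(scores))
  fit <- trait_fit(scores, trait, n_perm = 99, seed = 3, trait_name = "skewed")
  expect_true(fit$logged)
  expect_gt(fit$r_squared, 0.9)   # linear after the log
})

test_that("procrustes similarity is exact for similarity transforms", {
  set.seed(24)
  A <- matrix(rnorm(20 * 2), 20, 2, dimnames = list(sprintf("p%02d", 1:20), NULL))
  B <- 2 * (A %*% rot(37 * pi / 180)) + 5
  res <- procrustes_compare(A, B, n_perm = 99, seed = 1)
  expect_equal(res$r, 1, tolerance = 1e-10)
  expect_equal(res$m2, 0, tolerance = 1e-10)
  # reflection too
  Brefl <- B %*% diag(c(-1, 1))
  expect_equal(procrustes_compare(A, Brefl, n_perm = 99, seed = 1)$r, 1,
               tolerance = 1e-10)
  expect_error(procrustes_compare(A[1:2, ], B[1:2, ]), "at least 3")
})

test_that("procrustes r is symmetric and invariant over random configurations", {
  set.seed(25)
  for (rep in 1:25) {
    A <- matrix(rnorm(12 * 2), 12, 2)
    B <- matrix(rnorm(12 * 2), 12, 2)
    r_ab <- procrustes_compare(A, B, n_perm = 19, seed = 1)$r
    r_ba <- procrustes_compare(B, A, n_perm = 19, seed = 1)$r
    expect_equal(r_ab, r_ba, tolerance = 1e-10)
    # similarity transforms of either argument leave r unchanged
    B2 <- sweep(0.3 * (B %*% rot(runif(1, 0, 2 * pi))), 2, rnorm(2), "+")
    expect_equal(procrustes_compare(A, B2, n_perm = 19, seed = 1)$r, r_ab,
                 tolerance = 1e-10)
    expect_true(r_ab >= 0 && r_ab <= 1)
  }
})

test_that("perturbing one point lowers r smoothly from one", {
  set.seed(26)
  A <- matrix(rnorm(15 * 2), 15, 2)
  rs <- vapply(c(0.1, 0.5, 2), function(eps) {
    B <- A; B[1, ] <- B[1, ] + eps
    procrustes_compare(A, B, n_perm = 19, seed = 1)$r
  }, numeric(1))
  expect_true(all(rs < 1 & rs > 0))
  expect_true(all(diff(rs) < 0))
})

test_that("weighted global PCA reduces to the pooled PCA for equal weights", {
  set.seed(27)
  m1 <- low_rank_matrix(30, 9, 3, seed = 5, noise_sd = 0.4)
  m2 <- low_rank_matrix(30, 9, 3, seed = 6, noise_sd = 0.4)
  colnames(m1) <- colnames(m2) <- rate_columns()$column
  rownames(m1) <- sprintf("a%02d", 1:30); rownames(m2) <- sprintf("b%02d", 1:30)
  cfg <- fast_config(n_permutations = 50L)
  res <- global_weighted_pca(list(s1 = m1, s2 = m2), cfg)
  pooled <- pca_axes(rbind(m1, m2))
  expect_equal(res$var_prop, pooled$var_prop, tolerance = 1e-8)
  expect_equal(abs(res$loadings), abs(pooled$loadings), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(global_weighted_pca(list(s1 = m1), cfg), "at least 2")
})

test_that("duplicating one site's species leaves the weighted axes unchanged", {
  set.seed(28)
  m1 <- low_rank_matrix(25, 9, 3, seed = 7, noise_sd = 0.4)
  m2 <- low_rank_matrix(20, 9, 3, seed = 8, noise_sd = 0.4)
  colnames(m1) <- colnames(m2) <- rate_columns()$column
  rownames(m1) <- sprintf("a%02d", 1:25); rownames(m2) <- sprintf("b%02d", 1:20)
  m2dup <- rbind(m2, m2)
  rownames(m2dup) <- sprintf("b%02d", 1:40)
  cfg <- fast_config(n_permutations = 20L)
  r1 <- global_weighted_pca(list(s1 = m1, s2 = m2), cfg)
  r2 <- global_weighted_pca(list(s1 = m1, s2 = m2dup), cfg)
  expect_equal(abs(r1$loadings), abs(r2$loadings), tolerance = 1e-8)
  expect_equal(r1$eigenvalues, r2$eigenvalues, tolerance = 1e-8)
})

test_that("weighted PCA matches a direct weighted-covariance eigendecomposition", {
  set.seed(29)
  m1 <- low_rank_matrix(12, 9, 2, seed = 9, noise_sd = 0.3)
  m2 <- low_rank_matrix(8, 9, 2, seed = 10, noise_sd = 0.3)
  m2[, 1] <- -m2[, 1]   # planted axis flip in the smaller site
  colnames(m1) <- colnames(m2) <- rate_columns()$column
  rownames(m1) <- sprintf("a%02d", 1:12); rownames(m2) <- sprintf("b%02d", 1:8)
  x <- rbind(m1, m2)
  w <- c(rep(1 / 12, 12), rep(1 / 8, 8)); w <- w / sum(w)
  # oracle: eigenvalues of the weighted correlation matrix
  mu <- colSums(x * w)
  xc <- sweep(x, 2, mu)
  sdw <- sqrt(colSums(xc^2 * w))
  xs <- sweep(xc, 2, sdw, "/")
  C <- t(xs) %*% (xs * w)
  oracle <- eigen(C, symmetric = TRUE)
  res <- global_weighted_pca(list(s1 = m1, s2 = m2),
                             fast_config(n_permutations = 20L))
  expect_equal(res$eigenvalues, oracle$values, tolerance = 1e-8)
  expect_equal(abs(res$loadings), abs(oracle$vectors), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("hull peeling covers the requested fraction and nests by fraction", {
  set.seed(30)
  pts <- matrix(rnorm(40 * 2), 40, 2)
  hs <- hull_areas(pts, fractions = c(0.10, 0.50, 0.90))
  areas <- vapply(hs, function(h) h$area, numeric(1))
  expect_true(all(diff(areas) > 0))     # monotone in the fraction
  expect_equal(hs[["f0.90"]]$n_points, 36L)  # ceiling(0.9 * 40)
  expect_equal(hs[["f0.10"]]$n_points, 4L)
  # ten points at f = 0.9: exactly nine retained
  ten <- matrix(rnorm(20), 10, 2)
  h9 <- hull_areas(ten, fractions = 0.9)
  expect_equal(h9[["f0.90"]]$n_points, 9L)
  # points on a circle at f = 1: the hull is the full polygon
  ang <- seq(0, 2 * pi, length.out = 13)[-13]
  circ <- cbind(cos(ang), sin(ang))
  h <- hull_areas(circ, fractions = 1)
  expect_equal(h[["f1.00"]]$n_points, 12L)
  expect_equal(nrow(h[["f1.00"]]$polygon), 12L)
  expect_equal(h[["f1.00"]]$area, 12 * 0.5 * sin(2 * pi / 12), tolerance = 1e-10)
})

test_that("two planted clusters: cores disjoint, 90% hulls overlapping", {
  set.seed(31)
  a <- matrix(rnorm(60 * 2, sd = 1.2), 60, 2) + rep(c(-2, 0), each = 60)
  b <- matrix(rnorm(60 * 2, sd = 1.2), 60, 2) + rep(c(2, 0), each = 60)
  ha <- hull_areas(a); hb <- hull_areas(b)
  # cores separated along the planted axis
  expect_lt(max(ha[["f0.10"]]$polygon[, 1]), min(hb[["f0.10"]]$polygon[, 1]))
  # outer hulls overlap
  expect_gt(max(ha[["f0.90"]]$polygon[, 1]), min(hb[["f0.90"]]$polygon[, 1]))
  # degenerate collinear input warns and returns zero area
  line <- cbind(1:6, 2 * (1:6))
  expect_warning(h0 <- hull_areas(line, fractions = 1), "degenerate")
  expect_equal(h0[["f1.00"]]$area, 0)
})
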