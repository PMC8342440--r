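# CCA fitting, loadings, the age-axis correlation, and bootstrap inference.

test_that("CCA recovers trivial and oracle-checked canonical correlations", {
  set.seed(1)
  # identical single column: perfect correlation
  e <- matrix(rnorm(50), 50, 1)
  m <- fit_cca(e, e)
  expect_equal(m$canonical_corrs, 1, tolerance = 1e-10)
  expect_equal(m$n_factors, 1)
  # independent domains at large n: near-zero leading correlation
  e1 <- matrix(rnorm(20000), 10000, 2)
  e2 <- matrix(rnorm(20000), 10000, 2)
  expect_lt(fit_cca(e1, e2)$canonical_corrs[1], 0.05)
  # 3-component problems against the generalized-eigenvalue oracle
  for (i in 1:5) {
    x <- matrix(rnorm(80 * 3), 80, 3)
    y <- x %*% matrix(rnorm(9), 3, 3) + matrix(rnorm(80 * 3), 80, 3)
    got <- fit_cca(x, y)$canonical_corrs
    expect_equal(got, oracle_canonical_corrs(x, y), tolerance = 1e-8)
    # cross-check against the stock implementation as well
    expect_equal(got, stats::cancor(x, y)$cor, tolerance = 1e-8)
  }
  expect_error(fit_cca(cbind(x[, 1], x[, 1]), y), "rank-deficient")
})

test_that("CCA correlations are invariant to invertible basis transforms", {
  set.seed(2)
  x <- matrix(rnorm(300), 100, 3)
  y <- x + matrix(rnorm(300, 0, 0.8), 100, 3)
  base <- fit_cca(x, y)$canonical_corrs
  for (i in 1:5) {
    a <- matrix(rnorm(9), 3, 3)
    b <- matrix(rnorm(9), 3, 3)
    while (abs(det(a)) < 0.1) a <- matrix(rnorm(9), 3, 3)
    while (abs(det(b)) < 0.1) b <- matrix(rnorm(9), 3, 3)
    expect_equal(fit_cca(x %*% a, y %*% b)$canonical_corrs, base,
                 tolerance = 1e-6)
  }
})

test_that("factors are unit-variance, uncorrelated within domain, ordered", {
  set.seed(3)
  x <- matrix(rnorm(400), 100, 4)
  y <- x %*% matrix(rnorm(16), 4) + matrix(rnorm(400), 100, 4)
  m <- fit_cca(x, y)
  expect_equal(apply(m$factors_f1, 2, sd), rep(1, 4), tolerance = 1e-8,
               ignore_attr = TRUE)
  c1 <- cor(m$factors_f1)
  expect_lt(max(abs(c1[upper.tri(c1)])), 1e-6)
  expect_true(all(diff(m$canonical_corrs) <= 1e-12))
  # per-axis correlation equals the reported canonical correlation
  for (j in 1:4) {
    expect_equal(cor(m$factors_f1[, j], m$factors_f2[, j]),
                 m$canonical_corrs[j], tolerance = 1e-8)
  }
  # orientation toward a hold-out variable
  age <- x[, 1] + rnorm(100, 0, 0.5)
  mo <- fit_cca(x, y, orient = age)
  expect_gte(cor(mo$factors_f1[, 1] + mo$factors_f2[, 1], age), 0)
})

test_that("loadings are correlations with the expected equivariances", {
  set.seed(4)
  n <- 60
  f <- matrix(rnorm(n * 2), n, 2)
  d <- cbind(v1 = f[, 1],                          # equals a factor
             v2 = rnorm(n),                        # unrelated
             v3 = -f[, 2] + rnorm(n, 0, 0.1))
  l <- compute_loadings(d, f)
  expect_equal(unname(l["v1", 1]), 1, tolerance = 1e-10)
  expect_lt(abs(l["v2", 1]), 0.35)
  expect_true(all(l >= -1 & l <= 1))
  # sign equivariance: negating a factor negates its loading column
  l2 <- compute_loadings(d, f %*% diag(c(1, -1)))
  expect_equal(l2[, 2], -l[, 2], tolerance = 1e-12)
  expect_error(compute_loadings(d, cbind(f[, 1], 0)), "zero-variance")
})

test_that("the age-axis correlation is the square root of the model R^2", {
  set.seed(5)
  n <- 200
  f1 <- rnorm(n); f2 <- rnorm(n)
  # age exactly equal to one factor
  expect_equal(age_correlation(f1, f2, f1)$r_age, 1, tolerance = 1e-10)
  # matches lm on the same data
  age <- 2 * f1 - f2 + rnorm(n)
  fit <- age_correlation(f1, f2, age)
  ref <- summary(lm(age ~ f1 + f2))
  expect_equal(fit$r_age, sqrt(ref$r.squared), tolerance = 1e-10)
  expect_equal(fit$w1, unname(coef(lm(age ~ f1 + f2))[2]), tolerance = 1e-10)
  # independent of age at large n: near zero
  expect_lt(age_correlation(rnorm(5000), rnorm(5000), rnorm(5000))$r_age,
            0.06)
  expect_error(age_correlation(f1, rep(0, n), age), "zero-variance")
  expect_error(age_correlation(f1, f1, age), "collinear")
})

test_that("bootstrap null test is deterministic and detects perfect structure", {
  set.seed(6)
  n <- 500
  f1 <- rnorm(n); f2 <- rnorm(n)
  res <- bootstrap_null_p(f1, f2, f1, n_boot = 500, seed = 9)
  expect_equal(res$p_value, 0)
  res2 <- bootstrap_null_p(f1, f2, f1, n_boot = 500, seed = 9)
  expect_identical(res$null, res2$null)
  # permutation variant agrees qualitatively
  resp <- bootstrap_null_p(f1, f2, f1, n_boot = 500, seed = 9,
                           method = "permute")
  expect_equal(resp$p_value, 0)
  expect_error(bootstrap_null_p(f1, f2, f1, n_boot = 50), "n_boot")
})

test_that("bootstrap SE vanishes for perfect fits and shrinks like 1/sqrt(n)", {
  set.seed(7)
  f1 <- rnorm(400); f2 <- rnorm(400)
  perfect <- bootstrap_se(f1, f2, 2 * f1 + f2, n_boot = 300, seed = 1)
  expect_lt(perfect$se, 1e-10)
  mk <- function(n, seed) {
    set.seed(seed)
    a <- rnorm(n); b <- rnorm(n)
    y <- 0.7 * a + 0.4 * b + rnorm(n)
    bootstrap_se(a, b, y, n_boot = 400, seed = 2)$se
  }
  se100 <- mean(vapply(1:6, function(s) mk(100, s), numeric(1)))
  se400 <- mean(vapply(1:6, function(s) mk(400, s + 50), numeric(1)))
  expect_gt(se100 / se400, 1.4)
  expect_lt(se100 / se400, 2.6)
  # determinism
  expect_identical(bootstrap_se(f1, f2, f1 + f2, 200, seed = 3)$replicates,
                   bootstrap_se(f1, f2, f1 + f2, 200, seed = 3)$replicates)
})

test_that("planted cross-domain coupling is recovered by a plain CCA fit", {
  pc <- planted_axis_cohort(n_subjects = 600, rho_cross = 0.6,
                            r_age_latent = 0.65, seed = 21)
  p1 <- prep_model(pc$behavior, NULL, NULL, 4, use_spd = TRUE)
  p2 <- prep_model(pc$network, NULL, NULL, 4, use_spd = FALSE)
  m <- fit_cca(p1$basis$scores, p2$basis$scores, orient = pc$ages)
  # training fit overestimates slightly; population value is 0.6
  expect_equal(m$canonical_corrs[1], 0.6, tolerance = 0.08)
  fit <- age_correlation(m$factors_f1[, 1], m$factors_f2[, 1], pc$ages)
  expect_equal(fit$r_age, 0.65, tolerance = 0.08)
})
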