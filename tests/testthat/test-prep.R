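# Filtering, z-scoring, deconfounding, nearest-SPD rotation and PCA.

make_table <- function(m, ids = sprintf("s%02d", seq_len(nrow(m)))) {
  colnames(m) <- colnames(m) %||% sprintf("v%02d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(subject_id = ids), tibble::as_tibble(m))
}

test_that("variable filter drops outlier and missing-heavy variables with reasons", {
  set.seed(10)
  n <- 40
  x <- matrix(rnorm(n * 4, 0, 1), n, 4)
  x[, 1] <- scale(x[, 1]) * 0.5          # clean
  x[5, 2] <- mean(x[, 2]) + 5 * sd(x[, 2])  # one extreme cell
  x[seq_len(24), 3] <- NA                 # 60% missing
  x[, 4] <- scale(x[, 4]) * 0.5          # clean
  tab <- make_table(x)
  out <- filter_variables(tab)
  rep <- removal_report(out)
  expect_setequal(rep$variable, c("v02", "v03"))
  expect_equal(rep$reason[rep$variable == "v02"], "outlier")
  expect_equal(rep$reason[rep$variable == "v03"], "missingness")
  expect_named(out, c("subject_id", "v01", "v04"))
  expect_error(filter_variables(make_table(matrix(c(rep(0, 19), 50), 20, 1))),
               "all variables removed")
})

test_that("filter agrees with a brute-force oracle on generated cohorts", {
  co <- generate_cohort(tiny_spec(seed = 11))
  x <- as.matrix(co$behavior[, -1])
  # oracle: recompute the removal set from scratch
  expected <- colnames(x)[vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    mean(is.na(v)) >= 0.5 ||
      max(abs(v - mean(v, na.rm = TRUE)) / sd(v, na.rm = TRUE),
          na.rm = TRUE) > 3
  }, logical(1))]
  got <- removal_report(filter_variables(co$behavior))
  expect_setequal(got$variable, expected)
  # planted corruption is always caught
  expect_true(all(colnames(x)[co$truth$dead_vars] %in% got$variable))
  expect_true(all(colnames(x)[co$truth$outlier_cells[, "col"]] %in%
                    got$variable))
})

test_that("z-scoring standardizes observed cells and preserves missingness", {
  tab <- make_table(cbind(a = c(1, 2, 3, 4), b = c(2, NA, 4, 6)))
  z <- zscore_features(tab)
  expect_equal(mean(z$a), 0, tolerance = 1e-10)
  expect_equal(sd(z$a), 1, tolerance = 1e-10)
  expect_true(is.na(z$b[2]))
  expect_equal(mean(z$b, na.rm = TRUE), 0, tolerance = 1e-10)
  expect_equal(sd(z$b, na.rm = TRUE), 1, tolerance = 1e-10)
  # already standardized -> unchanged
  zz <- zscore_features(z)
  expect_equal(as.matrix(zz[, -1]), as.matrix(z[, -1]), tolerance = 1e-10)
  expect_error(zscore_features(make_table(cbind(k = rep(3, 5)))),
               "zero-variance.*k")
})

test_that("deconfounding leaves residuals orthogonal to the design and is idempotent", {
  set.seed(3)
  n <- 80
  conf <- tibble::tibble(c1 = rnorm(n), c2 = rnorm(n))
  y <- cbind(v1 = conf$c1 * 2 + 0.5,             # exactly a confound
             v2 = rnorm(n),
             v3 = 3 * conf$c2 + rnorm(n, 0, 0.5))
  tab <- make_table(y)
  out <- deconfound(tab, conf)
  expect_lt(max(abs(out$v1)), 1e-10)
  for (v in c("v2", "v3")) {
    expect_lt(abs(cor(out[[v]], conf$c1)), 1e-8)
    expect_lt(abs(cor(out[[v]], conf$c2)), 1e-8)
  }
  # confound orthogonal (in sample) to the variable: unchanged up to the mean
  qconf <- tibble::tibble(q = residuals(lm(rnorm(n) ~ y[, 2])))
  out2 <- deconfound(make_table(y[, 2, drop = FALSE]), qconf)
  expect_equal(out2$v2, unname(y[, 2] - mean(y[, 2])), tolerance = 1e-8)
  # idempotence
  twice <- deconfound(out, conf)
  expect_equal(as.matrix(twice[, -1]), as.matrix(out[, -1]), tolerance = 1e-8)
  # missing rows: fit on observed rows only, NA preserved
  y2 <- y; y2[3, 2] <- NA
  outna <- deconfound(make_table(y2), conf)
  expect_true(is.na(outna$v2[3]))
  obs <- !is.na(y2[, 2])
  expect_lt(abs(cor(outna$v2[obs], conf$c1[obs])), 1e-8)
  expect_error(deconfound(tab, tibble::tibble(c1 = conf$c1, c1b = conf$c1)),
               "rank-deficient")
})

test_that("quadratic age structure survives linear age removal", {
  set.seed(4)
  n <- 200
  age <- runif(n, 18, 88)
  v <- -(age - 40)^2 + rnorm(n, 0, 10)
  conf <- tibble::tibble(c1 = rnorm(n))
  out <- deconfound(make_table(cbind(v = v)), conf, extra = age)
  # the linear component is removed exactly ...
  expect_lt(abs(cor(out$v, age)), 1e-8)
  # ... but the quadratic component survives
  expect_gt(abs(cor(out$v, (age - mean(age))^2)), 0.5)
})

test_that("nearest-SPD projection matches the eigenvalue-clipping oracle", {
  set.seed(5)
  # already SPD: fixed point
  a <- crossprod(matrix(rnorm(100), 20, 5)) / 19
  expect_equal(nearest_spd_covariance(a), (a + t(a)) / 2, tolerance = 1e-8)
  # indefinite 2x2
  m <- matrix(c(1, 1.2, 1.2, 1), 2, 2)
  out <- nearest_spd_covariance(m)
  expect_gte(min(eigen(out, symmetric = TRUE)$values), 1e-10 * (1 - 1e-6))
  e <- eigen(m, symmetric = TRUE)
  oracle <- e$vectors %*% (pmax(e$values, 1e-10) * t(e$vectors))
  expect_equal(out, oracle, tolerance = 1e-8)
  # complete-data table: equals the ordinary covariance
  x <- matrix(rnorm(200), 50, 4)
  expect_equal(nearest_spd_covariance(make_table(x)), cov(x),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("pairwise covariance equals the reference implementation", {
  set.seed(6)
  x <- matrix(rnorm(300), 60, 5)
  x[sample(length(x), 30)] <- NA
  expect_equal(pairwise_cov(x), cov(x, use = "pairwise.complete.obs"),
               tolerance = 1e-12)
})

test_that("PCA bases are orthonormal, ordered and reconstruct complete data", {
  set.seed(7)
  x <- matrix(rnorm(240), 40, 6)
  tab <- make_table(x)
  b <- pca_basis(tab, 6, method = "svd")
  expect_equal(crossprod(b$components), diag(6), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(b$explained_variance) <= 1e-10))
  # full-rank reconstruction
  xc <- sweep(x, 2, colMeans(x))
  expect_equal(b$scores %*% t(b$components), xc, tolerance = 1e-8,
               ignore_attr = TRUE)
  # scores centered per component
  expect_lt(max(abs(colMeans(b$scores))), 1e-8)
  # deterministic sign: largest-magnitude element positive
  for (j in 1:6) {
    expect_gt(b$components[which.max(abs(b$components[, j])), j], 0)
  }
  # data on a line: second eigenvalue ~ 0
  line <- outer(rnorm(30), c(1, 2, -1))
  b2 <- pca_basis(make_table(line), 2, method = "covariance",
                  cov_mat = nearest_spd_covariance(cov(line)))
  expect_lt(b2$explained_variance[2] / b2$explained_variance[1], 1e-8)
  expect_error(pca_basis(tab, 1), "n_comp")
  expect_error(pca_basis(tab, 50), "n_comp")
})

test_that("covariance-route PCA handles missing data by zero imputation", {
  set.seed(8)
  x <- matrix(rnorm(500), 100, 5)
  x[sample(length(x), 25)] <- NA
  tab <- zscore_features(make_table(x))
  b <- pca_basis(tab, 3, method = "covariance")
  x0 <- as.matrix(tab[, -1]); x0[is.na(x0)] <- 0
  expect_equal(b$scores, x0 %*% b$components, tolerance = 1e-12,
               ignore_attr = TRUE)
})
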