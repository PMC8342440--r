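# Canonical correlation analysis on PCA score matrices, loading
# reconstruction, the hold-out-variable (age) correlation and its bootstrap
# inference.

#' Fit a canonical correlation analysis
#'
#' Standard CCA between two score matrices, computed by singular value
#' decomposition of the whitened cross-covariance: with `S11`, `S22` the
#' within-domain covariances and `S12` the cross-covariance,
#' `K = S11^{-1/2} S12 S22^{-1/2}` is decomposed and the weight matrices are
#' `a = S11^{-1/2} U`, `b = S22^{-1/2} V`.  Factor pairs are ordered by
#' decreasing canonical correlation; each factor has unit variance.  Signs are
#' fixed deterministically (largest-magnitude weight positive); when `orient`
#' is supplied (e.g. age) the first factor pair is flipped jointly so that its
#' summed scores correlate non-negatively with it.
#'
#' @param e1,e2 Numeric matrices with one row per subject (PCA scores,
#'   typically); each must be full column rank.
#' @param orient Optional numeric hold-out variable used to orient the first
#'   canonical axis.
#' @return A `cca_model`: `weights_a`, `weights_b`, `factors_f1`,
#'   `factors_f2` (subjects x n_factors, unit variance), `canonical_corrs`,
#'   `n_factors = min(ncol(e1), ncol(e2))`.
#' @export
fit_cca <- function(e1, e2, orient = NULL) {
  e1 <- as.matrix(e1); e2 <- as.matrix(e2)
  if (nrow(e1) != nrow(e2)) abort("domains disagree on subject count")
  n <- nrow(e1)
  if (n <= max(ncol(e1), ncol(e2))) {
    abort("need more subjects than components in each domain")
  }
  c1 <- scale(e1, center = TRUE, scale = FALSE)
  c2 <- scale(e2, center = TRUE, scale = FALSE)
  s11 <- crossprod(c1) / (n - 1)
  s22 <- crossprod(c2) / (n - 1)
  s12 <- crossprod(c1, c2) / (n - 1)
  inv_sqrt <- function(s, label) {
    e <- eigen((s + t(s)) / 2, symmetric = TRUE)
    if (min(e$values) < max(e$values) * 1e-12) {
      abort(paste0("rank-deficient basis: ", label))
    }
    e$vectors %*% ((1 / sqrt(e$values)) * t(e$vectors))
  }
  w1 <- inv_sqrt(s11, "first domain")
  w2 <- inv_sqrt(s22, "second domain")
  k <- w1 %*% s12 %*% w2
  q <- min(ncol(e1), ncol(e2))
  sv <- svd(k, nu = q, nv = q)
  rho <- pmin(pmax(sv$d[seq_len(q)], 0), 1)
  a <- w1 %*% sv$u
  b <- w2 %*% sv$v
  # deterministic sign: largest-magnitude weight in `a` positive, with the
  # paired flip applied to `b` so each canonical correlation stays positive
  flips <- sign_convention(a)
  a <- sweep(a, 2, flips, `*`)
  b <- sweep(b, 2, flips, `*`)
  f1 <- c1 %*% a
  f2 <- c2 %*% b
  if (!is.null(orient)) {
    if (cor(f1[, 1] + f2[, 1], orient) < 0) {
      a[, 1] <- -a[, 1]; b[, 1] <- -b[, 1]
      f1[, 1] <- -f1[, 1]; f2[, 1] <- -f2[, 1]
    }
  }
  dimnames(a) <- list(colnames(e1), paste0("CA", seq_len(q)))
  dimnames(b) <- list(colnames(e2), paste0("CA", seq_len(q)))
  colnames(f1) <- colnames(f2) <- paste0("CA", seq_len(q))
  structure(list(weights_a = a, weights_b = b,
                 factors_f1 = f1, factors_f2 = f2,
                 canonical_corrs = rho, n_factors = q,
                 centers_e1 = attr(c1, "scaled:center"),
                 centers_e2 = attr(c2, "scaled:center")),
            class = "cca_model")
}

#' @export
print.cca_model <- function(x, ...) {
  cat("<cca_model>", x$n_factors, "canonical factor pairs; rho_1 =",
      signif(x$canonical_corrs[1], 4), "\n")
  invisible(x)
}

#' Project new score matrices through fitted CCA weights
#'
#' @param model A `cca_model`.
#' @param e1,e2 Score matrices for new subjects (same component spaces used
#'   in training).
#' @return List of factor matrices `f1`, `f2`.
#' @export
project_cca <- function(model, e1, e2) {
  e1 <- sweep(as.matrix(e1), 2, model$centers_e1)
  e2 <- sweep(as.matrix(e2), 2, model$centers_e2)
  list(f1 = e1 %*% model$weights_a, f2 = e2 %*% model$weights_b)
}

#' Canonical loadings of the original variables
#'
#' Loadings are the Pearson correlations between each original (normalized)
#' variable and each canonical factor score, computed over the subjects where
#' the variable is observed.
#'
#' @param data Feature tibble (first column subject id) or numeric matrix.
#' @param factors Factor-score matrix (subjects x n_factors).
#' @return Loadings matrix (variables x n_factors), entries in `[-1, 1]`.
#' @export
compute_loadings <- function(data, factors) {
  x <- if (is.data.frame(data)) table_to_matrix(data) else as.matrix(data)
  f <- as.matrix(factors)
  if (nrow(x) != nrow(f)) abort("data and factors disagree on subject count")
  fsd <- apply(f, 2, sd)
  if (any(!is.finite(fsd) | fsd < 1e-12)) abort("zero-variance factor column")
  cor(x, f, use = "pairwise.complete.obs")
}

#' Correlation of a canonical axis with age
#'
#' Ordinary least squares of age on the two first-axis factor-score columns
#' (plus intercept); the axis--age correlation is the square root of the
#' model R-squared, reported unsigned.
#'
#' @param f1_col,f2_col First-axis factor scores of the two domains.
#' @param age Per-subject ages.
#' @return An `age_axis_fit`: coefficients `w1`, `w2`, intercept `b`, and
#'   `r_age`.
#' @export
age_correlation <- function(f1_col, f2_col, age) {
  n <- length(age)
  if (length(f1_col) != n || length(f2_col) != n) {
    abort("inputs disagree on subject count")
  }
  if (n < 4) abort("need at least 4 subjects")
  if (var(f1_col) < 1e-24 || var(f2_col) < 1e-24) {
    abort("zero-variance regressor")
  }
  if (abs(cor(f1_col, f2_col)) > 1 - 1e-12) abort("collinear regressors")
  fit <- lm(age ~ f1_col + f2_col)
  cf <- stats::coef(fit)
  r2 <- r2_two(f1_col, f2_col, age)
  structure(list(w1 = unname(cf[2]), w2 = unname(cf[3]), b = unname(cf[1]),
                 r_age = sqrt(r2), n = n),
            class = "age_axis_fit")
}

#' @export
print.age_axis_fit <- function(x, ...) {
  cat("<age_axis_fit> r_age =", signif(x$r_age, 4), "( n =", x$n, ")\n")
  invisible(x)
}

# r_age for B resampled versions of (x1, x2) given by an n x B index matrix;
# y stays fixed unless y_idx is provided.
boot_r_age <- function(x1, x2, y, idx, y_idx = NULL) {
  n <- length(y)
  x1r <- matrix(x1[idx], n)
  x2r <- matrix(x2[idx], n)
  yr <- if (is.null(y_idx)) matrix(y, n, ncol(idx)) else matrix(y[y_idx], n)
  cs <- function(m) colSums(m)
  cm1 <- cs(x1r) / n; cm2 <- cs(x2r) / n; cmy <- cs(yr) / n
  v1 <- cs(x1r^2) / n - cm1^2
  v2 <- cs(x2r^2) / n - cm2^2
  vy <- cs(yr^2) / n - cmy^2
  c1y <- cs(x1r * yr) / n - cm1 * cmy
  c2y <- cs(x2r * yr) / n - cm2 * cmy
  c12 <- cs(x1r * x2r) / n - cm1 * cm2
  r1 <- c1y / sqrt(v1 * vy)
  r2 <- c2y / sqrt(v2 * vy)
  r12 <- c12 / sqrt(v1 * v2)
  bad <- !is.finite(r12) | abs(r12) > 1 - 1e-12 | !is.finite(r1) |
    !is.finite(r2)
  r2v <- (r1^2 + r2^2 - 2 * r1 * r2 * r12) / (1 - r12^2)
  r2v[bad] <- NA_real_
  sqrt(pmin(pmax(r2v, 0), 1))
}

#' Bootstrap null test for the age correlation
#'
#' Builds a null distribution by resampling the subject rows of the two
#' factor-score columns with replacement, breaking their pairing with age,
#' and recomputing the axis--age correlation each time.  The one-sided
#' p-value is the fraction of null replicates at or above the observed value.
#' A `"permute"` variant reorders rows without replacement instead.
#'
#' @param f1_col,f2_col First-axis factor scores.
#' @param age Per-subject ages.
#' @param n_boot Number of replicates (>= 100).
#' @param seed Integer seed.
#' @param method `"resample"` (with replacement, the default) or `"permute"`.
#' @return List: `p_value`, `observed`, `null` (replicate values).
#' @export
bootstrap_null_p <- function(f1_col, f2_col, age, n_boot = 10000, seed = 1,
                             method = c("resample", "permute")) {
  method <- match.arg(method)
  if (n_boot < 100) abort("n_boot must be >= 100")
  n <- length(age)
  obs <- age_correlation(f1_col, f2_col, age)$r_age
  null <- with_stream(seed, "null-boot", {
    idx <- if (method == "resample") {
      matrix(sample.int(n, n * n_boot, replace = TRUE), n)
    } else {
      vapply(seq_len(n_boot), function(i) sample.int(n), integer(n))
    }
    boot_r_age(f1_col, f2_col, age, idx)
  })
  null <- null[is.finite(null)]
  list(p_value = mean(null >= obs), observed = obs, null = null)
}

#' Bootstrap standard error of the age correlation
#'
#' Resamples subjects (factor rows and age jointly) with replacement and
#' recomputes the axis--age correlation, returning the resampled mean and
#' standard deviation.
#'
#' @inheritParams bootstrap_null_p
#' @return List: `mean`, `se`, `replicates`.
#' @export
bootstrap_se <- function(f1_col, f2_col, age, n_boot = 10000, seed = 1) {
  if (n_boot < 100) abort("n_boot must be >= 100")
  n <- length(age)
  reps <- with_stream(seed, "se-boot", {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n)
    boot_r_age(f1_col, f2_col, age, idx, y_idx = idx)
  })
  reps <- reps[is.finite(reps)]
  list(mean = mean(reps), se = sd(reps), replicates = reps)
}

#' Permutation null band for a correlation between two score vectors
#'
#' Permutes one vector relative to the other and records the absolute
#' correlation, giving a null band against which an observed canonical
#' correlation can be judged (e.g. the age-deconfounded model's first axis).
#'
#' @param f1_col,f2_col Score vectors.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param probs Quantiles of the null |correlation| to report.
#' @return List: `observed` (absolute correlation), `band` (named quantiles),
#'   `p_value` (fraction of null replicates at or above the observed value).
#' @export
permutation_null_band <- function(f1_col, f2_col, n_perm = 1000, seed = 1,
                                  probs = c(0.025, 0.5, 0.95, 0.975)) {
  obs <- abs(cor(f1_col, f2_col))
  null <- with_stream(seed, "perm-band", {
    vapply(seq_len(n_perm), function(i) {
      abs(cor(f1_col, sample(f2_col)))
    }, numeric(1))
  })
  list(observed = obs, band = quantile(null, probs),
       p_value = mean(null >= obs))
}
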