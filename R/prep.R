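# Variable filtering, z-scoring, nuisance deconfounding, nearest-SPD
# covariance rotation and PCA.  The pipeline order is fixed:
# filter -> z-score -> deconfound -> (behavior only: nearest-SPD) -> PCA.

#' Drop variables with extreme outliers or heavy missingness
#'
#' A variable is removed if any observation lies more than `outlier_sd`
#' standard deviations from that variable's own mean, or if at least
#' `min_presence` of its cells are missing.  The filter drops the whole
#' variable, not the offending cell.
#'
#' @param data Feature tibble; first column is the subject id, remaining
#'   columns numeric with `NA` for missing.
#' @param outlier_sd Outlier threshold in within-variable SD units.
#' @param min_presence Missing-fraction threshold at/above which a variable is
#'   dropped.
#' @return The filtered tibble, with the removal report attached as attribute
#'   `"removals"` (see [removal_report()]).
#' @export
filter_variables <- function(data, outlier_sd = 3, min_presence = 0.5) {
  x <- table_to_matrix(data)
  if (ncol(x) == 0) abort("no variables to filter")
  miss_frac <- colMeans(is.na(x))
  mu <- obs_mean(x)
  sdev <- obs_sd(x)
  zmax <- vapply(seq_len(ncol(x)), function(j) {
    if (!is.finite(sdev[j]) || sdev[j] == 0) return(0)
    max(abs(x[, j] - mu[j]) / sdev[j], na.rm = TRUE)
  }, numeric(1))
  drop_missing <- miss_frac >= min_presence
  drop_outlier <- !drop_missing & zmax > outlier_sd
  dropped <- drop_missing | drop_outlier
  report <- tibble::tibble(
    variable = colnames(x)[dropped],
    reason = unname(ifelse(drop_missing[dropped], "missingness", "outlier")),
    statistic = unname(ifelse(drop_missing[dropped], miss_frac[dropped],
                              zmax[dropped]))
  )
  keep <- !(drop_missing | drop_outlier)
  if (!any(keep)) abort("all variables removed by filtering")
  out <- data[, c(1L, 1L + which(keep))]
  attr(out, "removals") <- report
  out
}

#' Removal report of a filtered feature table
#'
#' @param data A tibble returned by [filter_variables()].
#' @return Tibble with columns `variable`, `reason` ("outlier" or
#'   "missingness") and `statistic` (max |z| or missing fraction).
#' @export
removal_report <- function(data) {
  rep <- attr(data, "removals")
  if (is.null(rep)) {
    tibble::tibble(variable = character(), reason = character(),
                   statistic = numeric())
  } else {
    rep
  }
}

#' Z-score each variable across subjects
#'
#' Per-variable standardization to mean 0 and (sample) SD 1 over the observed
#' cells; missing cells stay missing.
#'
#' @param data Feature tibble (first column subject id).
#' @return Standardized tibble of the same shape.
#' @export
zscore_features <- function(data) {
  x <- table_to_matrix(data)
  sdev <- obs_sd(x)
  bad <- !is.finite(sdev) | sdev == 0
  if (any(bad)) {
    abort(paste0("zero-variance variable(s): ",
                 paste(colnames(x)[bad], collapse = ", ")))
  }
  z <- sweep(sweep(x, 2, obs_mean(x)), 2, sdev, `/`)
  out <- matrix_to_table(z, as.character(data[[1]]), names(data)[1])
  attr(out, "removals") <- attr(data, "removals")
  out
}

# Build the [intercept | confounds | extra] design matrix.
confound_design <- function(confounds, extra = NULL, n = NULL) {
  cmat <- NULL
  if (!is.null(confounds)) {
    cf <- confounds
    if (is.data.frame(cf) && is.character(cf[[1]])) cf <- cf[, -1]
    cmat <- as.matrix(cf)
    storage.mode(cmat) <- "double"
  }
  emat <- NULL
  if (!is.null(extra)) {
    emat <- as.matrix(extra)
    storage.mode(emat) <- "double"
    if (is.null(colnames(emat))) {
      colnames(emat) <- paste0("extra", seq_len(ncol(emat)))
    }
  }
  nr <- if (!is.null(cmat)) nrow(cmat) else if (!is.null(emat)) nrow(emat) else n
  x <- cbind(`(Intercept)` = rep(1, nr), cmat, emat)
  if (anyNA(x)) abort("confound table must not contain missing values")
  if (qr(x)$rank < ncol(x)) abort("rank-deficient confound design")
  x
}

# OLS coefficients of each column of y on design x, computed per missingness
# pattern (rows with missing y are excluded variable by variable).
deconfound_fit <- function(y, x) {
  beta <- matrix(0, ncol(x), ncol(y),
                 dimnames = list(colnames(x), colnames(y)))
  complete <- !anyNA(y)
  full_cols <- if (complete) seq_len(ncol(y)) else which(colSums(is.na(y)) == 0)
  if (length(full_cols) > 0) {
    beta[, full_cols] <- qr.coef(qr(x), y[, full_cols, drop = FALSE])
  }
  part_cols <- setdiff(seq_len(ncol(y)), full_cols)
  for (j in part_cols) {
    obs <- !is.na(y[, j])
    beta[, j] <- qr.coef(qr(x[obs, , drop = FALSE]), y[obs, j])
  }
  beta[!is.finite(beta)] <- 0
  beta
}

#' Regress nuisance variables out of every feature
#'
#' Each variable is replaced by the residuals of an ordinary least-squares
#' regression on an intercept, the confound columns and any `extra` columns
#' (e.g. age, for the age-deconfounded model).  Rows where a variable is
#' missing are excluded from that variable's fit and remain missing in the
#' output.
#'
#' @param data Feature tibble (first column subject id).
#' @param confounds Confound tibble, one row per subject in the same order
#'   (a leading character subject-id column is ignored); no missing values.
#' @param extra Optional extra regressor(s): numeric vector or matrix (e.g.
#'   age).
#' @return Tibble of residuals with the same shape as `data`.
#' @export
deconfound <- function(data, confounds, extra = NULL) {
  y <- table_to_matrix(data)
  x <- confound_design(confounds, extra, n = nrow(y))
  if (nrow(x) != nrow(y)) abort("confounds and data disagree on subject count")
  beta <- deconfound_fit(y, x)
  resid <- y - x %*% beta
  resid[is.na(y)] <- NA_real_
  out <- matrix_to_table(resid, as.character(data[[1]]), names(data)[1])
  attr(out, "removals") <- attr(data, "removals")
  out
}

#' Nearest symmetric positive-definite covariance
#'
#' Computes the pairwise-complete covariance of a feature table (or takes a
#' covariance matrix directly) and projects it to the nearest symmetric
#' positive-definite matrix in the Frobenius sense, by alternating
#' symmetrization and eigenvalue flooring at `eps` until the smallest
#' eigenvalue clears the floor.
#'
#' @param x Feature tibble (first column subject id) or a square covariance
#'   matrix.
#' @param eps Eigenvalue floor (strictly positive).
#' @param max_iter Iteration cap; non-convergence is an error.
#' @return Symmetric positive-definite covariance matrix.
#' @export
nearest_spd_covariance <- function(x, eps = 1e-10, max_iter = 100) {
  if (is.data.frame(x)) {
    m <- table_to_matrix(x)
    if (ncol(m) < 2) abort("need at least two variables")
    cv <- pairwise_cov(m)
  } else {
    cv <- as.matrix(x)
    if (nrow(cv) != ncol(cv)) abort("covariance input must be square")
  }
  cv <- (cv + t(cv)) / 2
  for (it in seq_len(max_iter)) {
    e <- eigen(cv, symmetric = TRUE)
    if (min(e$values) >= eps) return(cv)
    vals <- pmax(e$values, eps)
    cv <- e$vectors %*% (vals * t(e$vectors))
    cv <- (cv + t(cv)) / 2
  }
  e <- eigen(cv, symmetric = TRUE, only.values = TRUE)
  if (min(e$values) >= eps * (1 - 1e-6)) return(cv)
  abort(sprintf(
    "nearest-SPD projection did not converge in %d iterations (min eigenvalue %.3e)",
    max_iter, min(e$values)))
}

#' Principal-component basis of a feature table
#'
#' Two routes, matching how the two data domains are treated: the
#' `"covariance"` method eigendecomposes a (nearest-SPD) covariance matrix
#' and scores subjects by projecting the zero-imputed data onto the
#' eigenvectors -- used for behavior tables that carry missing cells; the
#' `"svd"` method is standard PCA (column-centered SVD) for complete
#' matrices -- used for the network domain.  Components are ordered by
#' decreasing eigenvalue with a deterministic sign convention (the
#' largest-magnitude element of each component is positive).
#'
#' @param data Feature tibble (first column subject id).
#' @param n_comp Number of components, `2 <= n_comp <= min(n_subjects,
#'   n_variables)`.
#' @param method `"covariance"` or `"svd"`.
#' @param cov_mat Optional precomputed covariance (e.g. from
#'   [nearest_spd_covariance()]) for the covariance method.
#' @return A `pca_basis` object: `components` (variables x n_comp,
#'   orthonormal), `scores` (subjects x n_comp, the eigenvector matrix fed to
#'   the CCA), `explained_variance`, `center`, `method`.
#' @export
pca_basis <- function(data, n_comp, method = c("covariance", "svd"),
                      cov_mat = NULL) {
  method <- match.arg(method)
  x <- table_to_matrix(data)
  n <- nrow(x); m <- ncol(x)
  if (n_comp < 2 || n_comp > min(n, m)) {
    abort("n_comp must be between 2 and min(n_subjects, n_variables)")
  }
  if (method == "covariance") {
    if (is.null(cov_mat)) cov_mat <- nearest_spd_covariance(pairwise_cov(x))
    e <- eigen((cov_mat + t(cov_mat)) / 2, symmetric = TRUE)
    comps <- e$vectors[, seq_len(n_comp), drop = FALSE]
    evar <- e$values[seq_len(n_comp)]
    center <- rep(0, m)
    x0 <- x
    x0[is.na(x0)] <- 0
  } else {
    if (anyNA(x)) abort("svd method requires a complete matrix")
    center <- colMeans(x)
    xc <- sweep(x, 2, center)
    sv <- svd(xc, nu = 0, nv = n_comp)
    comps <- sv$v
    evar <- (sv$d^2 / (n - 1))[seq_len(n_comp)]
    x0 <- xc
  }
  flips <- sign_convention(comps)
  comps <- sweep(comps, 2, flips, `*`)
  rownames(comps) <- colnames(x)
  colnames(comps) <- paste0("PC", seq_len(n_comp))
  scores <- x0 %*% comps
  structure(list(components = comps, scores = scores,
                 explained_variance = evar, center = center,
                 method = method, variable_ids = colnames(x)),
            class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  cat("<pca_basis>", nrow(x$components), "variables ->",
      ncol(x$components), "components (", x$method, ")\n")
  invisible(x)
}

#' Project new data onto a fitted PCA basis
#'
#' @param basis A [pca_basis()].
#' @param data Feature tibble with the same variables.
#' @return Score matrix (subjects x components).
#' @export
project_pca <- function(basis, data) {
  x <- table_to_matrix(data)
  if (!identical(colnames(x), basis$variable_ids)) {
    abort("variable mismatch between basis and new data")
  }
  x <- sweep(x, 2, basis$center)
  x[is.na(x)] <- 0
  x %*% basis$components
}

# ---- trainable preprocessing for one data domain ------------------------
# Holds the training-set statistics needed to carry hold-out subjects through
# the identical pipeline: means/SDs for z-scoring, confound regression
# coefficients, and the PCA basis.

prep_model <- function(data, confounds, extra = NULL, n_comp,
                       use_spd = TRUE) {
  y <- table_to_matrix(data)
  mu <- obs_mean(y)
  sdev <- obs_sd(y)
  bad <- !is.finite(sdev) | sdev < 1e-12
  if (any(bad)) {
    abort(paste0("zero-variance variable(s) in training data: ",
                 paste(colnames(y)[bad], collapse = ", ")))
  }
  z <- sweep(sweep(y, 2, mu), 2, sdev, `/`)
  x <- confound_design(confounds, extra, n = nrow(z))
  beta <- deconfound_fit(z, x)
  resid <- z - x %*% beta
  resid[is.na(z)] <- NA_real_
  rtab <- matrix_to_table(resid, rownames(y))
  if (use_spd) {
    cv <- nearest_spd_covariance(rtab)
    basis <- pca_basis(rtab, n_comp, method = "covariance", cov_mat = cv)
  } else {
    basis <- pca_basis(rtab, n_comp, method = "svd")
  }
  structure(list(mu = mu, sdev = sdev, beta = beta, basis = basis,
                 use_spd = use_spd, variable_ids = colnames(y),
                 design_cols = colnames(x)),
            class = "prep_model")
}

# Apply training statistics to new subjects; never recomputes anything from
# the new data.
project_prep <- function(model, data, confounds, extra = NULL) {
  y <- table_to_matrix(data)
  if (!identical(colnames(y), model$variable_ids)) {
    abort("variable mismatch between training and test data")
  }
  z <- sweep(sweep(y, 2, model$mu), 2, model$sdev, `/`)
  x <- confound_design(confounds, extra, n = nrow(z))
  if (!identical(colnames(x), model$design_cols)) {
    abort("confound design mismatch between training and test data")
  }
  resid <- z - x %*% model$beta
  resid[is.na(z)] <- NA_real_
  rtab <- matrix_to_table(resid, rownames(y))
  project_pca(model$basis, rtab)
}
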