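# Repeated k-fold cross-validation of the two-domain CCA (hold-out factors
# and loadings, median-aggregated across repeats) and the PCA-dimension grid
# search that maximizes the hold-out correlation with age.

#' Train the full preprocessing + CCA pipeline on one set of subjects
#'
#' Fits, on the training subjects only: per-domain z-scoring statistics,
#' confound regression coefficients, the (behavior-only) nearest-SPD
#' covariance rotation, the PCA bases, and the CCA on the PCA scores.  The
#' returned object carries everything needed to project held-out subjects
#' without recomputing any statistic from them.
#'
#' @param behavior,network Feature tibbles (first column subject id).
#' @param confounds Optional confound tibble aligned to the same subjects.
#' @param age Optional per-subject ages; used to orient the first canonical
#'   axis and, when `deconfound_age = TRUE`, regressed out of both domains
#'   before PCA (the age-deconfounded model variant).
#' @param n_comp Length-2 integer vector: PCA components for (behavior,
#'   network).
#' @param deconfound_age Logical switch for the age-deconfounded variant.
#' @param use_spd Apply the nearest-SPD covariance route to the behavior
#'   domain (the network domain always uses standard PCA).
#' @return A `cca_pipeline` object.
#' @export
train_cca_pipeline <- function(behavior, network, confounds = NULL,
                               age = NULL, n_comp = c(2, 2),
                               deconfound_age = FALSE, use_spd = TRUE) {
  extra <- NULL
  if (deconfound_age) {
    if (is.null(age)) abort("deconfound_age = TRUE requires age")
    extra <- matrix(age, ncol = 1, dimnames = list(NULL, "age"))
  }
  prep1 <- prep_model(behavior, confounds, extra, n_comp[1], use_spd = use_spd)
  prep2 <- prep_model(network, confounds, extra, n_comp[2], use_spd = FALSE)
  cca <- fit_cca(prep1$basis$scores, prep2$basis$scores, orient = age)
  structure(list(prep_behavior = prep1, prep_network = prep2, cca = cca,
                 n_comp = n_comp, deconfound_age = deconfound_age),
            class = "cca_pipeline")
}

#' Project held-out subjects through a trained pipeline
#'
#' Test data are standardized with the training means/SDs, deconfounded with
#' the training regression coefficients, projected with the training PCA
#' components and finally with the training CCA weights.  No statistic is
#' recomputed on the test subjects.
#'
#' @param trained A `cca_pipeline` from [train_cca_pipeline()].
#' @param behavior,network Feature tibbles for the held-out subjects.
#' @param confounds Their confound rows (if the pipeline used confounds).
#' @param age Their ages (required iff the pipeline deconfounds age).
#' @return List of hold-out factor matrices `f1` (behavior), `f2` (network).
#' @export
holdout_project <- function(trained, behavior, network, confounds = NULL,
                            age = NULL) {
  stopifnot(inherits(trained, "cca_pipeline"))
  extra <- NULL
  if (trained$deconfound_age) {
    if (is.null(age)) abort("pipeline deconfounds age: supply test ages")
    extra <- matrix(age, ncol = 1, dimnames = list(NULL, "age"))
  }
  e1 <- project_prep(trained$prep_behavior, behavior, confounds, extra)
  e2 <- project_prep(trained$prep_network, network, confounds, extra)
  project_cca(trained$cca, e1, e2)
}

# Greedy alignment of assembled hold-out factors to a reference model:
# columns are matched by maximal summed |correlation| across both domains,
# then sign-flipped (jointly for the pair) to positive correlation.
align_factors <- function(f1, f2, ref_f1, ref_f2) {
  q <- ncol(f1)
  c1 <- cor(f1, ref_f1)
  c2 <- cor(f2, ref_f2)
  score <- abs(c1) + abs(c2)
  perm <- integer(q)
  signs <- numeric(q)
  avail <- rep(TRUE, q)
  # reference columns in order; each claims its best remaining hold-out column
  for (k in seq_len(q)) {
    j <- which.max(ifelse(avail, score[, k], -Inf))
    perm[k] <- j
    signs[k] <- if ((c1[j, k] + c2[j, k]) < 0) -1 else 1
    avail[j] <- FALSE
  }
  list(f1 = sweep(f1[, perm, drop = FALSE], 2, signs, `*`),
       f2 = sweep(f2[, perm, drop = FALSE], 2, signs, `*`),
       perm = perm, signs = signs)
}

fold_assignment <- function(n, k) sample(rep(seq_len(k), length.out = n))

#' Repeated k-fold cross-validation of the CCA
#'
#' Per repeat: subjects are freshly partitioned into `k` near-equal folds;
#' for each fold the full pipeline is trained on the remaining subjects and
#' the fold is hold-out-projected, so every subject receives exactly one
#' hold-out factor estimate per repeat.  Hold-out loadings are computed by
#' correlating the (full-data normalized) variables with the assembled
#' hold-out factor matrix.  Factors are aligned (order and sign) to a
#' full-data reference model before accumulation; final estimates are
#' element-wise medians across repeats with the across-repeat SD as standard
#' error.
#'
#' @inheritParams train_cca_pipeline
#' @param age Per-subject ages (used for axis orientation, the hold-out
#'   age correlation, and optionally deconfounding).
#' @param k Number of folds.
#' @param n_repeats Number of repeated random partitions.
#' @param seed Integer seed (fold draws derive from it).
#' @return A `cv_cca` object: median/SE hold-out factors and loadings, the
#'   per-repeat tibble (`repeat`, hold-out `rho1`, `r_age`), per-axis median
#'   hold-out canonical correlations, and the full-data `reference` pipeline.
#' @export
repeated_kfold_cca <- function(behavior, network, age, confounds = NULL,
                               k = 5, n_repeats = 100, n_comp = c(2, 2),
                               deconfound_age = FALSE, use_spd = TRUE,
                               seed = 1) {
  n <- nrow(behavior)
  if (n < 2 * k) abort("need at least 2k subjects")
  if (n_repeats < 1) abort("n_repeats must be >= 1")
  min_fold <- n %/% k
  if (min_fold < max(n_comp)) {
    abort("fold with fewer subjects than requested components")
  }
  ref <- train_cca_pipeline(behavior, network, confounds, age, n_comp,
                            deconfound_age, use_spd)
  q <- ref$cca$n_factors
  # full-data normalized variables, for hold-out loadings
  d1n <- normalized_matrix(ref$prep_behavior, behavior, confounds,
                           if (deconfound_age) age else NULL)
  d2n <- normalized_matrix(ref$prep_network, network, confounds,
                           if (deconfound_age) age else NULL)
  f1_arr <- array(NA_real_, c(n, q, n_repeats))
  f2_arr <- array(NA_real_, c(n, q, n_repeats))
  l1_arr <- array(NA_real_, c(ncol(d1n), q, n_repeats))
  l2_arr <- array(NA_real_, c(ncol(d2n), q, n_repeats))
  rho_rep <- matrix(NA_real_, n_repeats, q)
  r_age_rep <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    fold <- with_stream(seed, paste0("cvfold-", r), fold_assignment(n, k))
    f1h <- matrix(NA_real_, n, q)
    f2h <- matrix(NA_real_, n, q)
    for (fo in seq_len(k)) {
      test <- fold == fo
      trained <- train_cca_pipeline(
        behavior[!test, , drop = FALSE], network[!test, , drop = FALSE],
        subset_rows(confounds, !test), age[!test], n_comp,
        deconfound_age, use_spd)
      proj <- holdout_project(trained, behavior[test, , drop = FALSE],
                              network[test, , drop = FALSE],
                              subset_rows(confounds, test), age[test])
      f1h[test, ] <- proj$f1
      f2h[test, ] <- proj$f2
    }
    al <- align_factors(f1h, f2h, ref$cca$factors_f1, ref$cca$factors_f2)
    f1_arr[, , r] <- al$f1
    f2_arr[, , r] <- al$f2
    l1_arr[, , r] <- cor(d1n, al$f1, use = "pairwise.complete.obs")
    l2_arr[, , r] <- cor(d2n, al$f2, use = "pairwise.complete.obs")
    rho_rep[r, ] <- vapply(seq_len(q), function(j) {
      cor(al$f1[, j], al$f2[, j])
    }, numeric(1))
    r_age_rep[r] <- age_correlation(al$f1[, 1], al$f2[, 1], age)$r_age
  }
  med <- function(arr) apply(arr, c(1, 2), median)
  sdev <- function(arr) {
    if (dim(arr)[3] == 1) array(0, dim(arr)[1:2]) else apply(arr, c(1, 2), sd)
  }
  name_ax <- function(m, rn) {
    dimnames(m) <- list(rn, paste0("CA", seq_len(q))); m
  }
  structure(list(
    factors_f1 = name_ax(med(f1_arr), as.character(behavior[[1]])),
    factors_f2 = name_ax(med(f2_arr), as.character(behavior[[1]])),
    factors_f1_se = name_ax(sdev(f1_arr), as.character(behavior[[1]])),
    factors_f2_se = name_ax(sdev(f2_arr), as.character(behavior[[1]])),
    loadings_l1 = name_ax(med(l1_arr), colnames(d1n)),
    loadings_l2 = name_ax(med(l2_arr), colnames(d2n)),
    loadings_l1_se = name_ax(sdev(l1_arr), colnames(d1n)),
    loadings_l2_se = name_ax(sdev(l2_arr), colnames(d2n)),
    rho = apply(rho_rep, 2, median),
    rho_se = if (n_repeats == 1) rep(0, q) else apply(rho_rep, 2, sd),
    per_repeat = tibble::tibble(rep = seq_len(n_repeats),
                                rho1 = rho_rep[, 1], r_age = r_age_rep),
    r_age = median(r_age_rep),
    r_age_se = if (n_repeats == 1) 0 else sd(r_age_rep),
    k = k, n_repeats = n_repeats, n_comp = n_comp, seed = seed,
    deconfound_age = deconfound_age,
    age = age,
    reference = ref
  ), class = "cv_cca")
}

# Full-data normalized (z-scored + deconfounded) variable matrix from a
# fitted prep model; used for hold-out loadings.
normalized_matrix <- function(model, data, confounds, age = NULL) {
  y <- table_to_matrix(data)
  z <- sweep(sweep(y, 2, model$mu), 2, model$sdev, `/`)
  extra <- if (!is.null(age)) {
    matrix(age, ncol = 1, dimnames = list(NULL, "age"))
  }
  x <- confound_design(confounds, extra, n = nrow(z))
  resid <- z - x %*% model$beta
  resid[is.na(z)] <- NA_real_
  resid
}

subset_rows <- function(x, keep) {
  if (is.null(x)) NULL else x[keep, , drop = FALSE]
}

#' @export
print.cv_cca <- function(x, ...) {
  cat("<cv_cca>", x$n_repeats, "repeats of", x$k, "folds; hold-out rho_1 =",
      signif(x$rho[1], 4), "+/-", signif(x$rho_se[1], 3),
      "; r_age =", signif(x$r_age, 4), "+/-", signif(x$r_age_se, 3), "\n")
  invisible(x)
}

#' Bookkeeping for a PCA-dimension grid search
#'
#' Enumerates the grid of PCA component pairs and the total number of model
#' evaluations implied by the cross-validation design, without fitting
#' anything.
#'
#' @param p_min,p_max Inclusive component range per domain.
#' @param n_repeats Cross-validation repeats per cell.
#' @return List: `n_cells`, `n_models_total` (`n_cells * n_repeats`) and the
#'   `pairs` tibble.
#' @export
grid_plan <- function(p_min = 2, p_max = 100, n_repeats = 15000) {
  if (p_max < p_min) abort("empty grid range")
  vals <- seq.int(p_min, p_max)
  pairs <- tidyr::expand_grid(p_network = vals, p_behavior = vals)
  list(n_cells = nrow(pairs),
       n_models_total = nrow(pairs) * n_repeats,
       pairs = pairs)
}

#' Grid search over PCA component pairs against the age correlation
#'
#' Evaluates the cross-validated first-axis age correlation for every pair of
#' PCA dimensions in the range, and selects the pair maximizing the median
#' hold-out `r_age` (ties broken toward the smallest network then behavior
#' dimension).  Within each repeat/fold the preprocessing and PCA are fitted
#' once at the largest requested dimension and component subsets are sliced
#' from it, which is exact because principal components are nested.
#'
#' @inheritParams repeated_kfold_cca
#' @param p_range Length-2 inclusive range of component numbers applied to
#'   both domains.
#' @return A `grid_result`: `grid` tibble (`p_network`, `p_behavior`,
#'   `r_age_median`, `r_age_se`), `best_pair`, `n_models_total`.
#' @export
grid_search <- function(behavior, network, age, confounds = NULL,
                        p_range = c(2, 10), k = 5, n_repeats = 20,
                        deconfound_age = FALSE, use_spd = TRUE, seed = 1) {
  if (length(p_range) != 2 || p_range[2] < p_range[1]) abort("empty grid range")
  n <- nrow(behavior)
  p_max <- p_range[2]
  if (p_max > min(n - n %/% k - 1,
                  ncol(behavior) - 1, ncol(network) - 1)) {
    abort("p_range exceeds the rank limits of the data")
  }
  vals <- seq.int(p_range[1], p_range[2])
  pairs <- as.matrix(tidyr::expand_grid(p_network = vals, p_behavior = vals))
  r_age_mat <- matrix(NA_real_, nrow(pairs), n_repeats)
  for (r in seq_len(n_repeats)) {
    fold <- with_stream(seed, paste0("gridfold-", r), fold_assignment(n, k))
    # hold-out PCA scores at p_max for every fold, sliced per cell below
    hold1 <- matrix(NA_real_, n, p_max)
    hold2 <- matrix(NA_real_, n, p_max)
    train_scores <- vector("list", k)
    for (fo in seq_len(k)) {
      test <- fold == fo
      extra_tr <- if (deconfound_age) {
        matrix(age[!test], ncol = 1, dimnames = list(NULL, "age"))
      }
      extra_te <- if (deconfound_age) {
        matrix(age[test], ncol = 1, dimnames = list(NULL, "age"))
      }
      pm1 <- prep_model(behavior[!test, , drop = FALSE],
                        subset_rows(confounds, !test), extra_tr, p_max,
                        use_spd = use_spd)
      pm2 <- prep_model(network[!test, , drop = FALSE],
                        subset_rows(confounds, !test), extra_tr, p_max,
                        use_spd = FALSE)
      hold1[test, ] <- project_prep(pm1, behavior[test, , drop = FALSE],
                                    subset_rows(confounds, test), extra_te)
      hold2[test, ] <- project_prep(pm2, network[test, , drop = FALSE],
                                    subset_rows(confounds, test), extra_te)
      train_scores[[fo]] <- list(e1 = pm1$basis$scores, e2 = pm2$basis$scores)
    }
    for (ci in seq_len(nrow(pairs))) {
      p2 <- pairs[ci, "p_network"]; p1 <- pairs[ci, "p_behavior"]
      f1h <- matrix(NA_real_, n, 1)
      f2h <- matrix(NA_real_, n, 1)
      ok <- TRUE
      for (fo in seq_len(k)) {
        test <- fold == fo
        ts <- train_scores[[fo]]
        cc <- tryCatch(
          fit_cca(ts$e1[, seq_len(p1), drop = FALSE],
                  ts$e2[, seq_len(p2), drop = FALSE],
                  orient = age[!test]),
          error = function(e) NULL)
        if (is.null(cc)) { ok <- FALSE; break }
        pr <- project_cca(cc, hold1[test, seq_len(p1), drop = FALSE],
                          hold2[test, seq_len(p2), drop = FALSE])
        f1h[test, 1] <- pr$f1[, 1]
        f2h[test, 1] <- pr$f2[, 1]
      }
      if (ok) {
        r_age_mat[ci, r] <- r2_two(f1h[, 1], f2h[, 1], age)
      }
    }
  }
  r_age_mat <- sqrt(r_age_mat)
  grid <- tibble::tibble(
    p_network = pairs[, "p_network"],
    p_behavior = pairs[, "p_behavior"],
    r_age_median = apply(r_age_mat, 1, median, na.rm = TRUE),
    r_age_se = apply(r_age_mat, 1, sd, na.rm = TRUE)
  )
  ord <- order(-grid$r_age_median, grid$p_network, grid$p_behavior)
  best <- grid[ord[1], ]
  structure(list(grid = grid,
                 best_pair = c(p_behavior = best$p_behavior,
                               p_network = best$p_network),
                 best_r_age = best$r_age_median,
                 n_models_total = nrow(pairs) * n_repeats,
                 n_repeats = n_repeats, k = k, seed = seed),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat("<grid_result>", nrow(x$grid), "cells x", x$n_repeats,
      "repeats =", x$n_models_total, "model evaluations\n",
      "best pair: behavior", x$best_pair[["p_behavior"]], "/ network",
      x$best_pair[["p_network"]], "with median r_age",
      signif(x$best_r_age, 4), "\n")
  invisible(x)
}
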