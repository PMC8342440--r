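# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a quadratic lifespan trend fit
#'
#' @param x A `trend_fit` from [quadratic_trend()].
#' @param ... Unused.
#' @return One-row tibble: `quadratic_term`, `r_squared`, `aicc`,
#'   `n_points`, `constant`.
#' @export
tidy.trend_fit <- function(x, ...) {
  tibble::tibble(quadratic_term = x$quadratic_term, r_squared = x$r_squared,
                 aicc = x$aicc, n_points = x$n_points, constant = x$constant)
}

#' Tidy a fitted CCA
#'
#' @param x A `cca_model`.
#' @param ... Unused.
#' @return Tibble with one row per canonical axis: `axis`, `rho`.
#' @export
tidy.cca_model <- function(x, ...) {
  tibble::tibble(axis = seq_len(x$n_factors), rho = x$canonical_corrs)
}

#' @export
glance.cca_model <- function(x, ...) {
  tibble::tibble(n_factors = x$n_factors, rho1 = x$canonical_corrs[1],
                 n_subjects = nrow(x$factors_f1))
}

#' Tidy a cross-validated CCA
#'
#' @param x A `cv_cca`.
#' @param what `"axes"` (default; per-axis hold-out correlations),
#'   `"factors"` (long per-subject hold-out scores) or `"loadings"` (long
#'   per-variable loadings).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cv_cca <- function(x, what = c("axes", "factors", "loadings"), ...) {
  what <- match.arg(what)
  if (what == "axes") {
    return(tibble::tibble(axis = seq_along(x$rho), rho = x$rho,
                          rho_se = x$rho_se))
  }
  long <- function(m, se, id_name, domain) {
    tibble::as_tibble(m, rownames = id_name) |>
      tidyr::pivot_longer(-dplyr::all_of(id_name), names_to = "axis",
                          values_to = "estimate") |>
      dplyr::mutate(
        se = tibble::as_tibble(se, rownames = id_name) |>
          tidyr::pivot_longer(-dplyr::all_of(id_name)) |>
          dplyr::pull(.data$value),
        domain = domain)
  }
  if (what == "factors") {
    dplyr::bind_rows(
      long(x$factors_f1, x$factors_f1_se, "subject_id", "behavior"),
      long(x$factors_f2, x$factors_f2_se, "subject_id", "network"))
  } else {
    dplyr::bind_rows(
      long(x$loadings_l1, x$loadings_l1_se, "variable", "behavior"),
      long(x$loadings_l2, x$loadings_l2_se, "variable", "network"))
  }
}

#' @export
glance.cv_cca <- function(x, ...) {
  tibble::tibble(rho1 = x$rho[1], rho1_se = x$rho_se[1], r_age = x$r_age,
                 r_age_se = x$r_age_se, k = x$k, n_repeats = x$n_repeats,
                 n_comp_behavior = x$n_comp[1], n_comp_network = x$n_comp[2])
}

#' Tidy a grid-search result
#'
#' @param x A `grid_result`.
#' @param ... Unused.
#' @return The grid tibble (`p_network`, `p_behavior`, `r_age_median`,
#'   `r_age_se`).
#' @export
tidy.grid_result <- function(x, ...) x$grid

#' @export
glance.grid_result <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$grid), n_models_total = x$n_models_total,
                 best_p_behavior = x$best_pair[["p_behavior"]],
                 best_p_network = x$best_pair[["p_network"]],
                 best_r_age = x$best_r_age)
}

#' Tidy a rich-club partition
#'
#' @param x A `richclub_partition`.
#' @param ... Unused.
#' @return The node tibble (`node`, `degree`, `norm_degree`, `core`).
#' @export
tidy.richclub_partition <- function(x, ...) x$nodes

#' Tidy an RSA matrix
#'
#' @param x An `rsa_matrix`.
#' @param ... Unused.
#' @return Long tibble of unique off-diagonal pairs: `var1`, `var2`,
#'   `dissimilarity`, `block` (network-network / behavior-behavior /
#'   behavior-network).
#' @export
tidy.rsa_matrix <- function(x, ...) {
  s <- x$values
  ut <- which(upper.tri(s), arr.ind = TRUE)
  t1 <- x$info$domain_type[ut[, 1]]
  t2 <- x$info$domain_type[ut[, 2]]
  block <- ifelse(t1 == t2, paste0(t1, "-", t2), "behavior-network")
  tibble::tibble(var1 = x$info$variable[ut[, 1]],
                 var2 = x$info$variable[ut[, 2]],
                 dissimilarity = s[ut], block = block)
}

#' Tidy a module-averaged RSA matrix
#'
#' @param x An `rsa_modules`.
#' @param ... Unused.
#' @return Long tibble: `module1`, `module2`, `mean`, `sd`, `n_pairs`.
#' @export
tidy.rsa_modules <- function(x, ...) {
  idx <- which(upper.tri(x$mean, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(module1 = rownames(x$mean)[idx[, 1]],
                 module2 = colnames(x$mean)[idx[, 2]],
                 mean = x$mean[idx], sd = x$sd[idx], n_pairs = x$n_pairs[idx])
}
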