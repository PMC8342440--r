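# ggplot2 views of the main result types.  These render the numeric tables
# the analysis emits; aesthetics stay minimal on purpose.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_tile
#'   geom_col geom_errorbar scale_fill_gradient2 labs theme_minimal
#'   facet_wrap coord_fixed
#' @export
ggplot2::autoplot

#' Plot a quadratic lifespan trend
#'
#' Bin means with the fitted quadratic overlaid.
#'
#' @param object A `trend_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trend_fit <- function(object, ...) {
  pts <- tibble::tibble(age = object$bin_centers, value = object$bin_means)
  grid <- tibble::tibble(age = seq(min(pts$age), max(pts$age),
                                   length.out = 100))
  if (!object$constant) {
    grid$value <- stats::predict(object$fit,
                                 newdata = data.frame(x = grid$age))
  } else {
    grid$value <- mean(pts$value)
  }
  ggplot(pts, aes(x = .data$age, y = .data$value)) +
    geom_line(data = grid, colour = "grey40") +
    geom_point(size = 2) +
    labs(x = "age bin center (years)", y = "bin mean",
         title = sprintf("quadratic term %.3g, R² %.3f",
                         object$quadratic_term, object$r_squared)) +
    theme_minimal()
}

#' Plot the first canonical axis of a cross-validated CCA
#'
#' Hold-out behavior versus network factor scores, one point per subject,
#' colored by age when available.
#'
#' @param object A `cv_cca`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cv_cca <- function(object, ...) {
  d <- tibble::tibble(
    behavior = object$factors_f1[, 1],
    network = object$factors_f2[, 1],
    age = object$age
  )
  ggplot(d, aes(x = .data$network, y = .data$behavior, colour = .data$age)) +
    geom_point(alpha = 0.8) +
    labs(x = "CA1 network factor (hold-out)",
         y = "CA1 behavior factor (hold-out)",
         title = sprintf("hold-out ρ₁ = %.3f, r_age = %.3f",
                         object$rho[1], object$r_age)) +
    theme_minimal()
}

#' Heat map of the PCA-dimension grid search
#'
#' @param object A `grid_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.grid_result <- function(object, ...) {
  ggplot(object$grid, aes(x = .data$p_network, y = .data$p_behavior,
                          fill = .data$r_age_median)) +
    geom_tile() +
    labs(x = "network PCA components", y = "behavior PCA components",
         fill = "median r_age") +
    theme_minimal()
}

#' Tile map of a module-averaged RSA matrix
#'
#' @param object An `rsa_modules`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rsa_modules <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$module1, y = .data$module2, fill = .data$mean)) +
    geom_tile() +
    scale_fill_gradient2(midpoint = stats::median(d$mean)) +
    labs(x = NULL, y = NULL, fill = "dissimilarity") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Columns of per-module positive/negative loading means
#'
#' @param summary_tbl Output of [module_loading_summary()] (optionally with a
#'   `side` column).
#' @return A ggplot.
#' @export
plot_loading_summary <- function(summary_tbl) {
  p <- ggplot(summary_tbl,
              aes(x = .data$module, y = .data$mean_loading,
                  fill = .data$sign)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "mean CA1 loading") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("side" %in% names(summary_tbl)) p <- p + facet_wrap(~side, scales = "free_x")
  p
}
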