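# Connection-density networks from streamline counts, consensus thresholding,
# node degree, graph summaries and quadratic lifespan trends.

#' Container for per-subject streamline-count matrices
#'
#' @param counts List of symmetric nonnegative integer matrices (one per
#'   subject, zero diagonal, consistent node ordering).
#' @param voxel_counts Positive integer vector, voxels per node/parcel.
#' @param node_ids Optional character node labels.
#' @param subject_id Optional character subject labels.
#' @return A `connectome_stack` object.
#' @export
connectome_stack <- function(counts, voxel_counts, node_ids = NULL,
                             subject_id = NULL) {
  stopifnot(is.list(counts), length(counts) >= 1)
  p <- nrow(counts[[1]])
  if (is.null(node_ids)) node_ids <- sprintf("node_%03d", seq_len(p))
  if (is.null(subject_id)) subject_id <- sprintf("sub-%04d", seq_along(counts))
  if (length(voxel_counts) != p) abort("voxel_counts length must equal n_nodes")
  if (any(voxel_counts <= 0)) abort("voxel_counts must be positive")
  for (m in counts) {
    if (nrow(m) != p || ncol(m) != p) abort("inconsistent matrix dimensions")
    if (any(m < 0)) abort("streamline counts must be nonnegative")
    if (!isTRUE(all.equal(m, t(m), tolerance = 0))) {
      abort("streamline-count matrices must be symmetric")
    }
    if (any(diag(m) != 0)) abort("streamline-count matrices must have zero diagonal")
  }
  structure(list(counts = counts, voxel_counts = as.numeric(voxel_counts),
                 node_ids = node_ids, subject_id = subject_id),
            class = "connectome_stack")
}

#' @export
print.connectome_stack <- function(x, ...) {
  cat("<connectome_stack>", length(x$counts), "subjects x",
      length(x$node_ids), "nodes\n")
  invisible(x)
}

#' Streamline connection density
#'
#' Density of the connection between two parcels: twice the number of
#' streamlines terminating in both, divided by the parcels' combined voxel
#' count, `2 * s_ij / (n_i + n_j)`.
#'
#' @param s_ij Streamline count (nonnegative).
#' @param n_i,n_j Voxel counts of the two parcels (positive).
#' @return Numeric density (vectorized over inputs).
#' @export
connection_density <- function(s_ij, n_i, n_j) {
  if (any(n_i <= 0) || any(n_j <= 0)) {
    abort("voxel counts must be positive")
  }
  if (any(s_ij < 0)) abort("streamline counts must be nonnegative")
  (2 * s_ij) / (n_i + n_j)
}

#' Build density networks from a connectome stack
#'
#' Applies [connection_density()] elementwise to every subject's
#' streamline-count matrix.  The result is unthresholded; pass it through
#' [consensus_threshold()] before computing degree.
#'
#' @param stack A [connectome_stack()].
#' @return A `density_networks` object: per-subject density matrices, an
#'   all-`TRUE` edge mask, node and subject labels.
#' @export
build_density_networks <- function(stack) {
  stopifnot(inherits(stack, "connectome_stack"))
  v <- stack$voxel_counts
  denom <- outer(v, v, `+`)
  densities <- lapply(stack$counts, function(m) {
    d <- (2 * m) / denom
    diag(d) <- 0
    d
  })
  p <- length(stack$node_ids)
  structure(list(densities = densities,
                 edge_mask = matrix(TRUE, p, p),
                 node_ids = stack$node_ids,
                 subject_id = stack$subject_id,
                 thresholded = FALSE),
            class = "density_networks")
}

#' @export
print.density_networks <- function(x, ...) {
  cat("<density_networks>", length(x$densities), "subjects x",
      length(x$node_ids), "nodes;",
      if (x$thresholded) "consensus-thresholded" else "unthresholded", "\n")
  invisible(x)
}

# Count, per edge, the subjects in which it is nonzero.
edge_presence <- function(densities) {
  Reduce(`+`, lapply(densities, function(d) (d != 0) * 1))
}

#' Consensus threshold across subjects
#'
#' Keeps an edge only if it is nonzero in a strict majority of subjects
#' (more than `min_prop` of them); all other edges are zeroed in every
#' subject's matrix.
#'
#' @param nets A `density_networks` object.
#' @param min_prop Required presence proportion (default 0.5; edges present in
#'   exactly half the subjects are removed).
#' @return The thresholded `density_networks`, with `edge_mask` updated.
#' @export
consensus_threshold <- function(nets, min_prop = 0.5) {
  stopifnot(inherits(nets, "density_networks"))
  n <- length(nets$densities)
  if (n < 1) abort("need at least one subject")
  presence <- edge_presence(nets$densities)
  mask <- presence > min_prop * n
  diag(mask) <- FALSE
  nets$densities <- lapply(nets$densities, function(d) d * mask)
  nets$edge_mask <- mask
  nets$thresholded <- TRUE
  nets
}

#' Per-subject node degree
#'
#' Binary degree on the surviving edges: for each subject, the number of
#' nonzero connections incident to each node.
#'
#' @param nets A (preferably thresholded) `density_networks` object.
#' @return Tibble with `subject_id` and one integer column per node.
#' @export
node_degree <- function(nets) {
  stopifnot(inherits(nets, "density_networks"))
  deg <- t(vapply(nets$densities, function(d) colSums(d != 0),
                  numeric(length(nets$node_ids))))
  colnames(deg) <- nets$node_ids
  matrix_to_table(deg, nets$subject_id)
}

#' Graph summaries of one network matrix
#'
#' Highest node degree, edge density (fraction of possible undirected edges
#' present) and global efficiency (mean over node pairs of the inverse
#' shortest-path length on the binarized graph; disconnected pairs contribute
#' zero).
#'
#' @param net A symmetric matrix for one subject (weights are binarized).
#' @return One-row tibble: `highest_degree`, `density`, `efficiency`.
#' @export
graph_summaries <- function(net) {
  p <- nrow(net)
  if (is.null(p) || p < 2) abort("graph summaries undefined for < 2 nodes")
  adj <- (net != 0) * 1
  diag(adj) <- 0
  deg <- colSums(adj)
  n_edges <- sum(adj) / 2
  dens <- n_edges / upper_pairs(p)
  if (n_edges == 0) {
    eff <- 0
  } else {
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    d <- igraph::distances(g)
    inv <- 1 / d[upper.tri(d)]
    inv[!is.finite(inv)] <- 0
    eff <- mean(inv)
  }
  tibble::tibble(highest_degree = max(deg), density = dens, efficiency = eff)
}

#' Quadratic lifespan trend of a measure
#'
#' Averages a per-subject measure within equal-width age bins (decades by
#' default) and fits an ordinary least-squares quadratic to the bin means
#' versus bin centers.  Reports the quadratic coefficient, R-squared and the
#' small-sample-corrected Akaike criterion
#' `AICc = n ln(RSS/n) + 2k + 2k(k+1)/(n-k-1)` with `k = 3` parameters and
#' `n` = number of bins.
#'
#' @param values Per-subject measure.
#' @param ages Per-subject ages in years.
#' @param n_bins Number of age bins (must be > 4 for AICc to exist).
#' @param age_start Left edge of the first bin (default: 18 years).
#' @param bin_width Bin width in years (default: a decade).
#' @return A `trend_fit` object; see [tidy.trend_fit()].
#' @export
quadratic_trend <- function(values, ages, n_bins = 7, age_start = 18,
                            bin_width = 10) {
  stopifnot(length(values) == length(ages))
  if (n_bins <= 4) abort("AICc undefined for n_bins <= 4")
  if (length(values) < n_bins) abort("need at least n_bins subjects")
  bin <- pmin(pmax(floor((ages - age_start) / bin_width) + 1, 1), n_bins)
  centers <- age_start + (seq_len(n_bins) - 0.5) * bin_width
  means <- vapply(seq_len(n_bins), function(b) {
    v <- values[bin == b]
    if (length(v) == 0) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(means)
  if (sum(ok) <= 4) abort("too few populated bins for a quadratic AICc fit")
  x <- centers[ok]; y <- means[ok]
  nb <- length(y)
  constant <- sd(y) < 1e-12
  if (constant) {
    fit <- NULL
    quad <- 0; r2 <- 0; aicc <- NA_real_
  } else {
    fit <- lm(y ~ x + I(x^2))
    quad <- unname(stats::coef(fit)[3])
    rss <- sum(stats::residuals(fit)^2)
    tss <- sum((y - mean(y))^2)
    r2 <- 1 - rss / tss
    k <- 3
    aicc <- nb * log(rss / nb) + 2 * k + 2 * k * (k + 1) / (nb - k - 1)
  }
  structure(list(quadratic_term = quad, r_squared = r2, aicc = aicc,
                 n_points = nb, constant = constant,
                 bin_centers = x, bin_means = y, fit = fit),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("<trend_fit> quadratic term", signif(x$quadratic_term, 4),
      " R^2", signif(x$r_squared, 4), " AICc", signif(x$aicc, 5),
      " (", x$n_points, "bins )\n")
  if (x$constant) cat("  note: constant input, fit degenerate\n")
  invisible(x)
}
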