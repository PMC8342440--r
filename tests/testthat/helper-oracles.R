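# Independent brute-force oracles and small fixture builders used across the
# suite.  These deliberately avoid the package's own code paths.

# All-pairs shortest path lengths on a binary adjacency matrix
# (Floyd-Warshall); Inf for disconnected pairs.
bf_shortest_paths <- function(adj) {
  p <- nrow(adj)
  d <- matrix(Inf, p, p)
  d[adj != 0] <- 1
  diag(d) <- 0
  for (k in seq_len(p)) {
    for (i in seq_len(p)) {
      for (j in seq_len(p)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Graph summaries by exhaustive computation.
bf_graph_summaries <- function(adj) {
  adj <- (adj != 0) * 1
  diag(adj) <- 0
  p <- nrow(adj)
  d <- bf_shortest_paths(adj)
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  list(highest_degree = max(colSums(adj)),
       density = sum(adj) / 2 / (p * (p - 1) / 2),
       efficiency = if (sum(adj) == 0) 0 else mean(inv))
}

# Canonical correlations via the generalized-eigenvalue route:
# eigenvalues of S11^-1 S12 S22^-1 S21 are the squared canonical
# correlations.
oracle_canonical_corrs <- function(x, y) {
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  n <- nrow(xc)
  s11 <- crossprod(xc) / (n - 1)
  s22 <- crossprod(yc) / (n - 1)
  s12 <- crossprod(xc, yc) / (n - 1)
  m <- solve(s11, s12) %*% solve(s22, t(s12))
  ev <- sort(Re(eigen(m)$values), decreasing = TRUE)
  sqrt(pmin(pmax(ev[seq_len(min(ncol(x), ncol(y)))], 0), 1))
}

# Random symmetric binary adjacency with zero diagonal.
random_adjacency <- function(p, prob = 0.4) {
  a <- matrix(0, p, p)
  a[upper.tri(a)] <- rbinom(p * (p - 1) / 2, 1, prob)
  a + t(a)
}

# A small, fast cohort for unit tests.
tiny_spec <- function(seed = 42, ...) {
  args <- list(n_subjects = 70, n_behavior_vars = 24, n_nodes = 20,
               missing_rate = 0.02, n_dead_vars = 2, n_outlier_cells = 3,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(cohort_spec, args)
}

# Two small coupled feature tables with one shared latent axis; for CCA and
# cross-validation unit tests where the full generator is overkill.
toy_two_domain <- function(n = 150, m1 = 8, m2 = 10, rho = 0.7,
                           noise = 0.4, seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  z2 <- rho * z + sqrt(1 - rho^2) * rnorm(n)
  d1 <- outer(z, runif(m1, 0.7, 1.3)) + matrix(rnorm(n * m1, 0, noise), n)
  d2 <- outer(z2, runif(m2, 0.7, 1.3)) + matrix(rnorm(n * m2, 0, noise), n)
  colnames(d1) <- sprintf("a_%02d", seq_len(m1))
  colnames(d2) <- sprintf("b_%02d", seq_len(m2))
  ids <- sprintf("s%03d", seq_len(n))
  list(
    behavior = dplyr::bind_cols(tibble::tibble(subject_id = ids),
                                tibble::as_tibble(d1)),
    network = dplyr::bind_cols(tibble::tibble(subject_id = ids),
                               tibble::as_tibble(d2)),
    z = z, z2 = z2
  )
}
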