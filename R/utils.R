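# Internal helpers shared across modules.

#' @importFrom rlang abort warn .data
#' @importFrom stats cor cov lm median quantile rnorm runif rpois rbinom sd var
#' @importFrom utils head tail
NULL

# Derive an independent child seed from a master seed and a stream label, so
# that adding one generator never perturbs the draws of another.  A small
# multiplicative hash keeps everything inside the 32-bit integer range R
# requires of set.seed().
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(as.character(stream))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded from (seed, stream).
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(derive_seed(seed, stream))
  force(expr)
}

# Column means / sds over observed cells only.
obs_mean <- function(x) colMeans(x, na.rm = TRUE)
obs_sd <- function(x) apply(x, 2, sd, na.rm = TRUE)

# Pairwise-complete covariance computed with crossproducts; equivalent to
# stats::cov(x, use = "pairwise.complete.obs") but much faster for wide data.
pairwise_cov <- function(x) {
  x <- as.matrix(x)
  m <- !is.na(x)
  x0 <- x
  x0[!m] <- 0
  storage.mode(m) <- "double"
  n_xy <- crossprod(m)
  s_xy <- crossprod(x0)
  # sum of x over rows where y is also observed (and transpose for y over x)
  sx_y <- crossprod(x0, m)
  if (any(n_xy < 2)) {
    abort("pairwise covariance undefined: some variable pairs share < 2 observations")
  }
  cv <- (s_xy - sx_y * t(sx_y) / n_xy) / (n_xy - 1)
  (cv + t(cv)) / 2
}

# Coefficient of determination of y ~ [1, x1, x2]; returns NA when the
# regressors are degenerate rather than erroring (callers decide).
r2_two <- function(x1, x2, y) {
  v1 <- var(x1); v2 <- var(x2); vy <- var(y)
  if (!is.finite(v1) || !is.finite(v2) || !is.finite(vy) ||
      v1 < 1e-24 || v2 < 1e-24 || vy < 1e-24) {
    return(NA_real_)
  }
  r1 <- cor(x1, y); r2 <- cor(x2, y); r12 <- cor(x1, x2)
  if (abs(r12) > 1 - 1e-12) return(NA_real_)
  r2v <- (r1^2 + r2^2 - 2 * r1 * r2 * r12) / (1 - r12^2)
  min(max(r2v, 0), 1)
}

# Split a numeric feature tibble (first column = subject id) into the id
# vector and the numeric matrix.
table_to_matrix <- function(data, id_col = 1L) {
  stopifnot(is.data.frame(data))
  ids <- data[[id_col]]
  mat <- as.matrix(data[, -id_col, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(ids)
  mat
}

matrix_to_table <- function(mat, ids = rownames(mat), id_name = "subject_id") {
  out <- tibble::as_tibble(mat)
  out <- dplyr::bind_cols(tibble::tibble(!!id_name := ids), out)
  out
}

# Deterministic sign convention: orient each column of `v` so its
# largest-magnitude element is positive.  Returns the +/-1 flips applied.
sign_convention <- function(v) {
  flips <- apply(v, 2, function(col) {
    i <- which.max(abs(col))
    if (col[i] < 0) -1 else 1
  })
  flips
}

upper_pairs <- function(n) n * (n - 1) / 2
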