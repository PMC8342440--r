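# Representational similarity analysis on canonical loadings: the full
# dissimilarity matrix, its module average, the model-difference matrix, the
# chord-plot edge list and per-module loading summaries.

#' Loading dissimilarity matrix
#'
#' Stacks the network and behavior loading matrices (variables x factors) and
#' computes, for every pair of variables, `1 - |corr|` of their loading
#' profiles across all canonical factors.  The absolute value makes the
#' result invariant to flipping a whole variable's profile.  With the default
#' Pearson correlation, flipping the sign of a factor *column* is absorbed up
#' to the profile-centering term (exactly so for zero-mean profiles); the
#' `"cosine"` method (uncentered correlation) is exactly invariant to factor
#' sign indeterminacy.
#'
#' @param loadings_network Network-domain loadings (variables x factors).
#' @param loadings_behavior Behavior-domain loadings (same factor columns).
#' @param node_modules Tibble mapping network variables to modules
#'   (columns `node`/`variable` and `module`).
#' @param behavior_domains Tibble mapping behavior variables to domains
#'   (columns `variable` and `domain`).
#' @param method `"pearson"` (default) or `"cosine"`.
#' @return An `rsa_matrix`: `values` (symmetric, zero diagonal, entries in
#'   [0, 1]), `info` tibble (`variable`, `domain_type`, `module`).
#' @export
loading_dissimilarity <- function(loadings_network, loadings_behavior,
                                  node_modules = NULL,
                                  behavior_domains = NULL,
                                  method = c("pearson", "cosine")) {
  method <- match.arg(method)
  l1 <- as.matrix(loadings_network)
  l2 <- as.matrix(loadings_behavior)
  if (ncol(l1) != ncol(l2)) abort("loading matrices disagree on factor count")
  if (ncol(l1) < 2) abort("need at least two canonical factors")
  stacked <- rbind(l1, l2)
  row_sd <- apply(stacked, 1, sd)
  if (any(row_sd < 1e-14)) {
    abort(paste0("constant loading row(s): ",
                 paste(rownames(stacked)[row_sd < 1e-14], collapse = ", ")))
  }
  cc <- if (method == "pearson") {
    cor(t(stacked))
  } else {
    norms <- sqrt(rowSums(stacked^2))
    if (any(norms < 1e-14)) abort("zero loading row (cosine undefined)")
    tcrossprod(stacked / norms)
  }
  s <- 1 - abs(cc)
  s[s < 0] <- 0
  diag(s) <- 0
  s <- (s + t(s)) / 2
  lookup <- function(map, ids, value_col) {
    if (is.null(map)) return(rep(NA_character_, length(ids)))
    key_col <- intersect(c("variable", "node"), names(map))[1]
    map[[value_col]][match(ids, map[[key_col]])]
  }
  ids1 <- rownames(l1) %||% sprintf("net_%03d", seq_len(nrow(l1)))
  ids2 <- rownames(l2) %||% sprintf("beh_%03d", seq_len(nrow(l2)))
  info <- tibble::tibble(
    variable = c(ids1, ids2),
    domain_type = rep(c("network", "behavior"), c(nrow(l1), nrow(l2))),
    module = c(lookup(node_modules, ids1, "module"),
               lookup(behavior_domains, ids2, "domain"))
  )
  dimnames(s) <- list(info$variable, info$variable)
  structure(list(values = s, info = info), class = "rsa_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rsa_matrix <- function(x, ...) {
  cat("<rsa_matrix>", nrow(x$values), "x", ncol(x$values),
      "loading-dissimilarity matrix (",
      sum(x$info$domain_type == "network"), "network +",
      sum(x$info$domain_type == "behavior"), "behavior variables )\n")
  invisible(x)
}

#' Module-averaged dissimilarity matrix
#'
#' Averages the entries of an RSA matrix within every pair of modules
#' (network modules first, then behavior domains), excluding the diagonal
#' cells of the variable-level matrix so that singleton modules are
#' well-defined.  Returns the mean and SD per module pair.
#'
#' @param rsa An `rsa_matrix` with module labels, or a plain labeled matrix
#'   accompanied by `modules`.
#' @param modules Optional character vector of per-variable module labels
#'   (required when `rsa` is a plain matrix).
#' @param module_order Optional explicit ordering of the module labels.
#' @return An `rsa_modules` object: `mean`, `sd`, `n_pairs` (modules x
#'   modules matrices) and `module_type` (network/behavior per module).
#' @export
module_average <- function(rsa, modules = NULL, module_order = NULL) {
  if (inherits(rsa, "rsa_matrix")) {
    s <- rsa$values
    modules <- rsa$info$module
    mod_type <- rsa$info$domain_type
  } else {
    s <- as.matrix(rsa)
    if (is.null(modules)) abort("module labels required")
    mod_type <- rep(NA_character_, length(modules))
  }
  if (anyNA(modules)) abort("every variable needs a module label")
  if (is.null(module_order)) {
    # network modules first, then behavior domains, in order of appearance
    module_order <- unique(modules[order(match(
      ifelse(is.na(mod_type), "network", mod_type),
      c("network", "behavior")))])
  }
  if (!all(modules %in% module_order)) abort("module label not in ordering")
  nm <- length(module_order)
  mean_m <- matrix(NA_real_, nm, nm, dimnames = list(module_order, module_order))
  sd_m <- mean_m
  n_m <- matrix(0, nm, nm, dimnames = list(module_order, module_order))
  idx <- split(seq_along(modules), factor(modules, levels = module_order))
  if (any(lengths(idx) == 0)) abort("empty module")
  off_diag <- row(s) != col(s)
  for (i in seq_len(nm)) {
    for (j in i:nm) {
      block <- s[idx[[i]], idx[[j]], drop = FALSE]
      keep <- off_diag[idx[[i]], idx[[j]], drop = FALSE]
      vals <- block[keep]
      if (length(vals) == 0) {
        # a singleton module's diagonal cell has no variable pairs; it keeps
        # the zero self-dissimilarity of the variable-level matrix
        vals <- 0
      }
      mean_m[i, j] <- mean_m[j, i] <- mean(vals)
      sd_m[i, j] <- sd_m[j, i] <- if (length(vals) > 1) sd(vals) else 0
      n_m[i, j] <- n_m[j, i] <- length(vals)
    }
  }
  type_per_module <- vapply(module_order, function(m) {
    tt <- unique(mod_type[modules == m])
    tt <- tt[!is.na(tt)]
    if (length(tt) == 1) tt else NA_character_
  }, character(1))
  structure(list(mean = mean_m, sd = sd_m, n_pairs = n_m,
                 module_type = type_per_module),
            class = "rsa_modules")
}

#' @export
print.rsa_modules <- function(x, ...) {
  cat("<rsa_modules>", nrow(x$mean), "x", ncol(x$mean),
      "module-averaged dissimilarity\n")
  invisible(x)
}

#' Difference between two module-averaged RSA matrices
#'
#' Elementwise `S_1 - S_2`.  With `S_1` from the full model and `S_2` from
#' the age-deconfounded model, the cells that change are the module pairs
#' whose loading similarity depends on age: age-coupled pairs are similar in
#' the full model (small `S_1`) and decoupled in the age-removed model (large
#' `S_2`), so the age effect appears as strongly negative difference values.
#'
#' @param s1_modules,s2_modules `rsa_modules` objects with identical module
#'   labels, or plain matrices with identical dimnames.
#' @return Matrix `S_d = S_1 - S_2` (symmetric, entries in [-1, 1]).
#' @export
rsa_difference <- function(s1_modules, s2_modules) {
  m1 <- if (inherits(s1_modules, "rsa_modules")) s1_modules$mean else
    as.matrix(s1_modules)
  m2 <- if (inherits(s2_modules, "rsa_modules")) s2_modules$mean else
    as.matrix(s2_modules)
  if (!identical(dim(m1), dim(m2)) ||
      !identical(dimnames(m1), dimnames(m2))) {
    abort("module label mismatch between the two matrices")
  }
  m1 - m2
}

#' Extract the behavior-to-network block
#'
#' @param modules An `rsa_modules` object (needs module types), or a matrix
#'   plus explicit row/column module names.
#' @param value Which matrix to slice when `modules` is an `rsa_modules`
#'   (`"mean"` by default).
#' @return Matrix with network modules as rows and behavior domains as
#'   columns.
#' @export
btn_block <- function(modules, value = "mean") {
  stopifnot(inherits(modules, "rsa_modules"))
  tp <- modules$module_type
  m <- modules[[value]]
  m[tp == "network", tp == "behavior", drop = FALSE]
}

#' Chord-plot data from a brain-to-behavior block
#'
#' Converts a dissimilarity block back to similarity `r = 1 - S`, min--max
#' normalizes it to [0, 1], eliminates entries at or below the block's 75th
#' percentile (strictly greater survives), transforms survivors by
#' `(r * 1000)^2`, and emits a weighted bipartite edge list plus per-segment
#' totals (the chord wedge sizes).
#'
#' @param block Matrix (network modules x behavior domains) of dissimilarity
#'   values, e.g. [btn_block()] of an `rsa_modules` or of a difference
#'   matrix.
#' @param percentile Elimination percentile (default 75).
#' @param already_similarity Set `TRUE` if `block` already holds similarity
#'   values and the `1 - S` conversion must be skipped.
#' @return List: `edges` tibble (`network_module`, `behavior_domain`,
#'   `weight` with zeroed non-survivors), `wedges` tibble of per-segment
#'   totals, `cutoff` (the percentile value on the normalized scale).
#' @export
chord_data <- function(block, percentile = 75, already_similarity = FALSE) {
  m <- as.matrix(block)
  if (length(m) == 0) abort("empty block")
  r <- if (already_similarity) m else 1 - m
  rng <- range(r)
  if (diff(rng) < 1e-15) abort("constant block: percentile cut undefined")
  rn <- (r - rng[1]) / diff(rng)
  cut <- quantile(as.numeric(rn), percentile / 100, names = FALSE)
  w <- ifelse(rn > cut, (rn * 1000)^2, 0)
  rown <- rownames(m) %||% sprintf("net_mod_%d", seq_len(nrow(m)))
  coln <- colnames(m) %||% sprintf("beh_dom_%d", seq_len(ncol(m)))
  edges <- tibble::tibble(
    network_module = rep(rown, times = ncol(m)),
    behavior_domain = rep(coln, each = nrow(m)),
    similarity = as.numeric(rn),
    weight = as.numeric(w)
  )
  wedges <- dplyr::bind_rows(
    edges |>
      dplyr::group_by(segment = .data$network_module) |>
      dplyr::summarise(total = sum(.data$weight), .groups = "drop") |>
      dplyr::mutate(side = "network"),
    edges |>
      dplyr::group_by(segment = .data$behavior_domain) |>
      dplyr::summarise(total = sum(.data$weight), .groups = "drop") |>
      dplyr::mutate(side = "behavior")
  )
  list(edges = edges, wedges = wedges, cutoff = cut)
}

#' Per-module summary of first-axis loadings
#'
#' Within each module, averages the positive loadings into a positive mean
#' and the negative loadings into a negative mean (the two ends of the
#' canonical axis), attaching the mean cross-validation SE of the
#' contributing variables and a word-cloud scale.  The scale is the mean
#' magnitude by default; the summed magnitude is available via
#' `scale_by = "sum"`.
#'
#' @param loadings_ca1 Per-variable first-axis loadings.
#' @param modules Character vector of module labels, same length.
#' @param ses Optional per-variable cross-validation SEs.
#' @param scale_by `"mean"` (default) or `"sum"`.
#' @return Tibble: `module`, `sign`, `mean_loading`, `mean_se`, `n_vars`,
#'   `scale`, `empty`.
#' @export
module_loading_summary <- function(loadings_ca1, modules, ses = NULL,
                                   scale_by = c("mean", "sum")) {
  scale_by <- match.arg(scale_by)
  stopifnot(length(loadings_ca1) == length(modules))
  if (is.null(ses)) ses <- rep(NA_real_, length(loadings_ca1))
  purrr::map_dfr(unique(modules), function(m) {
    sel <- modules == m
    l <- loadings_ca1[sel]; s <- ses[sel]
    one_side <- function(keep, side) {
      if (!any(keep)) {
        return(tibble::tibble(module = m, sign = side, mean_loading = 0,
                              mean_se = NA_real_, n_vars = 0L,
                              scale = 0, empty = TRUE))
      }
      mload <- mean(l[keep])
      tibble::tibble(
        module = m, sign = side, mean_loading = mload,
        mean_se = mean(s[keep]), n_vars = sum(keep),
        scale = if (scale_by == "mean") abs(mload) else sum(abs(l[keep])),
        empty = FALSE
      )
    }
    dplyr::bind_rows(one_side(l > 0, "positive"), one_side(l < 0, "negative"))
  })
}
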