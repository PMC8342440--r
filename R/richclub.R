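# Group-average network, rich-club core/periphery partition, participation
# coefficients, and the association between first-axis loadings and degree.

#' Group-average density network
#'
#' Elementwise mean of the per-subject density matrices, with a consensus
#' rule applied after averaging: any edge not present (nonzero) in a strict
#' majority of subjects is set to zero.
#'
#' @param nets A `density_networks` object.
#' @return Symmetric mean density matrix.
#' @export
average_network <- function(nets) {
  stopifnot(inherits(nets, "density_networks"))
  n <- length(nets$densities)
  if (n < 1) abort("need at least one subject")
  mean_net <- Reduce(`+`, nets$densities) / n
  presence <- edge_presence(nets$densities)
  mean_net[presence <= 0.5 * n] <- 0
  diag(mean_net) <- 0
  dimnames(mean_net) <- list(nets$node_ids, nets$node_ids)
  mean_net
}

#' Rich-club partition of the group-average network
#'
#' Node degree is computed on the mean network, min--max normalized, and the
#' top `round(fraction * n)` nodes by normalized degree form the rich-club
#' core; the rest are the periphery.  Ties are broken by node index.  The
#' default fraction reproduces a 54-of-376 core.
#'
#' @param mean_net Mean density matrix from [average_network()].
#' @param fraction Proportion of nodes assigned to the core, in (0, 1).
#' @return A `richclub_partition`: `nodes` tibble (`node`, `degree`,
#'   `norm_degree`, `core`), `core_nodes`, `periphery_nodes`, `fraction`.
#' @export
rich_club_partition <- function(mean_net, fraction = 54 / 376) {
  if (fraction <= 0 || fraction >= 1) abort("fraction must be in (0, 1)")
  p <- nrow(mean_net)
  deg <- colSums(mean_net != 0)
  if (max(deg) == min(deg)) {
    abort("constant node degree: rich-club partition undefined")
  }
  norm_deg <- (deg - min(deg)) / (max(deg) - min(deg))
  n_core <- round(fraction * p)
  if (n_core < 1) n_core <- 1
  ord <- order(-norm_deg, seq_len(p))
  core_idx <- sort(ord[seq_len(n_core)])
  node_ids <- colnames(mean_net)
  if (is.null(node_ids)) node_ids <- sprintf("node_%03d", seq_len(p))
  nodes <- tibble::tibble(node = node_ids, degree = as.numeric(deg),
                          norm_degree = norm_deg,
                          core = seq_len(p) %in% core_idx)
  structure(list(nodes = nodes,
                 core_nodes = node_ids[core_idx],
                 periphery_nodes = node_ids[-core_idx],
                 fraction = fraction, mean_net = mean_net),
            class = "richclub_partition")
}

#' @export
print.richclub_partition <- function(x, ...) {
  cat("<richclub_partition>", length(x$core_nodes), "core /",
      length(x$periphery_nodes), "periphery nodes ( fraction",
      signif(x$fraction, 4), ")\n")
  invisible(x)
}

#' Rich-club participation coefficient
#'
#' For each node, the ratio of its connections to nodes of its own group
#' (core or periphery) to its connections to the other group, counting
#' nonzero edges.  Nodes with no cross-group connection get `NA` with a flag
#' rather than an infinity.  A standard normalized alternative
#' (within / total) is available via `method = "fraction"`.
#'
#' @param mean_net Mean density matrix.
#' @param partition A `richclub_partition`.
#' @param method `"ratio"` (within / between, the default) or `"fraction"`
#'   (within / total).
#' @return Tibble: `node`, `core`, `within`, `between`, `participation`,
#'   `undefined`.
#' @export
participation_coefficient <- function(mean_net, partition,
                                      method = c("ratio", "fraction")) {
  method <- match.arg(method)
  stopifnot(inherits(partition, "richclub_partition"))
  core <- partition$nodes$core
  adj <- mean_net != 0
  within <- vapply(seq_len(nrow(adj)), function(i) {
    sum(adj[i, core == core[i]]) - 0  # diagonal already zero
  }, numeric(1))
  between <- vapply(seq_len(nrow(adj)), function(i) {
    sum(adj[i, core != core[i]])
  }, numeric(1))
  pc <- if (method == "ratio") {
    ifelse(between == 0, NA_real_, within / between)
  } else {
    tot <- within + between
    ifelse(tot == 0, NA_real_, within / tot)
  }
  tibble::tibble(node = partition$nodes$node, core = core,
                 within = within, between = between,
                 participation = pc,
                 undefined = !is.finite(pc) | is.na(pc))
}

# Bootstrap p for a Spearman correlation: null built by resampling one margin
# with replacement (breaking the pairing); SE by joint pair resampling.
spearman_boot <- function(x, y, n_boot, seed, stream) {
  obs <- suppressWarnings(cor(x, y, method = "spearman"))
  n <- length(x)
  with_stream(seed, stream, {
    null <- vapply(seq_len(n_boot), function(i) {
      suppressWarnings(cor(x[sample.int(n, n, replace = TRUE)], y,
                           method = "spearman"))
    }, numeric(1))
    reps <- vapply(seq_len(n_boot), function(i) {
      id <- sample.int(n, n, replace = TRUE)
      suppressWarnings(cor(x[id], y[id], method = "spearman"))
    }, numeric(1))
    tibble::tibble(r = obs,
                   se = sd(reps, na.rm = TRUE),
                   p_value = mean(null >= obs, na.rm = TRUE),
                   n = n)
  })
}

#' Association between first-axis loadings and node degree
#'
#' Relates the network-domain first-axis canonical loadings to the rich-club
#' structure: (i) mean loading in core and periphery with a bootstrap p-value
#' for their difference (two-sided, label resampling), and (ii) Spearman rank
#' correlations between loading and degree over all nodes, the core only and
#' the periphery only, each with a bootstrap SE and one-sided p-value.
#'
#' @param loadings_ca1 Per-node first-axis loadings, aligned to the partition
#'   node order.
#' @param partition A `richclub_partition`.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @return List: `group_means` tibble, `diff_p_value`, `spearman` tibble
#'   (scope = all/core/periphery).
#' @export
loading_degree_association <- function(loadings_ca1, partition,
                                       n_boot = 2000, seed = 1) {
  stopifnot(inherits(partition, "richclub_partition"))
  core <- partition$nodes$core
  deg <- partition$nodes$norm_degree
  if (length(loadings_ca1) != length(core)) {
    abort("loadings and partition disagree on node count")
  }
  if (sum(core) < 3 || sum(!core) < 3) abort("group smaller than 3 nodes")
  mean_core <- mean(loadings_ca1[core])
  mean_peri <- mean(loadings_ca1[!core])
  obs_diff <- mean_core - mean_peri
  n <- length(core)
  diff_stats <- with_stream(seed, "rc-diff", {
    null <- vapply(seq_len(n_boot), function(i) {
      lab <- core[sample.int(n, n, replace = TRUE)]
      if (all(lab) || !any(lab)) return(NA_real_)
      mean(loadings_ca1[lab]) - mean(loadings_ca1[!lab])
    }, numeric(1))
    se_core <- sd(vapply(seq_len(n_boot), function(i) {
      mean(sample(loadings_ca1[core], sum(core), replace = TRUE))
    }, numeric(1)))
    se_peri <- sd(vapply(seq_len(n_boot), function(i) {
      mean(sample(loadings_ca1[!core], sum(!core), replace = TRUE))
    }, numeric(1)))
    list(p = mean(abs(null) >= abs(obs_diff), na.rm = TRUE),
         se_core = se_core, se_peri = se_peri)
  })
  sp <- dplyr::bind_rows(
    dplyr::mutate(spearman_boot(loadings_ca1, deg, n_boot, seed, "rc-sp-all"),
                  scope = "all"),
    dplyr::mutate(spearman_boot(loadings_ca1[core], deg[core], n_boot, seed,
                                "rc-sp-core"), scope = "core"),
    dplyr::mutate(spearman_boot(loadings_ca1[!core], deg[!core], n_boot, seed,
                                "rc-sp-peri"), scope = "periphery")
  )
  list(
    group_means = tibble::tibble(
      group = c("core", "periphery"),
      mean_loading = c(mean_core, mean_peri),
      se = c(diff_stats$se_core, diff_stats$se_peri),
      n = c(sum(core), sum(!core))
    ),
    diff_p_value = diff_stats$p,
    spearman = sp[, c("scope", "r", "se", "p_value", "n")]
  )
}
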