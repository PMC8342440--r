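# Synthetic lifespan cohorts: a latent age axis coupling behavior and
# structural connectomes, with confounds, missingness and injected outliers.

#' Specification of a synthetic lifespan cohort
#'
#' Collects every knob of the synthetic-cohort generator in one validated
#' object.  Defaults emulate the study conditions the analysis is designed
#' for: 594 subjects evenly sampled across 18--88 years (decade bins), 334
#' behavior variables in 7 domains with quadratic age trends (about half
#' increasing, half decreasing), 376-node connectomes whose node degree
#' follows an inverted U over age, confounds mildly correlated with age,
#' sparse missingness, and a few injected extreme values to exercise the
#' variable filters.
#'
#' @param n_subjects Number of subjects.
#' @param age_range Two-element numeric, low and high age in years.
#' @param n_age_bins Number of equal-width age bins with balanced counts
#'   (decade bins by default).
#' @param n_behavior_vars Number of behavior variables.
#' @param n_nodes Number of network nodes (brain parcels).
#' @param frac_increasing Proportion of behavior variables with positive
#'   coupling to the latent axis (increasing arm of the lifespan trend).
#' @param latent_peak_age Vertex, in years, of the quadratic latent axis.
#' @param coupling_mean Mean per-variable coupling magnitude; the default
#'   0.6 puts the latent axis near 25% of a variable's variance, the size of
#'   age effect typical of lifespan cognitive scores.
#' @param coupling_sd Dispersion of per-variable coupling magnitudes.
#' @param noise_sd Residual dispersion (SD) of each behavior variable; the
#'   residual distribution is bounded (uniform), emulating range-limited
#'   normalized assessment scores in which extreme outliers are data faults
#'   rather than tail draws.
#' @param missing_rate Proportion of behavior cells missing completely at
#'   random.
#' @param n_dead_vars Number of behavior variables made >50% missing (these
#'   must be caught by the missingness filter).
#' @param n_outlier_cells Number of cells replaced by values far outside
#'   (>3 SD) their column distribution, each placed in a distinct otherwise
#'   clean variable while such variables remain.
#' @param degree_coupling Nonnegative scaling of expected streamline counts by
#'   the latent axis, `(1 + degree_coupling * latent)`; 0 decouples the
#'   connectome from age.
#' @param frac_weak_edges Fraction of group-topology edges given expected
#'   counts low enough to appear in fewer than half of subjects (these must
#'   be removed by consensus thresholding).
#' @param seed Integer seed; all generator randomness derives from it through
#'   per-component streams, so identical seeds give identical cohorts.
#'
#' @return A `cohort_spec` object (a validated list).
#' @export
cohort_spec <- function(n_subjects = 594,
                        age_range = c(18, 88),
                        n_age_bins = 7,
                        n_behavior_vars = 334,
                        n_nodes = 376,
                        frac_increasing = 0.5,
                        latent_peak_age = 40,
                        coupling_mean = 0.6,
                        coupling_sd = 0.15,
                        noise_sd = 1,
                        missing_rate = 0.02,
                        n_dead_vars = 5,
                        n_outlier_cells = 10,
                        degree_coupling = 0.3,
                        frac_weak_edges = 0.1,
                        seed = 1) {
  spec <- list(
    n_subjects = as.integer(n_subjects), age_range = as.numeric(age_range),
    n_age_bins = as.integer(n_age_bins),
    n_behavior_vars = as.integer(n_behavior_vars), n_nodes = as.integer(n_nodes),
    frac_increasing = frac_increasing, latent_peak_age = latent_peak_age,
    coupling_mean = coupling_mean, coupling_sd = coupling_sd,
    noise_sd = noise_sd,
    missing_rate = missing_rate, n_dead_vars = as.integer(n_dead_vars),
    n_outlier_cells = as.integer(n_outlier_cells),
    degree_coupling = degree_coupling, frac_weak_edges = frac_weak_edges,
    seed = as.integer(seed)
  )
  if (spec$n_subjects <= 0) abort("n_subjects must be positive")
  if (length(spec$age_range) != 2 || diff(spec$age_range) <= 0) {
    abort("age_range must be (low, high) with low < high")
  }
  if (spec$frac_increasing < 0 || spec$frac_increasing > 1) {
    abort("frac_increasing must be in [0, 1]")
  }
  if (spec$missing_rate < 0 || spec$missing_rate > 1) {
    abort("missing_rate must be in [0, 1]")
  }
  if (spec$frac_weak_edges < 0 || spec$frac_weak_edges > 1) {
    abort("frac_weak_edges must be in [0, 1]")
  }
  if (spec$n_dead_vars > spec$n_behavior_vars) {
    abort("invalid spec: n_behavior_vars < n_dead_vars")
  }
  if (spec$degree_coupling < 0) abort("degree_coupling must be >= 0")
  structure(spec, class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>", x$n_subjects, "subjects,",
      x$n_behavior_vars, "behavior variables,", x$n_nodes, "nodes; ages",
      x$age_range[1], "-", x$age_range[2], "in", x$n_age_bins, "bins; seed",
      x$seed, "\n")
  invisible(x)
}

# Ages drawn uniformly within each of n_age_bins equal-width bins, with bin
# counts differing by at most one (remainder assigned to the earliest bins).
sample_ages <- function(spec) {
  nb <- spec$n_age_bins
  base <- spec$n_subjects %/% nb
  counts <- rep(base, nb)
  rem <- spec$n_subjects - base * nb
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
  edges <- seq(spec$age_range[1], spec$age_range[2], length.out = nb + 1)
  ages <- unlist(lapply(seq_len(nb), function(b) {
    runif(counts[b], edges[b], edges[b + 1])
  }))
  list(ages = ages, bin = rep(seq_len(nb), counts))
}

latent_axis <- function(ages, peak) {
  raw <- -(ages - peak)^2
  as.numeric(scale(raw))
}

# Continuous confounds are built as r * standardized(age) + sqrt(1-r^2) * noise
# rescaled to realistic units; |r| <= 0.3 so that deconfounding cannot
# silently remove the age-coupled signal of interest.
generate_confounds <- function(ages, seed) {
  n <- length(ages)
  a <- as.numeric(scale(ages))
  with_stream(seed, "confounds", {
    # bounded (uniform) residual mixing: vitals of a screened healthy cohort
    # are range-limited, so confound columns carry no extreme tails
    mk <- function(r, mean, sd) {
      z <- r * a + sqrt(1 - r^2) * runif(n, -sqrt(3), sqrt(3))
      mean + sd * z
    }
    tibble::tibble(
      sex = rbinom(n, 1, 0.5),
      height = mk(-0.15, 170, 9),
      weight = mk(0.10, 74, 13),
      heart_rate = mk(0.20, 68, 9),
      systolic_bp = mk(0.30, 125, 14),
      diastolic_bp = mk(0.25, 78, 9)
    )
  })
}

#' Generate a synthetic lifespan cohort
#'
#' Draws ages balanced across equal-width bins, forms a standardized
#' negative-quadratic latent axis of age (peak at `latent_peak_age`), and
#' builds behavior variables as `beta_j * latent + gamma_j' confounds + noise`
#' with a `frac_increasing` share of positive couplings.  Missing cells are
#' MCAR at `missing_rate`; `n_dead_vars` variables are made >50% missing and
#' `n_outlier_cells` cells are pushed far outside their column distribution,
#' so downstream filters have something to catch.  The `truth` record stores
#' every coupling coefficient so planted signal can be recovered exactly.
#'
#' @param spec A [cohort_spec()].
#' @return A `syn_cohort` list with elements `ages`, `age_bin`, `latent`,
#'   `confounds` (tibble), `behavior` (tibble, first column `subject_id`,
#'   `NA` = missing), `behavior_domains` / `node_modules` label tibbles,
#'   `connectomes` (a [connectome_stack]) and `truth`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  m <- spec$n_behavior_vars
  ab <- with_stream(spec$seed, "ages", sample_ages(spec))
  ages <- ab$ages
  latent <- latent_axis(ages, spec$latent_peak_age)
  confounds <- generate_confounds(ages, spec$seed)
  conf_z <- scale(as.matrix(confounds))

  n_pos <- round(spec$frac_increasing * m)
  signs <- rep(c(1, -1), c(n_pos, m - n_pos))
  beh <- with_stream(spec$seed, "behavior", {
    beta <- signs * pmax(abs(rnorm(m, spec$coupling_mean, spec$coupling_sd)), 0.1)
    gamma <- matrix(rnorm(ncol(conf_z) * m, 0, 0.1), ncol(conf_z), m)
    # residuals are bounded (uniform, matching sd = noise_sd): normalized
    # assessment scores are range-limited, so >3-SD cells occur essentially
    # only where the corruption step injects them
    eps <- matrix(runif(n * m, -sqrt(3), sqrt(3)) * spec$noise_sd, n, m)
    values <- latent %*% t(beta) + conf_z %*% gamma + eps
    list(values = values, beta = beta, gamma = gamma)
  })
  values <- beh$values
  colnames(values) <- sprintf("beh_%03d", seq_len(m))

  # corruption: MCAR missingness, dead variables, extreme cells
  corr <- with_stream(spec$seed, "corruption", {
    miss <- matrix(runif(n * m) < spec$missing_rate, n, m)
    dead <- integer(0)
    if (spec$n_dead_vars > 0) {
      dead <- sort(sample.int(m, spec$n_dead_vars))
      for (j in dead) {
        miss[sample.int(n, ceiling(0.6 * n)), j] <- TRUE
      }
    }
    out_cells <- NULL
    if (spec$n_outlier_cells > 0) {
      clean <- setdiff(seq_len(m), dead)
      # distinct clean columns while they last, then recycle
      cols <- if (spec$n_outlier_cells <= length(clean)) {
        sample(clean, spec$n_outlier_cells)
      } else {
        c(sample(clean), sample(clean, spec$n_outlier_cells - length(clean),
                                replace = TRUE))
      }
      rows <- sample.int(n, spec$n_outlier_cells, replace = TRUE)
      out_cells <- cbind(row = rows, col = cols)
    }
    list(miss = miss, dead = dead, out_cells = out_cells)
  })
  if (!is.null(corr$out_cells)) {
    for (i in seq_len(nrow(corr$out_cells))) {
      r <- corr$out_cells[i, 1]; cidx <- corr$out_cells[i, 2]
      col <- values[, cidx]
      values[r, cidx] <- mean(col) + 6 * sd(col)
      corr$miss[r, cidx] <- FALSE
    }
  }
  values[corr$miss] <- NA_real_

  subject_id <- sprintf("sub-%04d", seq_len(n))
  maps <- generate_label_maps(spec)
  cohort <- structure(list(
    spec = spec,
    subject_id = subject_id,
    ages = ages,
    age_bin = ab$bin,
    latent = latent,
    confounds = dplyr::bind_cols(tibble::tibble(subject_id = subject_id),
                                 confounds),
    behavior = matrix_to_table(values, subject_id),
    behavior_domains = maps$behavior_domains,
    node_modules = maps$node_modules,
    truth = list(
      beta = beh$beta, gamma = beh$gamma,
      latent_fun = function(age) latent_axis(age, spec$latent_peak_age),
      missing_mask = corr$miss, dead_vars = corr$dead,
      outlier_cells = corr$out_cells
    )
  ), class = "syn_cohort")
  cohort$connectomes <- generate_connectomes(cohort, spec)
  cohort
}

#' @export
print.syn_cohort <- function(x, ...) {
  cat("<syn_cohort>", length(x$ages), "subjects,",
      ncol(x$behavior) - 1, "behavior variables,",
      length(x$connectomes$node_ids), "nodes\n")
  invisible(x)
}

#' Generate per-subject streamline-count connectomes
#'
#' A fixed group-level topology (with a designated high-degree core and a ring
#' guaranteeing connectivity) assigns each edge an expected streamline count;
#' per subject the expectation is scaled by `(1 + degree_coupling * latent)`
#' and counts are drawn from a Poisson distribution, giving symmetric
#' nonnegative integer matrices with zero diagonals.  A `frac_weak_edges`
#' subset of edges gets expectations low enough to appear in fewer than half
#' of subjects.  Fixed per-parcel voxel counts are emitted alongside.
#'
#' @param cohort A `syn_cohort` (needs `latent`).
#' @param spec The [cohort_spec()] used to build it.
#' @return A [connectome_stack].
#' @export
generate_connectomes <- function(cohort, spec) {
  if (spec$n_nodes < 2) abort("invalid spec: n_nodes must be >= 2")
  p <- spec$n_nodes
  n <- length(cohort$latent)

  topo <- with_stream(spec$seed, "topology", {
    n_core <- max(2L, round(0.15 * p))
    core <- seq_len(n_core)
    w <- matrix(0, p, p)
    pick <- function(idx_i, idx_j, prob) {
      for (i in idx_i) for (j in idx_j) {
        if (j > i && runif(1) < prob) w[i, j] <<- rgamma2()
      }
    }
    rgamma2 <- function() 0.8 + stats::rgamma(1, shape = 1.5, scale = 2.5)
    pick(core, core, 0.8)
    pick(core, setdiff(seq_len(p), core), 0.25)
    pick(setdiff(seq_len(p), core), setdiff(seq_len(p), core), 0.12)
    # core edges are hub-strength
    w[core, core] <- w[core, core] * 5
    # ring: connectivity + guaranteed nonzero degree everywhere
    for (i in seq_len(p)) {
      j <- if (i == p) 1L else i + 1L
      w[min(i, j), max(i, j)] <- max(w[min(i, j), max(i, j)], 12)
    }
    # a couple of moderate-presence edges per node so degree varies across
    # subjects at every node
    for (i in seq_len(p)) {
      for (j in sample(setdiff(seq_len(p), i), min(3L, p - 1L))) {
        lo <- min(i, j); hi <- max(i, j)
        if (w[lo, hi] == 0) w[lo, hi] <- runif(1, 0.8, 2.5)
      }
    }
    idx <- which(upper.tri(w) & w > 0)
    n_weak <- round(spec$frac_weak_edges * length(idx))
    if (n_weak > 0) {
      weak <- sample(idx, n_weak)
      w[weak] <- 0.5  # Poisson(0.5): present in ~39% of subjects
    }
    voxels <- round(runif(p, 150, 1200))
    list(w = w + t(w), voxels = voxels)
  })

  counts <- with_stream(spec$seed, "streamlines", {
    scale_i <- pmax(1 + spec$degree_coupling * cohort$latent, 0.05)
    ut <- upper.tri(topo$w)
    base <- topo$w[ut]
    lapply(seq_len(n), function(i) {
      m <- matrix(0L, p, p)
      m[ut] <- rpois(length(base), base * scale_i[i])
      m + t(m)
    })
  })

  node_ids <- sprintf("node_%03d", seq_len(p))
  connectome_stack(counts, topo$voxels, node_ids,
                   subject_id = cohort$subject_id)
}

#' Label maps for network modules and behavior domains
#'
#' Partitions nodes into ten modules (seven canonical functional networks
#' plus hippocampus, amygdala and remaining subcortex) and behavior variables
#' into seven domains (attention, memory, language, emotion, motor, social,
#' clinical).  Every item receives exactly one label; cortical nodes are split
#' near-equally across the seven networks.
#'
#' @param spec A [cohort_spec()].
#' @return List of two tibbles: `node_modules` (node, module) and
#'   `behavior_domains` (variable, domain).
#' @export
generate_label_maps <- function(spec) {
  networks <- c("visual", "somatomotor", "dorsal_attention",
                "ventral_attention", "limbic", "frontoparietal",
                "default_mode")
  domains <- c("attention", "memory", "language", "emotion", "motor",
               "social", "clinical")
  p <- spec$n_nodes
  if (p >= 17) {
    sub_labels <- c(rep("hippocampus", 2), rep("amygdala", 2),
                    rep("subcortical", 6))
  } else {
    sub_labels <- head(c("hippocampus", "amygdala", "subcortical"),
                       max(0, p - 7))
  }
  n_cortex <- p - length(sub_labels)
  cortex <- rep(networks, length.out = 0)
  if (n_cortex > 0) {
    base <- n_cortex %/% 7
    counts <- rep(base, 7)
    rem <- n_cortex - base * 7
    if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
    cortex <- rep(networks, counts)
  }
  node_modules <- tibble::tibble(
    node = sprintf("node_%03d", seq_len(p)),
    module = c(cortex, sub_labels)
  )
  m <- spec$n_behavior_vars
  base <- m %/% 7
  counts <- rep(base, 7)
  rem <- m - base * 7
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
  behavior_domains <- tibble::tibble(
    variable = sprintf("beh_%03d", seq_len(m)),
    domain = rep(domains, counts)
  )
  list(node_modules = node_modules, behavior_domains = behavior_domains)
}

#' Cohort with a planted single latent axis at known strengths
#'
#' A calibration generator for parameter-recovery studies.  A latent axis `z`
#' is mixed with standardized age at correlation `r_age_latent`; the network
#' domain carries `z` exactly, while the behavior domain carries an attenuated
#' copy at correlation `rho_cross`.  By construction the population canonical
#' correlation between the domains is `rho_cross` and the multiple correlation
#' of age on the two domain axes is exactly `r_age_latent`, so a
#' cross-validated model should recover both.  Optionally, only the variables
#' of chosen behavior domains / network modules are coupled (the rest are pure
#' noise), which plants a block structure recoverable by representational
#' similarity analysis.
#'
#' @param n_subjects Number of subjects.
#' @param rho_cross Planted cross-domain canonical correlation, in (0, 1].
#' @param r_age_latent Planted correlation between age and the shared axis.
#' @param n_behavior_vars,n_network_vars Variables per domain.
#' @param noise_sd Residual dispersion of each observed variable.
#' @param coupled_behavior_domains,coupled_network_modules Optional character
#'   vectors restricting which label groups carry the axis; `NULL` couples
#'   everything.
#' @param age_range,n_age_bins As in [cohort_spec()].
#' @param seed Integer seed.
#' @return A `planted_cohort` list: `ages`, `latent`, `behavior` and `network`
#'   feature tibbles, label tibbles, `confounds`, and a `truth` record.
#' @export
planted_axis_cohort <- function(n_subjects = 600,
                                rho_cross = 0.6,
                                r_age_latent = 0.65,
                                n_behavior_vars = 30,
                                n_network_vars = 30,
                                noise_sd = 0.3,
                                coupled_behavior_domains = NULL,
                                coupled_network_modules = NULL,
                                age_range = c(18, 88),
                                n_age_bins = 7,
                                seed = 1) {
  stopifnot(rho_cross > 0, rho_cross <= 1,
            r_age_latent >= 0, r_age_latent <= 1)
  spec <- cohort_spec(n_subjects = n_subjects, age_range = age_range,
                      n_age_bins = n_age_bins,
                      n_behavior_vars = n_behavior_vars,
                      n_nodes = n_network_vars, seed = seed)
  ab <- with_stream(seed, "planted-ages", sample_ages(spec))
  ages <- ab$ages
  a_std <- as.numeric(scale(ages))
  n <- n_subjects

  dat <- with_stream(seed, "planted-axes", {
    lam <- r_age_latent
    z <- if (lam >= 1) a_std else lam * a_std + sqrt(1 - lam^2) * rnorm(n)
    z <- as.numeric(scale(z))
    z_net <- z
    z_beh <- rho_cross * z + sqrt(1 - rho_cross^2) * rnorm(n)
    z_beh <- as.numeric(scale(z_beh))
    mk_domain <- function(m, axis, coupled, prefix) {
      b <- runif(m, 0.8, 1.2) * sample(c(-1, 1), m, replace = TRUE)
      b[!coupled] <- 0
      vals <- axis %*% t(b) + matrix(rnorm(n * m, 0, noise_sd), n, m)
      colnames(vals) <- sprintf("%s_%03d", prefix, seq_len(m))
      list(values = vals, b = b)
    }
    maps <- generate_label_maps(spec)
    cb <- if (is.null(coupled_behavior_domains)) {
      rep(TRUE, n_behavior_vars)
    } else maps$behavior_domains$domain %in% coupled_behavior_domains
    cn <- if (is.null(coupled_network_modules)) {
      rep(TRUE, n_network_vars)
    } else maps$node_modules$module %in% coupled_network_modules
    beh <- mk_domain(n_behavior_vars, z_beh, cb, "beh")
    net <- mk_domain(n_network_vars, z_net, cn, "node")
    list(z = z, z_beh = z_beh, beh = beh, net = net,
         coupled_behavior = cb, coupled_network = cn, maps = maps)
  })

  subject_id <- sprintf("sub-%04d", seq_len(n))
  confounds <- generate_confounds(ages, derive_seed(seed, "planted"))
  structure(list(
    subject_id = subject_id,
    ages = ages,
    latent = dat$z,
    behavior = matrix_to_table(dat$beh$values, subject_id),
    network = matrix_to_table(dat$net$values, subject_id),
    behavior_domains = dat$maps$behavior_domains,
    node_modules = dplyr::rename(dat$maps$node_modules, variable = "node"),
    confounds = dplyr::bind_cols(tibble::tibble(subject_id = subject_id),
                                 confounds),
    truth = list(rho_cross = rho_cross, r_age_latent = r_age_latent,
                 beta_behavior = dat$beh$b, beta_network = dat$net$b,
                 coupled_behavior = dat$coupled_behavior,
                 coupled_network = dat$coupled_network,
                 latent_behavior = dat$z_beh)
  ), class = "planted_cohort")
}
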