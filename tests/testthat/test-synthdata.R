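# The synthetic-cohort generator: determinism, planted structure, corruption
# bookkeeping, label partitions and connectome construction.

test_that("cohort generation is seed-deterministic and age-bin balanced", {
  spec <- cohort_spec(n_subjects = 140, n_age_bins = 7, n_behavior_vars = 20,
                      n_nodes = 15, seed = 1)
  co1 <- generate_cohort(spec)
  co2 <- generate_cohort(spec)
  expect_identical(co1$behavior, co2$behavior)
  expect_identical(co1$confounds, co2$confounds)
  expect_identical(co1$connectomes$counts, co2$connectomes$counts)
  # 140 subjects over 7 bins -> exactly 20 per decade bin
  expect_equal(unname(table(co1$age_bin)), rep(20L, 7),
               ignore_attr = TRUE)
  # uneven division: counts differ by at most one
  co3 <- generate_cohort(cohort_spec(n_subjects = 73, n_behavior_vars = 10,
                                     n_nodes = 8, n_dead_vars = 0,
                                     n_outlier_cells = 0, seed = 2))
  expect_lte(diff(range(table(co3$age_bin))), 1)
  expect_true(all(co3$ages >= 18 & co3$ages <= 88))
})

test_that("noiseless cohorts reproduce the planted linear model exactly", {
  spec <- cohort_spec(n_subjects = 60, n_behavior_vars = 12, n_nodes = 8,
                      noise_sd = 0, missing_rate = 0, n_dead_vars = 0,
                      n_outlier_cells = 0, seed = 7)
  co <- generate_cohort(spec)
  conf_z <- scale(as.matrix(co$confounds[, -1]))
  expected <- co$latent %*% t(co$truth$beta) + conf_z %*% co$truth$gamma
  got <- as.matrix(co$behavior[, -1])
  expect_equal(unname(got), unname(expected), tolerance = 1e-12)
  # latent axis: standardized negative quadratic of age
  expect_equal(mean(co$latent), 0, tolerance = 1e-12)
  expect_equal(sd(co$latent), 1, tolerance = 1e-12)
  expect_equal(cor(co$latent, -(co$ages - 40)^2), 1, tolerance = 1e-12)
  # the configured share of increasing variables
  expect_equal(sum(co$truth$beta > 0), round(0.5 * 12))
})

test_that("corruption machinery plants what the filters must catch", {
  spec <- tiny_spec(seed = 11)
  co <- generate_cohort(spec)
  x <- as.matrix(co$behavior[, -1])
  miss_frac <- colMeans(is.na(x))
  expect_length(co$truth$dead_vars, 2)
  expect_true(all(miss_frac[co$truth$dead_vars] > 0.5))
  # injected cells are extreme in their column (z computed on observed cells)
  for (i in seq_len(nrow(co$truth$outlier_cells))) {
    r <- co$truth$outlier_cells[i, 1]
    j <- co$truth$outlier_cells[i, 2]
    z <- abs(x[r, j] - mean(x[, j], na.rm = TRUE)) / sd(x[, j], na.rm = TRUE)
    expect_gt(z, 3)
  }
  expect_error(generate_cohort(cohort_spec(n_behavior_vars = 3,
                                           n_dead_vars = 5)),
               "n_dead_vars")
})

test_that("strongly coupled variables recover the latent axis", {
  spec <- cohort_spec(n_subjects = 200, n_behavior_vars = 12, n_nodes = 8,
                      noise_sd = 0.2, missing_rate = 0, n_dead_vars = 0,
                      n_outlier_cells = 0, seed = 3)
  co <- generate_cohort(spec)
  strong <- order(-abs(co$truth$beta))[1:3]
  for (j in strong) {
    expect_gt(abs(cor(co$behavior[[j + 1]], co$latent)), 0.8)
  }
})

test_that("connectomes are symmetric counts whose coupling tracks the latent axis", {
  spec0 <- tiny_spec(seed = 5, degree_coupling = 0)
  co0 <- generate_cohort(spec0)
  for (m in co0$connectomes$counts[1:4]) {
    expect_identical(m, t(m))
    expect_true(all(diag(m) == 0))
    expect_true(all(m >= 0))
    expect_true(all(m == round(m)))
  }
  # null coupling: mean degree independent of the latent axis
  deg0 <- rowMeans(table_to_matrix(node_degree(consensus_threshold(
    build_density_networks(co0$connectomes)))))
  expect_lt(abs(cor(deg0, co0$latent)), 0.25)

  # delta = 0.5 at n = 300: total streamline count tracks the latent axis
  spec1 <- cohort_spec(n_subjects = 300, n_behavior_vars = 6, n_nodes = 25,
                       degree_coupling = 0.5, n_dead_vars = 0,
                       n_outlier_cells = 0, seed = 6)
  co1 <- generate_cohort(spec1)
  totals <- vapply(co1$connectomes$counts, sum, numeric(1))
  expect_gt(cor(totals, co1$latent), 0.4)

  # a subset of edges is present in fewer than half of subjects
  pres <- Reduce(`+`, lapply(co1$connectomes$counts, function(m) (m != 0) * 1))
  n <- length(co1$connectomes$counts)
  frac <- pres[upper.tri(pres)][pres[upper.tri(pres)] > 0] / n
  expect_gt(sum(frac < 0.5), 0)
  expect_error(
    generate_connectomes(co1, cohort_spec(n_nodes = 1, n_behavior_vars = 5)),
    "n_nodes")
})

test_that("label maps partition nodes into 10 modules and variables into 7 domains", {
  spec <- cohort_spec(n_nodes = 376, n_behavior_vars = 334)
  maps <- generate_label_maps(spec)
  expect_equal(nrow(maps$node_modules), 376)
  expect_equal(dplyr::n_distinct(maps$node_modules$module), 10)
  expect_equal(nrow(maps$behavior_domains), 334)
  expect_equal(dplyr::n_distinct(maps$behavior_domains$domain), 7)
  # partition: every item labeled exactly once
  expect_false(any(duplicated(maps$node_modules$node)))
  expect_false(any(duplicated(maps$behavior_domains$variable)))
  expect_false(anyNA(maps$node_modules$module))
  expect_false(anyNA(maps$behavior_domains$domain))
})

test_that("planted-axis cohorts carry the requested coupling strengths", {
  pc <- planted_axis_cohort(n_subjects = 2000, rho_cross = 0.6,
                            r_age_latent = 0.65, noise_sd = 0.2, seed = 4)
  expect_equal(cor(pc$latent, pc$truth$latent_behavior), 0.6,
               tolerance = 0.06)
  expect_equal(abs(cor(pc$latent, pc$ages)), 0.65, tolerance = 0.05)
  # purely age-driven variant: latent IS standardized age
  pc1 <- planted_axis_cohort(n_subjects = 300, r_age_latent = 1, seed = 5)
  expect_equal(abs(cor(pc1$latent, pc1$ages)), 1, tolerance = 1e-10)
})
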