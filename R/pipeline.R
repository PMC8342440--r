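# End-to-end orchestration: network features -> preprocessing -> (optional
# grid search) -> repeated k-fold CCA -> bootstrap inference -> rich club ->
# RSA, with reproducible on-disk artifacts.

#' Configuration of a pipeline run
#'
#' Exactly one of `spec` (a synthetic-cohort specification) or `input_dir`
#' (a directory in the layout written by [write_cohort()]) must be given.
#'
#' @param spec A [cohort_spec()] for synthetic data.
#' @param input_dir Directory with behavior/confound/age tables, a
#'   `connectomes/` subdirectory and label maps.
#' @param deconfound_age The full-model vs age-deconfounded-model switch.
#' @param k Cross-validation folds.
#' @param n_repeats Cross-validation repeats.
#' @param n_comp Fixed PCA component pair (behavior, network); ignored when
#'   `grid_range` is supplied.
#' @param grid_range Optional inclusive range for a PCA-dimension grid
#'   search; the winning pair is then used for the final model.
#' @param n_boot Bootstrap replicates for inference.
#' @param fraction Rich-club core fraction.
#' @param percentile Chord-plot elimination percentile.
#' @param seed Integer master seed.
#' @param out_dir Optional artifact directory; when given, every table named
#'   by the analysis stages is written there along with a run manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(spec = NULL, input_dir = NULL,
                            deconfound_age = FALSE, k = 5, n_repeats = 100,
                            n_comp = c(10, 10), grid_range = NULL,
                            n_boot = 2000, fraction = 54 / 376,
                            percentile = 75, seed = 1, out_dir = NULL) {
  if (is.null(spec) == is.null(input_dir)) {
    abort("exactly one of `spec` and `input_dir` must be set")
  }
  stopifnot(k >= 2, n_repeats >= 1, n_boot >= 100)
  structure(list(spec = spec, input_dir = input_dir,
                 deconfound_age = deconfound_age, k = k,
                 n_repeats = n_repeats, n_comp = n_comp,
                 grid_range = grid_range, n_boot = n_boot,
                 fraction = fraction, percentile = percentile,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$spec)) {
    cohort <- generate_cohort(config$spec)
    list(behavior = cohort$behavior, confounds = cohort$confounds,
         ages = cohort$ages, connectomes = cohort$connectomes,
         node_modules = cohort$node_modules,
         behavior_domains = cohort$behavior_domains)
  } else {
    dir <- config$input_dir
    behavior <- read_feature_table(file.path(dir, "behavior.tsv"))
    confounds <- read_feature_table(file.path(dir, "confounds.tsv"))
    ages_tab <- readr::read_tsv(file.path(dir, "ages.tsv"),
                                show_col_types = FALSE)
    list(behavior = behavior, confounds = confounds, ages = ages_tab$age,
         connectomes = read_connectomes(file.path(dir, "connectomes")),
         node_modules = read_label_map(file.path(dir, "node_modules.tsv")),
         behavior_domains = read_label_map(file.path(dir,
                                                     "behavior_domains.tsv")))
  }
}

#' Run the full analysis pipeline
#'
#' Executes, in order: density-network construction and consensus
#' thresholding, node degree and graph summaries with quadratic lifespan
#' trends, behavior-variable filtering, the (optionally grid-tuned)
#' repeated k-fold cross-validated CCA, bootstrap inference on the first
#' canonical axis versus age, the rich-club analysis of the group-average
#' network, and the representational similarity analysis on the
#' cross-validated loadings.  Rerunning with an identical configuration and
#' seed reproduces all numeric outputs exactly.
#'
#' @param config A [pipeline_config()].
#' @return A `cca_bundle` with every stage's result; written to
#'   `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t_all <- proc.time()[["elapsed"]]
  timing <- c()
  tick <- function(label, t0) {
    timing[[label]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  }

  t0 <- proc.time()[["elapsed"]]
  inputs <- load_pipeline_inputs(config)
  tick("load", t0)

  # --- network features -------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  nets <- consensus_threshold(build_density_networks(inputs$connectomes))
  degree <- node_degree(nets)
  summaries <- purrr::map_dfr(nets$densities, graph_summaries)
  summaries <- dplyr::bind_cols(
    tibble::tibble(subject_id = nets$subject_id), summaries)
  trend <- function(v) tidy(quadratic_trend(v, inputs$ages))
  graph_trends <- dplyr::bind_rows(
    dplyr::mutate(trend(summaries$highest_degree), measure = "highest_degree"),
    dplyr::mutate(trend(summaries$density), measure = "density"),
    dplyr::mutate(trend(summaries$efficiency), measure = "efficiency")
  )
  tick("netfeatures", t0)

  # --- behavior preparation --------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  behavior <- filter_variables(inputs$behavior)
  removals <- removal_report(behavior)
  behavior_domains <- inputs$behavior_domains[
    inputs$behavior_domains$variable %in% names(behavior)[-1], ]
  beh_mat <- table_to_matrix(behavior)
  behavior_trends <- purrr::map_dfr(seq_len(ncol(beh_mat)), function(j) {
    dplyr::mutate(trend(beh_mat[, j]), variable = colnames(beh_mat)[j])
  })
  tick("prep", t0)

  # --- component selection ---------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  grid <- NULL
  n_comp <- config$n_comp
  if (!is.null(config$grid_range)) {
    grid <- grid_search(behavior, degree, inputs$ages, inputs$confounds,
                        p_range = config$grid_range, k = config$k,
                        n_repeats = max(5, config$n_repeats %/% 10),
                        deconfound_age = config$deconfound_age,
                        seed = derive_seed(config$seed, "grid"))
    n_comp <- c(grid$best_pair[["p_behavior"]], grid$best_pair[["p_network"]])
  }
  tick("tuning", t0)

  # --- cross-validated CCA ---------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  cv <- repeated_kfold_cca(behavior, degree, inputs$ages, inputs$confounds,
                           k = config$k, n_repeats = config$n_repeats,
                           n_comp = n_comp,
                           deconfound_age = config$deconfound_age,
                           seed = derive_seed(config$seed, "cv"))
  tick("cv_cca", t0)

  # --- inference on the first canonical axis ---------------------------
  t0 <- proc.time()[["elapsed"]]
  f1 <- cv$factors_f1[, 1]
  f2 <- cv$factors_f2[, 1]
  null_test <- bootstrap_null_p(f1, f2, inputs$ages, config$n_boot,
                                seed = derive_seed(config$seed, "nullp"))
  se_boot <- bootstrap_se(f1, f2, inputs$ages, config$n_boot,
                          seed = derive_seed(config$seed, "seboot"))
  rho_band <- permutation_null_band(f1, f2, n_perm = min(config$n_boot, 2000),
                                    seed = derive_seed(config$seed, "band"))
  inference <- list(
    r_age = age_correlation(f1, f2, inputs$ages)$r_age,
    r_age_p = null_test$p_value,
    r_age_se = se_boot$se,
    rho1 = cv$rho[1],
    rho1_band = rho_band
  )
  tick("inference", t0)

  # --- rich club --------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  mean_net <- average_network(nets)
  partition <- rich_club_partition(mean_net, config$fraction)
  pc <- participation_coefficient(mean_net, partition)
  rc_assoc <- loading_degree_association(
    cv$loadings_l2[, 1], partition, n_boot = config$n_boot,
    seed = derive_seed(config$seed, "richclub"))
  node_table <- dplyr::left_join(partition$nodes,
                                 pc[, c("node", "participation")],
                                 by = "node")
  node_table$loading_ca1 <- cv$loadings_l2[node_table$node, 1]
  tick("richclub", t0)

  # --- RSA --------------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  rsa <- loading_dissimilarity(cv$loadings_l2, cv$loadings_l1,
                               node_modules = inputs$node_modules,
                               behavior_domains = behavior_domains)
  rsa_mod <- module_average(rsa)
  chord <- chord_data(btn_block(rsa_mod), config$percentile)
  loading_summaries <- dplyr::bind_rows(
    dplyr::mutate(module_loading_summary(
      cv$loadings_l2[, 1],
      inputs$node_modules$module[match(rownames(cv$loadings_l2),
                                       inputs$node_modules$node)],
      cv$loadings_l2_se[, 1]), side = "network"),
    dplyr::mutate(module_loading_summary(
      cv$loadings_l1[, 1],
      behavior_domains$domain[match(rownames(cv$loadings_l1),
                                    behavior_domains$variable)],
      cv$loadings_l1_se[, 1]), side = "behavior")
  )
  tick("rsa", t0)

  timing[["total"]] <- round(proc.time()[["elapsed"]] - t_all, 3)
  bundle <- structure(list(
    config = config, ages = inputs$ages,
    subject_id = as.character(behavior[[1]]),
    degree = degree, edge_mask = nets$edge_mask,
    graph_summaries = summaries, graph_trends = graph_trends,
    behavior_trends = behavior_trends, removals = removals,
    behavior_domains = behavior_domains,
    node_modules = inputs$node_modules,
    grid = grid, n_comp = n_comp, cv = cv, inference = inference,
    mean_net = mean_net, partition = partition,
    participation = pc, richclub_association = rc_assoc,
    node_table = node_table,
    rsa = rsa, rsa_modules = rsa_mod, chord = chord,
    loading_summaries = loading_summaries,
    timing = unlist(timing)
  ), class = "cca_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' @export
print.cca_bundle <- function(x, ...) {
  cat("<cca_bundle>", length(x$ages), "subjects;",
      if (x$config$deconfound_age) "age-deconfounded model" else "full model",
      "\n  components (behavior, network):", x$n_comp[1], ",", x$n_comp[2],
      "\n  hold-out rho_1:", signif(x$inference$rho1, 4),
      " r_age:", signif(x$inference$r_age, 4),
      "( p =", signif(x$inference$r_age_p, 3), ")\n")
  invisible(x)
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) readr::write_tsv(x, file.path(dir, name))
  w(bundle$degree, "node_degree.tsv")
  write_matrix_tsv(bundle$edge_mask * 1, file.path(dir, "edge_mask.tsv"))
  w(bundle$graph_summaries, "graph_summaries.tsv")
  w(bundle$graph_trends, "graph_trends.tsv")
  w(bundle$behavior_trends, "behavior_trends.tsv")
  w(bundle$removals, "variable_removals.tsv")
  if (!is.null(bundle$grid)) w(bundle$grid$grid, "grid_search.tsv")
  write_matrix_tsv(bundle$cv$factors_f1, file.path(dir, "factors_behavior.tsv"))
  write_matrix_tsv(bundle$cv$factors_f2, file.path(dir, "factors_network.tsv"))
  write_matrix_tsv(bundle$cv$loadings_l1, file.path(dir, "loadings_behavior.tsv"))
  write_matrix_tsv(bundle$cv$loadings_l2, file.path(dir, "loadings_network.tsv"))
  w(bundle$cv$per_repeat, "cv_per_repeat.tsv")
  w(bundle$node_table, "richclub_nodes.tsv")
  write_matrix_tsv(bundle$rsa$values, file.path(dir, "rsa_full.tsv"))
  write_matrix_tsv(bundle$rsa_modules$mean, file.path(dir, "rsa_modules.tsv"))
  w(bundle$chord$edges, "chord_edges.tsv")
  w(bundle$loading_summaries, "module_loading_summary.tsv")
  summary_json <- list(
    n_comp = bundle$n_comp,
    rho = bundle$cv$rho, rho_se = bundle$cv$rho_se,
    r_age = bundle$inference$r_age, r_age_se = bundle$inference$r_age_se,
    r_age_p = bundle$inference$r_age_p,
    rho1_null_band = as.list(bundle$inference$rho1_band$band),
    richclub = list(core = length(bundle$partition$core_nodes),
                    periphery = length(bundle$partition$periphery_nodes)),
    timing = as.list(bundle$timing)
  )
  jsonlite::write_json(summary_json, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- list.files(dir, full.names = TRUE)
  manifest <- list(
    seed = bundle$config$seed,
    deconfound_age = bundle$config$deconfound_age,
    k = bundle$config$k, n_repeats = bundle$config$n_repeats,
    n_boot = bundle$config$n_boot,
    package_version = as.character(utils::packageVersion("braincca")),
    r_version = R.version.string,
    timing_seconds = as.list(bundle$timing),
    files = as.list(tools::md5sum(files[basename(files) != "manifest.json"]))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Compare the full and age-deconfounded models
#'
#' Tabulates the first-axis canonical correlation and age correlation (with
#' bootstrap p-values) of the two model bundles, computes the module-level
#' RSA difference `S_d = S_1 - S_2` and its chord data, and flags whether the
#' age-deconfounded model's first canonical correlation falls inside its
#' permutation null band.
#'
#' @param bundle_m1 Full-model `cca_bundle`.
#' @param bundle_m2 Age-deconfounded `cca_bundle` on the same cohort.
#' @return A `model_comparison`: `table` tibble, `s_d` matrix, `chord`,
#'   `m2_rho1_in_null_band`.
#' @export
compare_models <- function(bundle_m1, bundle_m2) {
  stopifnot(inherits(bundle_m1, "cca_bundle"),
            inherits(bundle_m2, "cca_bundle"))
  if (!identical(bundle_m1$subject_id, bundle_m2$subject_id)) {
    abort("cohort mismatch between bundles")
  }
  tab <- tibble::tibble(
    model = c("M1", "M2"),
    deconfound_age = c(bundle_m1$config$deconfound_age,
                       bundle_m2$config$deconfound_age),
    rho1 = c(bundle_m1$inference$rho1, bundle_m2$inference$rho1),
    r_age = c(bundle_m1$inference$r_age, bundle_m2$inference$r_age),
    r_age_p = c(bundle_m1$inference$r_age_p, bundle_m2$inference$r_age_p)
  )
  s_d <- rsa_difference(bundle_m1$rsa_modules, bundle_m2$rsa_modules)
  tp <- bundle_m1$rsa_modules$module_type
  btn_d <- s_d[tp == "network", tp == "behavior", drop = FALSE]
  # a constant difference block (e.g. identical models) has no percentile cut
  chord <- tryCatch(chord_data(btn_d, bundle_m1$config$percentile),
                    error = function(e) NULL)
  band <- bundle_m2$inference$rho1_band
  structure(list(
    table = tab, s_d = s_d, btn_difference = btn_d, chord = chord,
    m2_rho1_in_null_band = abs(bundle_m2$inference$rho1) <=
      band$band[["95%"]]
  ), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  print(x$table)
  cat("age-deconfounded rho_1 inside permutation null band:",
      x$m2_rho1_in_null_band, "\n")
  invisible(x)
}
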