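# Loading-dissimilarity RSA: the full matrix, module averages, model
# differences, chord data and module loading summaries.

test_that("loading dissimilarity is 1 - |corr| with the documented limits", {
  base <- c(0.5, -0.2, 0.8, 0.1)
  l_net <- rbind(a = base, b = -base)          # identical and anticorrelated
  ortho <- residuals(lm(rnorm(4) ~ base))      # exactly uncorrelated profile
  l_beh <- rbind(c = base * 2 + 0.1, d = ortho)
  rsa <- loading_dissimilarity(l_net, l_beh)
  s <- rsa$values
  expect_equal(s["a", "b"], 0, tolerance = 1e-12)   # anticorrelated: 0
  expect_equal(s["a", "c"], 0, tolerance = 1e-12)   # linear transform: 0
  expect_equal(s["a", "d"], 1, tolerance = 1e-10)   # orthogonal: 1
  expect_true(all(diag(s) == 0))
  expect_identical(s, t(s))
  expect_true(all(s >= 0 & s <= 1))
  # |corr| absorbs flipping a whole variable profile exactly
  rsa_row <- loading_dissimilarity(rbind(a = -base, b = base), l_beh)
  expect_equal(rsa_row$values, s, tolerance = 1e-12)
  # factor-column sign flips: exactly absorbed by the cosine method
  flip <- diag(c(1, -1, -1, 1))
  cos1 <- loading_dissimilarity(l_net, l_beh, method = "cosine")
  cos2 <- loading_dissimilarity(l_net %*% flip, l_beh %*% flip,
                                method = "cosine")
  expect_equal(cos2$values, cos1$values, tolerance = 1e-12)
  # ... and by Pearson up to the centering term only (small here)
  rsa2 <- loading_dissimilarity(l_net %*% flip, l_beh %*% flip)
  expect_equal(rsa2$values, s, tolerance = 0.02)
  expect_error(loading_dissimilarity(rbind(a = rep(0.3, 4)), l_beh),
               "constant.*a")
  expect_error(loading_dissimilarity(l_net[, 1, drop = FALSE],
                                     l_beh[, 1, drop = FALSE]), "two")
})

test_that("module averaging reduces dimensions and respects identities", {
  set.seed(1)
  q <- 5
  l_net <- matrix(rnorm(6 * q), 6, dimnames = list(sprintf("n%d", 1:6), NULL))
  l_beh <- matrix(rnorm(4 * q), 4, dimnames = list(sprintf("v%d", 1:4), NULL))
  nm <- tibble::tibble(node = sprintf("n%d", 1:6),
                       module = rep(c("m1", "m2"), each = 3))
  bd <- tibble::tibble(variable = sprintf("v%d", 1:4),
                       domain = rep(c("d1", "d2"), each = 2))
  rsa <- loading_dissimilarity(l_net, l_beh, nm, bd)
  mod <- module_average(rsa)
  expect_equal(dim(mod$mean), c(4, 4))
  expect_equal(rownames(mod$mean), c("m1", "m2", "d1", "d2"))
  # constant off-diagonal matrix: every module mean equals the constant
  s_const <- matrix(0.4, 10, 10); diag(s_const) <- 0
  rsa_c <- rsa; rsa_c$values <- s_const
  mod_c <- module_average(rsa_c)
  expect_true(all(abs(mod_c$mean - 0.4) < 1e-12))
  # singleton modules reproduce the original matrix
  rsa_s <- rsa
  rsa_s$info$module <- rsa$info$variable
  mod_s <- module_average(rsa_s)
  off <- row(rsa$values) != col(rsa$values)
  expect_equal(mod_s$mean[rsa$info$variable, rsa$info$variable][off],
               rsa$values[off], tolerance = 1e-12, ignore_attr = TRUE)
  # dimension bookkeeping: 376 + 334 variables -> 710 matrix -> 17 modules
  expect_equal(upper_pairs(710), 251695)
  expect_equal(upper_pairs(17), 136)
})

test_that("RSA difference is an elementwise, antisymmetric subtraction", {
  m1 <- matrix(runif(16), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  m1 <- (m1 + t(m1)) / 2
  m2 <- m1 * 0.5
  expect_equal(rsa_difference(m1, m1), m1 * 0)
  d <- rsa_difference(m1, m2)
  expect_equal(d, m1 - m2)
  expect_equal(rsa_difference(m2, m1), -d)
  m3 <- m2; dimnames(m3) <- list(LETTERS[1:4], LETTERS[1:4])
  expect_error(rsa_difference(m1, m3), "mismatch")
})

test_that("chord data applies the strict percentile cut and square transform", {
  block <- matrix(1 - c(0.1, 0.2, 0.3, 0.4), 2, 2,
                  dimnames = list(c("m1", "m2"), c("d1", "d2")))
  # similarities normalize to {0, 1/3, 2/3, 1}; the 75th percentile is 0.75,
  # so exactly one cell survives the strict cut
  ch <- chord_data(block, percentile = 75)
  expect_equal(sum(ch$edges$weight > 0), 1)
  expect_equal(max(ch$edges$weight), 1000^2)
  # survivors are monotone in the underlying similarity
  set.seed(2)
  b2 <- matrix(runif(12), 3, 4)
  ch2 <- chord_data(b2, percentile = 50)
  kept <- ch2$edges[ch2$edges$weight > 0, ]
  expect_equal(order(kept$similarity), order(kept$weight))
  # the unique maximum always survives
  b3 <- matrix(0.3, 2, 3); b3[1, 1] <- 0.9
  ch3 <- chord_data(b3, already_similarity = TRUE)
  expect_equal(sum(ch3$edges$weight > 0), 1)
  expect_equal(ch3$edges$network_module[ch3$edges$weight > 0], "net_mod_1")
  # wedge totals sum the surviving weights per segment
  expect_equal(sum(ch2$wedges$total[ch2$wedges$side == "network"]),
               sum(ch2$edges$weight))
  expect_error(chord_data(matrix(0.5, 2, 2)), "constant")
})

test_that("module loading summaries split positive and negative ends", {
  l <- c(0.2, 0.4, -0.1, 0.3, -0.5)
  mods <- c("A", "A", "A", "B", "B")
  ses <- c(0.01, 0.03, 0.02, 0.05, 0.07)
  s <- module_loading_summary(l, mods, ses)
  a_pos <- s[s$module == "A" & s$sign == "positive", ]
  expect_equal(a_pos$mean_loading, 0.3)
  expect_equal(a_pos$mean_se, 0.02)
  a_neg <- s[s$module == "A" & s$sign == "negative", ]
  expect_equal(a_neg$mean_loading, -0.1)
  # all-negative module: positive side flagged empty
  s2 <- module_loading_summary(c(-0.2, -0.4), c("C", "C"))
  expect_true(s2$empty[s2$sign == "positive"])
  expect_equal(s2$mean_loading[s2$sign == "positive"], 0)
  # scale ordering matches mean-magnitude ordering across modules
  pos <- s[s$sign == "positive", ]
  expect_equal(order(pos$scale), order(abs(pos$mean_loading)))
  # sum-based scale available
  s3 <- module_loading_summary(l, mods, scale_by = "sum")
  expect_equal(s3$scale[s3$module == "A" & s3$sign == "positive"], 0.6)
})

test_that("planted cross-domain structure lands in the most similar btn cells", {
  pc <- planted_axis_cohort(
    n_subjects = 260, rho_cross = 0.8, r_age_latent = 0.9,
    n_behavior_vars = 35, n_network_vars = 40,
    coupled_behavior_domains = c("memory", "language"),
    coupled_network_modules = c("visual", "limbic"), seed = 31)
  cv <- repeated_kfold_cca(pc$behavior, pc$network, pc$ages, k = 5,
                           n_repeats = 4, n_comp = c(3, 3), seed = 32)
  rsa <- loading_dissimilarity(
    cv$loadings_l2, cv$loadings_l1,
    node_modules = dplyr::rename(pc$node_modules, node = "variable"),
    behavior_domains = pc$behavior_domains)
  mod <- module_average(rsa)
  btn <- btn_block(mod)
  coupled <- as.matrix(expand.grid(c("visual", "limbic"),
                                   c("memory", "language")))
  cvals <- btn[coupled]
  # the four coupled module pairs occupy the lowest (most similar) quartile
  expect_true(all(cvals <= quantile(as.numeric(btn), 0.25) + 1e-12))
})
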