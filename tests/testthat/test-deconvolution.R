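test_that("discriminating-probe selection recovers planted markers and matches brute force", {
  panel <- generate_reference_panel(300, 10, seed = 6)
  markers <- rownames(panel$means)[grepl("^cpgM", rownames(panel$means))]
  sel <- select_discriminating_probes(panel, k = 60)
  expect_setequal(sel, markers)

  # brute-force between-type dispersion ranking
  score <- apply(panel$means, 1, var)
  top <- names(sort(score, decreasing = TRUE))[1:60]
  expect_setequal(sel, top)

  expect_setequal(select_discriminating_probes(panel, k = 300),
                  rownames(panel$means))
  expect_error(select_discriminating_probes(panel, k = 5), "at least 6")
})

test_that("constrained projection recovers noiseless mixtures to 1e-6", {
  panel <- generate_reference_panel(300, 10, seed = 6)
  R <- panel$means
  w_true <- c(CD8T = 0, CD4T = 0.4, NK = 0, Bcell = 0, Mono = 0, Gran = 0.6)
  v <- cbind(mix = R %*% w_true, pure = R[, "NK"])
  colnames(v) <- c("mix", "pure")
  b <- beta_matrix(v)
  props <- estimate_proportions(b, panel)
  got_mix <- unlist(props[props$sample_id == "mix", citewas:::CELL_TYPES])
  expect_lt(max(abs(got_mix - w_true)), 1e-6)
  got_pure <- unlist(props[props$sample_id == "pure", citewas:::CELL_TYPES])
  expect_lt(max(abs(got_pure - c(0, 0, 1, 0, 0, 0))), 1e-6)
  expect_true(all(props$fit_residual < 1e-6))
})

test_that("projection is equivariant to sample and probe permutations", {
  set.seed(14)
  panel <- generate_reference_panel(200, 8, seed = 9)
  cfg <- simulation_config(n_cases = 15, n_controls = 15, n_probes = 200,
                           n_snps = 20, n_mediated = 0, n_consequential = 0,
                           n_independent = 0, batch_location = c(0, 0),
                           batch_scale = c(1, 1), plate_location = c(0, 0),
                           noise_sd = 0.2, seed = 9)
  coh <- generate_cohort(cfg, panel = panel)
  props <- estimate_proportions(coh$beta, panel)
  perm_s <- sample(ncol(coh$beta$values))
  perm_p <- sample(nrow(coh$beta$values))
  shuffled <- beta_matrix(coh$beta$values[perm_p, perm_s],
                          probes = coh$beta$probes[perm_p, ])
  props2 <- estimate_proportions(shuffled, panel)
  m1 <- as.matrix(props[order(props$sample_id), citewas:::CELL_TYPES])
  m2 <- as.matrix(props2[order(props2$sample_id), citewas:::CELL_TYPES])
  expect_equal(m1, m2, tolerance = 1e-9)
})

test_that("noisy Dirichlet mixtures are recovered with small RMSE, degrading with noise", {
  panel <- generate_reference_panel(300, 10, seed = 16)
  rmse_at <- function(noise_sd) {
    cfg <- simulation_config(n_cases = 100, n_controls = 100, n_probes = 300,
                             n_snps = 20, n_mediated = 0, n_consequential = 0,
                             n_independent = 0,
                             case_cell_shift = c(CD8T = 0, CD4T = 0, NK = 0,
                                                 Bcell = 0, Mono = 0, Gran = 0),
                             batch_location = c(0, 0), batch_scale = c(1, 1),
                             plate_location = c(0, 0), noise_sd = noise_sd,
                             seed = 16)
    coh <- generate_cohort(cfg, panel = panel)
    props <- estimate_proportions(coh$beta, panel)
    truth <- coh$truth$cell_fractions
    est <- as.matrix(props[match(truth$sample_id, props$sample_id),
                           citewas:::CELL_TYPES])
    sqrt(colMeans((est - as.matrix(truth[, citewas:::CELL_TYPES]))^2))
  }
  r03 <- rmse_at(0.3)
  expect_lt(max(r03), 0.05)
  means <- vapply(c(0.1, 0.4, 0.8), function(s) mean(rmse_at(s)), numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("proportion contrasts handle identical groups and recover planted shifts", {
  props <- tibble::tibble(sample_id = sprintf("S%04d", 1:8))
  for (ct in citewas:::CELL_TYPES) props[[ct]] <- rep(1 / 6, 8)
  props$fit_residual <- 0
  class(props) <- c("cell_proportions", class(props))
  samples <- make_toy_samples(8)
  samples$case_status <- rep(c(1L, 0L), 4)
  ctr <- compare_proportions(props, samples)
  expect_equal(ctr$difference, rep(0, 6))
  expect_equal(ctr$p_value, rep(1, 6))
  expect_true(all(ctr$conf_low <= ctr$difference &
                    ctr$difference <= ctr$conf_high))

  # default case shift reproduces the qualitative blood pattern
  cfg <- simulation_config(n_cases = 200, n_controls = 200, n_probes = 300,
                           n_snps = 20, n_mediated = 0, n_consequential = 0,
                           n_independent = 0, batch_location = c(0, 0),
                           batch_scale = c(1, 1), plate_location = c(0, 0),
                           noise_sd = 0.3, seed = 18)
  coh <- generate_cohort(cfg)
  props2 <- estimate_proportions(coh$beta, coh$panel)
  ctr2 <- compare_proportions(props2, coh$samples)
  get <- function(ct) ctr2$difference[ctr2$cell_type == ct]
  expect_gt(get("Gran"), 0)
  expect_lt(get("CD4T"), 0)
  expect_lt(get("CD8T"), 0)
  expect_lt(ctr2$p_value[ctr2$cell_type == "Gran"], 0.05)

  expect_error(compare_proportions(props[1:2, ], samples[1:2, ]), "at least 2")
})

test_that("variance explained is 1 for pure mixtures, 0 after shuffling, and bounded", {
  panel <- generate_reference_panel(200, 8, seed = 19)
  cfg <- simulation_config(n_cases = 40, n_controls = 40, n_probes = 200,
                           n_snps = 20, n_mediated = 0, n_consequential = 0,
                           n_independent = 0,
                           case_cell_shift = c(CD8T = 0, CD4T = 0, NK = 0,
                                               Bcell = 0, Mono = 0, Gran = 0),
                           batch_location = c(0, 0), batch_scale = c(1, 1),
                           plate_location = c(0, 0), noise_sd = 0, seed = 19)
  coh <- generate_cohort(cfg, panel = panel)
  M <- logit_transform(coh$beta)
  props <- coh$truth$cell_fractions
  props$fit_residual <- 0
  ve <- variance_explained(M, props)
  marker <- grepl("^cpgM", ve$per_probe$probe_id)
  # the mixture is linear in beta; the logit bends it slightly, so the
  # marker R-squared sits just below 1
  expect_gt(min(ve$per_probe$r_squared[marker], na.rm = TRUE), 0.98)
  expect_true(all(ve$per_probe$r_squared >= 0 & ve$per_probe$r_squared <= 1,
                  na.rm = TRUE))

  set.seed(1)
  shuffled <- props
  shuffled$sample_id <- sample(shuffled$sample_id)
  cfg_noise <- cfg; cfg_noise$noise_sd <- 0.3; cfg_noise$seed <- 20
  coh2 <- generate_cohort(cfg_noise, panel = panel)
  ve2 <- variance_explained(logit_transform(coh2$beta), shuffled)
  expect_lt(ve2$mean_r_squared, 0.1)
})
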