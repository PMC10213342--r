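test_that("zero-noise planting reproduces the target spectra exactly", {
  cfg <- panel_sim_config(noise = 0, seed = 71)
  sim <- simulate_panel(cfg)
  gp <- grouped_panel(sim$expression, sim$metadata)
  for (g in names(gp$groups)) {
    fr <- eigendecompose(gram_matrix(gp$groups[[g]]))$fractions
    expect_equal(fr, cfg$spectra[[g]], tolerance = 1e-8)
    # the planted leading direction is recovered up to sign
    v <- eigendecompose(gram_matrix(gp$groups[[g]]))$vectors_profile[, 1]
    expect_equal(abs(sum(v * sim$truth$directions[[g]])), 1,
                 tolerance = 1e-8)
  }
})

test_that("generators are pure functions of their seed", {
  a <- simulate_panel(panel_sim_config(seed = 72))
  b <- simulate_panel(panel_sim_config(seed = 72))
  expect_identical(a, b)
  c1 <- simulate_classification_cohort(seed = 73)
  c2 <- simulate_classification_cohort(seed = 73)
  expect_identical(c1, c2)
  d1 <- simulate_background_modules(seed = 74)
  d2 <- simulate_background_modules(seed = 74)
  expect_identical(d1, d2)
})

test_that("raw-mode output is nonnegative and round-trips through the log step", {
  cfg <- panel_sim_config(
    spectra = stats::setNames(rep(list(c(0.9, 0.05, 0.03, 0.02)), 4),
                              c("control", "incipient", "moderate", "severe")),
    noise = 0.01, seed = 75)
  sim <- simulate_panel(cfg, mode = "raw")
  expect_identical(sim$expression$scale, "raw")
  expect_true(all(sim$expression$values >= 0))
  gp <- grouped_panel(sim$expression, sim$metadata)
  for (g in names(gp$groups)) {
    f1 <- leading_fraction(eigendecompose(gram_matrix(gp$groups[[g]])))
    expect_equal(f1, 0.9, tolerance = 0.03)
  }
  # an unrealizable request errors instead of silently shifting the spectrum
  flat <- panel_sim_config(
    spectra = stats::setNames(rep(list(c(0.3, 0.3, 0.2, 0.2)), 4),
                              c("control", "incipient", "moderate", "severe")),
    noise = 0, seed = 76)
  expect_error(simulate_panel(flat, mode = "raw", max_tries = 20),
               "nonnegative")
})

test_that("invalid spectra and undersized groups are rejected", {
  expect_error(panel_sim_config(spectra = list(control = c(0.5, 0.3, 0.3, 0.1)),
                                sizes = c(control = 9)),
               "sum 1")
  expect_error(panel_sim_config(spectra = list(control = c(0.2, 0.5, 0.2, 0.1)),
                                sizes = c(control = 9)),
               "nonincreasing")
  cfg <- panel_sim_config(sizes = c(control = 3))
  expect_error(simulate_panel(cfg), "exact spectra")
})

test_that("noiseless MMSE is the exact (rounded) linear map and clips at the ends", {
  X <- matrix(c(1, 2, 3, 4,
                2, 2, 2, 2,
                9, 9, 9, 9), 4, 3)
  rownames(X) <- gene_panel()$symbols
  colnames(X) <- paste0("s", 1:3)
  mm <- simulate_mmse(X, coeffs = c(1, 1, 1, 1), intercept = 2, noise_sd = 0)
  expect_identical(mm$mmse, c(12L, 10L, 30L))  # third sample clipped at 30
  truth <- attr(mm, "truth")
  expect_equal(truth$linear, c(s1 = 12, s2 = 10, s3 = 38))
})

test_that("zero coefficients give constant MMSE and a degenerate evaluation", {
  sim <- simulate_panel(panel_sim_config(sizes = c(8, 8, 8, 8), seed = 77))
  mm <- simulate_mmse(sim$expression, coeffs = rep(0, 4), intercept = 15,
                      noise_sd = 0)
  expect_true(all(mm$mmse == 15L))
})

test_that("auto-calibrated MMSE spans a realistic range and trains well", {
  sim <- simulate_panel(panel_sim_config(sizes = c(8, 8, 8, 8), seed = 78))
  mm <- simulate_mmse(sim$expression, noise_sd = 1, seed = 178)
  expect_true(all(mm$mmse >= 0 & mm$mmse <= 30))
  expect_gte(stats::sd(mm$mmse), 4)  # wide cognitive spread, not degenerate
})

test_that("classification cohorts honour sizes, separation and back-construction", {
  sim <- simulate_classification_cohort(seed = 79)
  expect_identical(as.vector(table(sim$labels)[c("control", "patient")]),
                   c(180L, 181L))
  # features recovered exactly from the back-constructed panel
  f <- extract_features(sim$expression)
  expect_equal(f$sum_expr, sim$features$sum_expr, tolerance = 1e-10)
  expect_equal(f$sd_expr, sim$features$sd_expr, tolerance = 1e-10)
  # delta = 0 is chance level; delta = 3 is nearly separable
  tr0 <- simulate_classification_cohort(delta = 0, seed = 80)
  te0 <- simulate_classification_cohort(n_control = 100, n_patient = 100,
                                        delta = 0, seed = 81)
  clf0 <- train_panel_classifier(extract_features(tr0$expression),
                                 tr0$labels, iters = 1000)
  auc0 <- roc_curve(predict(clf0, extract_features(te0$expression)),
                    te0$labels, positive = "patient")$auc
  expect_gte(auc0, 0.35)
  expect_lte(auc0, 0.65)
  tr3 <- simulate_classification_cohort(delta = 3, seed = 82)
  te3 <- simulate_classification_cohort(n_control = 100, n_patient = 100,
                                        delta = 3, seed = 83)
  clf3 <- train_panel_classifier(extract_features(tr3$expression),
                                 tr3$labels, iters = 1000)
  auc3 <- roc_curve(predict(clf3, extract_features(te3$expression)),
                    te3$labels, positive = "patient")$auc
  expect_gte(auc3, 0.95)
})

test_that("background modules carry their planted correlation structure", {
  bg <- simulate_background_modules(k_modules = 2, genes_per_module = 30,
                                    within_cor = 0.8, n_noise = 10,
                                    n_samples = 40, seed = 84)
  X <- bg$expression$values
  idx1 <- which(bg$truth$membership == "true_1")
  rho <- stats::cor(t(X[idx1, ]))
  expect_equal(mean(rho[upper.tri(rho)]), 0.8, tolerance = 0.1)
  noise_idx <- which(bg$truth$membership == "noise")
  rho_n <- stats::cor(t(X[c(idx1[1:5], noise_idx[1:5]), ]))
  expect_lt(mean(abs(rho_n[1:5, 6:10])), 0.25)
  expect_identical(as.vector(table(bg$truth$membership)[c("noise", "true_1")]),
                   c(10L, 30L))
})
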