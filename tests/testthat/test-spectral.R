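test_that("the Gram matrix is the table of uncentered row dot products", {
  R <- gram_matrix(matrix(c(1, 3, 2, 4), 2, 2))$R  # rows [1,2] and [3,4]
  expect_equal(unname(R), matrix(c(5, 11, 11, 25), 2, 2))
  # orthonormal rows give the identity
  Q <- qr.Q(qr(matrix(stats::rnorm(16), 4)))
  expect_equal(unname(gram_matrix(t(Q))$R), diag(4), tolerance = 1e-12)
  expect_error(gram_matrix(matrix(c(1, Inf, 2, 3), 2, 2)), "non-finite")
  expect_error(gram_matrix(matrix(1, 1, 5)), "at least 2")
})

test_that("eigenvalue fractions match the closed form for a 2x2 Gram matrix", {
  # R = [[5,11],[11,25]]: eigenvalues 15 +/- sqrt(221), trace 30
  sr <- eigendecompose(gram_matrix(matrix(c(1, 3, 2, 4), 2, 2)))
  expect_equal(sr$fractions,
               c((15 + sqrt(221)) / 30, (15 - sqrt(221)) / 30),
               tolerance = 1e-12)
})

test_that("flat, rank-1 and degenerate spectra behave as defined", {
  # identity Gram (s = 4): all fractions 1/4
  X <- sqrt(2) * t(qr.Q(qr(matrix(stats::rnorm(36), 6)))[, 1:4])
  sr <- eigendecompose(gram_matrix(X))
  expect_equal(sr$fractions, rep(0.25, 4), tolerance = 1e-12)
  # rank-1 panel (identical duplicated gene rows): leading fraction 1
  v <- c(1, 2, 3, 4, 5)
  X1 <- rbind(v, v, v, v)
  sr1 <- eigendecompose(gram_matrix(X1))
  expect_equal(sr1$fractions, c(1, 0, 0, 0), tolerance = 1e-12)
  expect_equal(leading_fraction(sr1), 1)
  # all-zero panel is rejected
  expect_error(eigendecompose(gram_matrix(matrix(0, 4, 5))), "degenerate")
})

test_that("spectral reconstruction and orthonormality invariants hold", {
  set.seed(11)
  for (i in 1:20) {
    X <- matrix(stats::rnorm(4 * sample(7:9, 1), 2, 0.5), 4)
    gm <- gram_matrix(X)
    sr <- eigendecompose(gm)
    expect_equal(sum(sr$fractions), 1, tolerance = 1e-9)
    expect_true(all(sr$fractions >= 0 & sr$fractions <= 1))
    expect_true(all(diff(sr$fractions) <= 1e-12))
    Q <- sr$vectors_raw
    expect_equal(crossprod(Q), diag(4), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(Q %*% diag(sr$values) %*% t(Q), gm$R, tolerance = 1e-8,
                 ignore_attr = TRUE)
    # leading fraction bounds for an s-gene panel
    expect_gte(leading_fraction(sr), 1 / 4 - 1e-12)
    expect_lte(leading_fraction(sr), 1 + 1e-12)
  }
})

test_that("Gram fractions equal normalized squared singular values", {
  set.seed(12)
  for (i in 1:25) {
    X <- matrix(stats::rnorm(4 * 8), 4)
    fr <- eigendecompose(gram_matrix(X))$fractions
    sv2 <- svd(X)$d^2
    expect_equal(fr, sv2 / sum(sv2), tolerance = 1e-8)
  }
})

test_that("fractions are invariant to scaling and equivariant to row permutation", {
  set.seed(13)
  X <- matrix(stats::rnorm(4 * 7, 2), 4)
  base <- eigendecompose(gram_matrix(X))
  for (c in c(-3, 0.01, 7)) {
    expect_equal(eigendecompose(gram_matrix(c * X))$fractions,
                 base$fractions, tolerance = 1e-10)
  }
  perm <- c(3, 1, 4, 2)
  pr <- eigendecompose(gram_matrix(X[perm, ]))
  expect_equal(pr$fractions, base$fractions, tolerance = 1e-10)
  expect_equal(abs(pr$vectors_raw), abs(base$vectors_raw[perm, ]),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("leading-vector alignment flags reversals and validates sizes", {
  set.seed(14)
  sr <- eigendecompose(gram_matrix(matrix(stats::rnorm(4 * 7, 2), 4)))
  self <- compare_leading_vectors(sr, sr)
  expect_equal(self$alignment, 1, tolerance = 1e-12)
  expect_false(self$reversed)
  v <- sr$vectors_raw[, 1]
  opp <- compare_leading_vectors(v, -v)
  expect_equal(opp$alignment, -1, tolerance = 1e-12)
  expect_true(opp$reversed)
  expect_error(compare_leading_vectors(v, c(1, 2, 3)), "differ")
})

test_that("the published control and severe leading directions are anti-aligned", {
  rv <- reference_eigenvectors()
  cmp <- compare_leading_vectors(rv$control[, 1], rv$severe[, 1])
  expect_equal(cmp$alignment, -0.9442237, tolerance = 1e-6)
  expect_true(cmp$reversed)
})

test_that("identical groups give a flat trajectory with no reversal", {
  set.seed(15)
  X <- matrix(stats::rnorm(4 * 8, 2), 4)
  srs <- lapply(c("control", "incipient", "moderate", "severe"),
                function(g) eigendecompose(gram_matrix(X, group = g)))
  traj <- coordination_trajectory(srs)
  expect_equal(unname(traj$deltas), rep(0, 3), tolerance = 1e-12)
  expect_false(any(traj$reversed))
  expect_equal(unname(diag(traj$alignment)), rep(1, 4))
  expect_true(all(traj$alignment >= -1 - 1e-12 & traj$alignment <= 1 + 1e-12))
})

test_that("a planted direction flip is detected through the profile anchor", {
  v <- c(1, 1, 1, 1) / 2
  cfg <- panel_sim_config(directions = list(control = v, incipient = v,
                                            moderate = v, severe = -v),
                          seed = 21)
  sim <- simulate_panel(cfg)
  gp <- grouped_panel(sim$expression, sim$metadata)
  srs <- lapply(names(gp$groups), function(g)
    eigendecompose(gram_matrix(gp$groups[[g]], group = g)))
  traj <- coordination_trajectory(srs)
  expect_true(traj$reversed[["severe"]])
  expect_false(traj$reversed[["moderate"]])
})

test_that("bootstrap intervals cover the point estimate", {
  set.seed(16)
  X <- matrix(stats::rnorm(4 * 9, 2, 0.3), 4)
  bs <- bootstrap_leading_fraction(X, n_boot = 200, seed = 3)
  expect_true(bs$lower <= bs$estimate && bs$estimate <= bs$upper)
  expect_length(bs$replicates, 200)
})
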