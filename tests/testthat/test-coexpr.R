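test_that("Spearman correlation handles monotone rows, reversals and ties", {
  X <- rbind(a = c(1, 2, 3, 4, 5), b = c(2, 4, 9, 16, 30),
             c = c(5, 4, 3, 2, 1))
  rho <- spearman_matrix(X)
  expect_equal(rho["a", "b"], 1)
  expect_equal(rho["a", "c"], -1)
  # ties: agreement with Pearson applied to hand-built average ranks
  set.seed(41)
  Y <- matrix(sample(1:4, 40, replace = TRUE), 4, 10)
  rownames(Y) <- paste0("g", 1:4); colnames(Y) <- paste0("s", 1:10)
  rho2 <- spearman_matrix(Y)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(rho2[i, j],
                 oracle_pearson(rank(Y[i, ]), rank(Y[j, ])),
                 tolerance = 1e-10)
  }
  # constant gene: correlation zeroed with a warning
  Z <- rbind(flat = rep(2, 5), var = c(1, 3, 2, 5, 4))
  expect_warning(rz <- spearman_matrix(Z), "constant")
  expect_equal(rz["flat", "var"], 0)
  expect_equal(diag(rz), c(flat = 1, var = 1))
})

test_that("soft-threshold adjacency raises |corr| to the power beta", {
  corr <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  a <- soft_adjacency(corr, 8)
  expect_identical(a[1, 2], 0.00390625)  # 0.5^8 exactly
  corr_neg <- matrix(c(1, -0.5, -0.5, 1), 2, 2)
  expect_identical(soft_adjacency(corr_neg, 8)[1, 2], 0.00390625)
  expect_equal(soft_adjacency(matrix(1, 2, 2), 8)[1, 2], 1)
  expect_error(soft_adjacency(corr, 0), "beta")
  expect_error(soft_adjacency(matrix(2, 2, 2), 8), "correlation")
})

test_that("scale-free fit selects a power for hub-structured networks only", {
  # heavy-tailed loadings on one factor give a broad connectivity spectrum
  set.seed(42)
  n <- 50; ng <- 300
  loads <- (seq_len(ng))^(-0.4)
  f <- stats::rnorm(n)
  X <- t(vapply(loads, function(l) l * f + sqrt(max(0, 1 - l^2)) *
                  stats::rnorm(n), numeric(n)))
  rownames(X) <- paste0("g", seq_len(ng)); colnames(X) <- paste0("s", 1:n)
  rho <- spearman_matrix(X)
  ps <- pick_soft_power(rho, betas = c(1, 2, 4, 6, 8))
  expect_false(is.na(ps$beta))
  expect_gte(max(ps$fit_table$fit_rsq), 0.8)
  # a single candidate that meets the threshold is chosen
  ps8 <- pick_soft_power(rho, betas = 8)
  expect_identical(ps8$beta, 8)
  # complete graph of equal weights has no scale-free signature
  flat <- matrix(0.5, 40, 40); diag(flat) <- 1
  expect_warning(psf <- pick_soft_power(flat, betas = c(2, 4, 8)), "no candidate")
  expect_true(is.na(psf$beta))
  expect_true(all(psf$fit_table$fit_rsq < 0.8))
})

test_that("three planted blocks are recovered essentially perfectly", {
  bg <- simulate_background_modules(k_modules = 3, genes_per_module = 40,
                                    within_cor = 0.8, n_noise = 40,
                                    n_samples = 30, seed = 11)
  adj <- soft_adjacency(spearman_matrix(bg$expression), beta = 8)
  asg <- detect_modules(adj, expr = bg$expression, min_size = 30)
  ari <- mclust::adjustedRandIndex(asg$module, bg$truth$membership)
  expect_gte(ari, 0.8)
  sizes <- attr(asg, "sizes")
  expect_identical(sum(names(sizes) != "unassigned"), 3L)
})

test_that("independent noise genes all land in the sink module", {
  bg <- simulate_background_modules(k_modules = 1, genes_per_module = 2,
                                    loads = 0, n_noise = 100,
                                    n_samples = 30, seed = 12)
  adj <- soft_adjacency(spearman_matrix(bg$expression), beta = 8)
  asg <- detect_modules(adj, expr = bg$expression, min_size = 30)
  expect_true(all(asg$module == "unassigned"))
})

test_that("blocks with correlated latent factors merge under the merge cut", {
  n <- 30
  set.seed(13)
  f1 <- stats::rnorm(n)
  f2 <- 0.9 * f1 + sqrt(1 - 0.81) * stats::rnorm(n)
  bg <- simulate_background_modules(k_modules = 2, genes_per_module = 40,
                                    n_noise = 0, factors = cbind(f1, f2),
                                    seed = 14)
  adj <- soft_adjacency(spearman_matrix(bg$expression), beta = 8)
  asg <- detect_modules(adj, expr = bg$expression, min_size = 30,
                        merge_cut = 0.25)
  sizes <- attr(asg, "sizes")
  expect_identical(sum(names(sizes) != "unassigned"), 1L)
  # merging monotonicity: a larger merge cut never yields more modules
  n_mod <- function(mc) {
    s <- attr(detect_modules(adj, expr = bg$expression, min_size = 30,
                             merge_cut = mc), "sizes")
    sum(names(s) != "unassigned")
  }
  counts <- vapply(c(0.05, 0.15, 0.3, 0.5), n_mod, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("fewer genes than min_size yields a sink-only assignment", {
  bg <- simulate_background_modules(k_modules = 1, genes_per_module = 5,
                                    n_noise = 0, n_samples = 10, seed = 15)
  adj <- soft_adjacency(spearman_matrix(bg$expression), beta = 8)
  expect_warning(asg <- detect_modules(adj, min_size = 30), "fewer genes")
  expect_true(all(asg$module == "unassigned"))
})

test_that("module eigengenes summarize, orient and recover planted factors", {
  # identical rows: eigengene proportional to the standardized shared profile
  prof <- c(3, 1, 4, 1, 5, 9)
  Xm <- rbind(prof, prof, prof)
  eg <- module_eigengene(Xm)
  z <- (prof - mean(prof)) / stats::sd(prof)
  expect_equal(abs(oracle_pearson(eg, z)), 1, tolerance = 1e-10)
  expect_gt(sum(eg * z), 0)  # sign follows the mean profile
  # negating every gene flips the eigengene
  set.seed(16)
  Xr <- matrix(stats::rnorm(5 * 12), 5, 12)
  expect_equal(module_eigengene(-Xr), -module_eigengene(Xr),
               tolerance = 1e-10)
  # planted one-factor module: eigengene tracks the factor
  f <- stats::rnorm(30)
  bg <- simulate_background_modules(k_modules = 1, genes_per_module = 40,
                                    n_noise = 0, factors = cbind(f),
                                    within_cor = 0.8, seed = 17)
  eg2 <- module_eigengene(bg$expression$values)
  expect_gte(abs(stats::cor(eg2, f)), 0.95)
  expect_error(module_eigengene(matrix(1, 3, 4)), "constant")
})

test_that("module-trait correlation ranks a group-coded module on top", {
  group_code <- rep(1:4, times = c(9, 7, 8, 7))
  set.seed(18)
  other <- stats::rnorm(31)
  bg <- simulate_background_modules(k_modules = 2, genes_per_module = 40,
                                    n_noise = 20, n_samples = 31,
                                    factors = cbind(scale(group_code), other),
                                    within_cor = 0.8, seed = 19)
  adj <- soft_adjacency(spearman_matrix(bg$expression), beta = 8)
  asg <- detect_modules(adj, expr = bg$expression, min_size = 30)
  eg <- module_eigengenes(asg, bg$expression)
  traits <- cbind(group = group_code, age = stats::rnorm(31))
  mt <- module_trait_correlation(eg, traits)
  expect_true(all(abs(mt$cor) <= 1))
  # the module carrying the group factor has the highest |corr| with group
  top <- rownames(mt$cor)[which.max(abs(mt$cor[, "group"]))]
  group_block_module <- asg$module[asg$gene_id == "gene_001"]
  expect_identical(top, group_block_module)
  expect_gte(max(abs(mt$cor[, "group"])), 0.8)
  # a trait equal to an eigengene correlates exactly 1
  mt2 <- module_trait_correlation(eg, cbind(self = eg[, 1]))
  expect_equal(unname(mt2$cor[1, "self"]), 1, tolerance = 1e-10)
  # constant trait: zero with warning
  expect_warning(mt3 <- module_trait_correlation(eg, cbind(flat = rep(2, 31))),
                 "constant trait")
  expect_true(all(mt3$cor[, "flat"] == 0))
})
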