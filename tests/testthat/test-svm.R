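test_that("sum/SD features follow their closed forms and gene-order symmetry", {
  panel <- cbind(c(2, 2, 2, 2), c(1, 2, 3, 4))
  rownames(panel) <- gene_panel()$symbols
  colnames(panel) <- c("a", "b")
  f <- extract_features(panel)
  expect_equal(f$sum_expr, c(8, 10))
  expect_equal(f$sd_expr, c(0, sqrt(1.25)))  # population SD of 1..4
  fs <- extract_features(panel, sd_type = "sample")
  expect_equal(fs$sd_expr[2], sqrt(5 / 3), tolerance = 1e-12)
  # permuting gene rows changes nothing
  perm <- panel[c(3, 1, 4, 2), ]
  expect_equal(extract_features(perm)[, -1], f[, -1])
  expect_error(extract_features(panel[1:3, ]), "at least 4")
})

test_that("RBF similarity has unit peak, exact e^-1 point and monotone decay", {
  x <- c(0.3, -1.2)
  expect_identical(rbf_similarity(x, x, 0.5), 1)
  l <- x + c(1, 0)  # squared distance exactly 1
  expect_equal(rbf_similarity(x, l, 0.5), exp(-1), tolerance = 1e-12)
  d <- seq(0.1, 3, by = 0.1)
  sims <- vapply(d, function(dd) rbf_similarity(c(0, 0), c(dd, 0), 0.5),
                 numeric(1))
  expect_true(all(diff(sims) < 0))
  expect_error(rbf_similarity(x, l, 0), "sigma2")
  expect_error(rbf_similarity(x, c(1, 2, 3)), "dimension")
})

test_that("the landmark map has unit self-similarity and widens with sigma2", {
  set.seed(61)
  F <- matrix(stats::rnorm(20), 10, 2)
  Y <- rbf_map(F, F, 0.5)
  expect_equal(unname(diag(Y)), rep(1, 10))
  Y2 <- rbf_map(F, F, 1.0)
  off <- upper.tri(Y)
  expect_true(all(Y2[off] >= Y[off]))
  expect_equal(rbf_map(matrix(c(1, 0), 1), matrix(c(0, 0), 1), 0.5)[1, 1],
               exp(-1), tolerance = 1e-12)
})

test_that("the subgradient solver separates clouds and matches a convex solver", {
  sim <- simulate_classification_cohort(n_control = 20, n_patient = 20,
                                        delta = 3, seed = 62)
  Z <- scale(as.matrix(sim$features[, c("sum_expr", "sd_expr")]))
  Y <- rbf_map(Z, Z, 0.5)
  m <- svm_train(Y, sim$labels, C = 1)
  acc <- mean((svm_decision(m, Y) >= 0) == (sim$labels == "patient"))
  expect_gte(acc, 0.95)
  # objective within 1% of an established convex solver on the same problem
  y_pm <- ifelse(sim$labels == "patient", 1, -1)
  ref <- e1071::svm(Y, factor(sim$labels), kernel = "linear", cost = 1,
                    scale = FALSE)
  w_ref <- drop(t(ref$coefs) %*% Y[ref$index, , drop = FALSE])
  b_ref <- -ref$rho
  obj <- function(w, b)
    0.5 * sum(w^2) + sum(pmax(0, 1 - y_pm * (drop(Y %*% w) + b)))
  ref_obj <- min(obj(w_ref, b_ref), obj(-w_ref, -b_ref))
  expect_lte(m$objective, ref_obj * 1.01)
})

test_that("flipping every label exactly negates the decision function", {
  sim <- simulate_classification_cohort(n_control = 15, n_patient = 15,
                                        delta = 1.5, seed = 63)
  Z <- scale(as.matrix(sim$features[, c("sum_expr", "sd_expr")]))
  Y <- rbf_map(Z, Z, 0.5)
  flipped <- factor(ifelse(sim$labels == "patient", "control", "patient"),
                    levels = levels(sim$labels))
  m1 <- svm_train(Y, sim$labels, C = 1, iters = 500)
  m2 <- svm_train(Y, flipped, C = 1, iters = 500)
  expect_equal(svm_decision(m1, Y), -svm_decision(m2, Y), tolerance = 1e-8)
  expect_error(svm_train(Y, rep("patient", nrow(Y))), "two classes")
})

test_that("confusion counts implement sensitivity p/(p+n) and specificity t/(f+t)", {
  scores <- c(2, 1, -1, -2, 0.5, -0.5)
  labels <- c("patient", "patient", "patient", "control", "control", "control")
  cc <- confusion_counts(scores, labels, threshold = 0, positive = "patient")
  expect_identical(cc[c("p", "n", "t", "f")],
                   list(p = 2L, n = 1L, t = 2L, f = 1L))
  expect_equal(cc$sensitivity, 2 / 3)
  expect_equal(cc$specificity, 2 / 3)
})

test_that("ROC endpoints, monotonicity and AUC corner cases are exact", {
  lab <- rep(c("control", "patient"), each = 4)
  perfect <- roc_curve(c(1, 2, 3, 4, 5, 6, 7, 8), lab, positive = "patient")
  expect_equal(perfect$auc, 1)
  inverted <- roc_curve(c(8, 7, 6, 5, 4, 3, 2, 1), lab, positive = "patient")
  expect_equal(inverted$auc, 0)
  set.seed(64)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    scores <- round(stats::rnorm(n), 1)  # coarse rounding forces ties
    labels <- sample(c("control", "patient"), n, replace = TRUE,
                     prob = c(0.5, 0.5))
    if (length(unique(labels)) < 2) next
    rc <- roc_curve(scores, labels, positive = "patient")
    expect_equal(rc$curve$fpr[1], 0)
    expect_equal(rc$curve$sensitivity[1], 0)
    expect_equal(utils::tail(rc$curve$fpr, 1), 1)
    expect_equal(utils::tail(rc$curve$sensitivity, 1), 1)
    expect_true(all(diff(rc$curve$fpr) >= 0))
    expect_true(all(diff(rc$curve$sensitivity) >= 0))
    expect_equal(rc$auc, oracle_auc(scores, labels, "patient"),
                 tolerance = 1e-10)
  }
})

test_that("random scores on balanced labels give chance-level AUC", {
  set.seed(65)
  scores <- stats::rnorm(1000)
  labels <- rep(c("control", "patient"), 500)
  auc <- roc_curve(scores, labels, positive = "patient")$auc
  expect_gte(auc, 0.45)
  expect_lte(auc, 0.55)
})

test_that("the end-to-end classifier scores new cohorts sensibly", {
  tr <- simulate_classification_cohort(n_control = 60, n_patient = 60,
                                       delta = 3, seed = 66)
  te <- simulate_classification_cohort(n_control = 30, n_patient = 30,
                                       delta = 3, seed = 67)
  clf <- train_panel_classifier(extract_features(tr$expression), tr$labels,
                                iters = 1000)
  auc <- roc_curve(predict(clf, extract_features(te$expression)), te$labels,
                   positive = "patient")$auc
  expect_gte(auc, 0.95)
  # k-means landmark reduction stays functional
  clf_k <- train_panel_classifier(extract_features(tr$expression), tr$labels,
                                  n_landmarks = 10, iters = 500, seed = 5)
  auc_k <- roc_curve(predict(clf_k, extract_features(te$expression)),
                     te$labels, positive = "patient")$auc
  expect_gte(auc_k, 0.9)
})
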