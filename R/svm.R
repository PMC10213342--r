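# From-scratch max-margin classifier over (sum, SD) panel features with RBF
# landmark mapping, plus ROC/AUC built from sensitivity = p/(p+n) and
# specificity = t/(f+t).

#' Sum and standard-deviation features of the panel
#'
#' Each sample is summarized by the sum of its four log10 panel expression
#' values and their standard deviation. Both statistics are symmetric in
#' the genes, so the features are invariant to panel row order.
#'
#' @param panel numeric genes x samples matrix (log10 scale) with >= 4 rows.
#' @param sd_type `"population"` (divide by the panel size; default) or
#'   `"sample"` (divide by size - 1).
#' @return data.frame with `sample_id`, `sum_expr`, `sd_expr`.
#' @export
extract_features <- function(panel, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (inherits(panel, "expr_matrix")) panel <- panel$values
  if (nrow(panel) < 4L) stopf("panel has %d rows; need at least 4", nrow(panel))
  ids <- colnames(panel)
  if (is.null(ids)) ids <- paste0("S", seq_len(ncol(panel)))
  mu <- colMeans(panel)
  ss <- colSums(sweep(panel, 2L, mu)^2)
  denom <- if (sd_type == "population") nrow(panel) else nrow(panel) - 1L
  data.frame(sample_id = ids, sum_expr = colSums(panel),
             sd_expr = sqrt(ss / denom), stringsAsFactors = FALSE)
}

#' Gaussian (RBF) similarity between two feature vectors
#'
#' `exp(-||x - l||^2 / (2 sigma2))`; equals 1 at zero distance and decays
#' monotonically with distance.
#'
#' @param x,l numeric vectors of equal length.
#' @param sigma2 positive bandwidth (default 0.5).
#' @return similarity in (0, 1\].
#' @export
rbf_similarity <- function(x, l, sigma2 = 0.5) {
  if (length(x) != length(l)) stopf("dimension mismatch")
  if (!is_scalar_number(sigma2) || sigma2 <= 0) stopf("`sigma2` must be > 0")
  exp(-sum((x - l)^2) / (2 * sigma2))
}

#' RBF landmark mapping
#'
#' Represents every sample by its vector of Gaussian similarities to a set
#' of landmark points — the kernel feature expansion used by the classifier.
#'
#' @param features samples x d numeric matrix.
#' @param landmarks m x d numeric matrix (nonempty).
#' @param sigma2 positive bandwidth (default 0.5).
#' @return samples x m matrix of similarities.
#' @export
rbf_map <- function(features, landmarks, sigma2 = 0.5) {
  features <- as.matrix(features)
  landmarks <- as.matrix(landmarks)
  if (nrow(landmarks) == 0L) stopf("landmark set is empty")
  if (ncol(features) != ncol(landmarks)) stopf("dimension mismatch")
  if (!is_scalar_number(sigma2) || sigma2 <= 0) stopf("`sigma2` must be > 0")
  d2 <- outer(rowSums(features^2), rowSums(landmarks^2), `+`) -
    2 * tcrossprod(features, landmarks)
  exp(-pmax(d2, 0) / (2 * sigma2))
}

# Hinge objective: 0.5 ||w||^2 + C * sum_i max(0, 1 - y_i (w.x_i + b)).
svm_objective <- function(w, b, Y, y, C) {
  0.5 * sum(w^2) + C * sum(pmax(0, 1 - y * (drop(Y %*% w) + b)))
}

#' Train a soft-margin linear classifier on mapped features
#'
#' Minimizes the hinge objective `0.5 ||W||^2 + C sum hinge` by
#' deterministic full-batch subgradient descent with step size 1/t
#' (the classical schedule for a 1-strongly-convex objective), returning
#' the average of the second half of the iterates. Maximizing the margin
#' `1 / ||W||^2` is equivalent to the `0.5 ||W||^2` penalty.
#'
#' @param Y samples x m mapped feature matrix (from [rbf_map()]).
#' @param labels two-level factor/character/numeric labels; the second
#'   level sorted (or the larger numeric) is the positive class.
#' @param C soft-margin cost (default 1).
#' @param iters subgradient iterations (default 2000).
#' @return object of class `svm_model`: list with `w`, `b`, `C`, `margin`
#'   (`1 / ||w||^2`), `objective`, `objective_trace`, `levels`.
#' @export
svm_train <- function(Y, labels, C = 1, iters = 2000L) {
  Y <- as.matrix(Y)
  if (!is_scalar_number(C) || C <= 0) stopf("`C` must be > 0")
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2L) stopf("need exactly two classes (got %d)", length(lv))
  y <- ifelse(as.character(labels) == lv[2L], 1, -1)
  w <- rep(0, ncol(Y)); b <- 0
  w_acc <- w; b_acc <- 0; n_acc <- 0L
  trace <- numeric(iters)
  for (t in seq_len(iters)) {
    margins <- y * (drop(Y %*% w) + b)
    viol <- margins < 1
    gw <- w - C * drop(crossprod(Y[viol, , drop = FALSE], y[viol]))
    gb <- -C * sum(y[viol])
    eta <- 1 / t
    w <- w - eta * gw
    b <- b - eta * gb
    trace[t] <- svm_objective(w, b, Y, y, C)
    if (t > iters / 2) {
      w_acc <- w_acc + w; b_acc <- b_acc + b; n_acc <- n_acc + 1L
    }
  }
  w_avg <- w_acc / n_acc; b_avg <- b_acc / n_acc
  # keep whichever of (last, averaged) iterate has the lower objective
  if (svm_objective(w_avg, b_avg, Y, y, C) <
      svm_objective(w, b, Y, y, C)) {
    w <- w_avg; b <- b_avg
  }
  structure(list(w = w, b = b, C = C, margin = 1 / sum(w^2),
                 objective = svm_objective(w, b, Y, y, C),
                 objective_trace = trace, levels = lv),
            class = "svm_model")
}

#' Decision values of a trained classifier
#'
#' @param model an [svm_train()] model.
#' @param Y mapped feature matrix.
#' @return numeric decision values `Y w + b`; positive favours the positive
#'   class (`model$levels[2]`).
#' @export
svm_decision <- function(model, Y) {
  drop(as.matrix(Y) %*% model$w) + model$b
}

#' Confusion counts at a fixed threshold
#'
#' Counts true positives `p`, false negatives `n`, true negatives `t` and
#' false positives `f`, and the derived sensitivity `p / (p + n)` and
#' specificity `t / (f + t)`.
#'
#' @param scores numeric decision values.
#' @param labels two-class labels; positive class is the second sorted
#'   level unless `positive` is given.
#' @param threshold classify as positive when `score >= threshold`
#'   (default 0).
#' @param positive positive-class label.
#' @return list with `p`, `n`, `t`, `f`, `sensitivity`, `specificity`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0,
                             positive = NULL) {
  lab <- as.character(labels)
  lv <- sort(unique(lab))
  if (length(lv) != 2L) stopf("need exactly two classes")
  if (is.null(positive)) positive <- lv[2L]
  truth <- lab == positive
  call_pos <- scores >= threshold
  p <- sum(call_pos & truth)
  n <- sum(!call_pos & truth)
  t <- sum(!call_pos & !truth)
  f <- sum(call_pos & !truth)
  list(p = p, n = n, t = t, f = f,
       sensitivity = p / (p + n), specificity = t / (f + t))
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the sorted unique scores (tied scores
#' move as one step), plotting sensitivity against 1 - specificity; the
#' area is computed by the trapezoid rule. The curve always starts at
#' (0, 0) and ends at (1, 1) and is monotone nondecreasing in both
#' coordinates.
#'
#' @param scores numeric decision values (higher favours positive).
#' @param labels two-class labels; positive class is the second sorted
#'   level unless `positive` is given.
#' @param positive positive-class label.
#' @return object of class `roc_curve`: list with `curve` (data.frame
#'   `fpr`, `sensitivity`, `threshold`) and `auc`.
#' @export
roc_curve <- function(scores, labels, positive = NULL) {
  lab <- as.character(labels)
  lv <- sort(unique(lab))
  if (length(lv) != 2L) stopf("need exactly two classes")
  if (is.null(positive)) positive <- lv[2L]
  truth <- lab == positive
  npos <- sum(truth); nneg <- sum(!truth)
  thr <- sort(unique(scores), decreasing = TRUE)
  fpr <- sens <- numeric(length(thr) + 1L)
  tp <- fp <- 0
  # cumulative counts walking the thresholds downward
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]; t_sorted <- truth[ord]
  i <- 1L
  for (k in seq_along(thr)) {
    while (i <= length(s_sorted) && s_sorted[i] >= thr[k]) {
      if (t_sorted[i]) tp <- tp + 1 else fp <- fp + 1
      i <- i + 1L
    }
    sens[k + 1L] <- tp / npos
    fpr[k + 1L] <- fp / nneg
  }
  auc <- sum(diff(fpr) * (utils::head(sens, -1L) + utils::tail(sens, -1L)) / 2)
  structure(list(curve = data.frame(fpr = fpr, sensitivity = sens,
                                    threshold = c(Inf, thr)),
                 auc = auc, positive = positive),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f (positive = %s)\n",
              nrow(x$curve), x$auc, x$positive))
  invisible(x)
}

#' Train the panel disease classifier
#'
#' The full classification path: z-scores the (sum, SD) features with
#' training-set statistics (RBF distances are scale-sensitive), uses the
#' scaled training samples themselves as landmarks (optionally a k-means
#' reduction), maps through [rbf_map()] and trains [svm_train()].
#'
#' @param features training samples x 2 feature matrix (columns
#'   `sum_expr`, `sd_expr` or any two numeric columns).
#' @param labels two-class labels.
#' @param sigma2 RBF bandwidth (default 0.5).
#' @param C soft-margin cost (default 1).
#' @param n_landmarks `NULL` (all training samples) or a k-means landmark
#'   count.
#' @param iters subgradient iterations.
#' @param seed seed for the optional k-means landmark selection.
#' @return object of class `panel_classifier` with a `predict` method
#'   returning decision values for new feature rows.
#' @export
train_panel_classifier <- function(features, labels, sigma2 = 0.5, C = 1,
                                   n_landmarks = NULL, iters = 2000L,
                                   seed = 1L) {
  X <- as.matrix(features[, intersect(c("sum_expr", "sd_expr"),
                                      colnames(features)), drop = FALSE])
  if (!ncol(X)) X <- as.matrix(features)
  mu <- colMeans(X); sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- scale(X, center = mu, scale = sdv)
  landmarks <- if (is.null(n_landmarks)) Z else
    with_seed(seed, stats::kmeans(Z, centers = n_landmarks)$centers)
  Y <- rbf_map(Z, landmarks, sigma2)
  model <- svm_train(Y, labels, C = C, iters = iters)
  structure(list(svm = model, landmarks = landmarks, sigma2 = sigma2,
                 center = mu, scale = sdv,
                 feature_names = colnames(X)),
            class = "panel_classifier")
}

#' @export
predict.panel_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  Z <- scale(X, center = object$center, scale = object$scale)
  svm_decision(object$svm, rbf_map(Z, object$landmarks, object$sigma2))
}
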