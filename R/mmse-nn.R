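# From-scratch 4-32-1 feedforward network predicting MMSE from the panel.
#
# Architecture: y = b + c . sigmoid(k + W x), i.e. a single sigmoid hidden
# layer of 32 units and a LINEAR output (no output nonlinearity). Trained by
# per-sample stochastic gradient descent on squared error, in a seeded
# shuffled order, so identical seed + data give bitwise-identical
# parameters.

sigmoid <- function(v) 1 / (1 + exp(-v))

#' Initialize network parameters
#'
#' Uniform(-r, r) initialization with r = sqrt(6 / (fan_in + fan_out)) per
#' layer; biases start at zero.
#'
#' @param seed integer seed.
#' @param n_in input dimension (default 4, the panel size).
#' @param n_hidden hidden units (default 32).
#' @return object of class `nn_params`: list with `W` (n_hidden x n_in),
#'   `k` (hidden biases), `c` (hidden-to-output weights), `b` (output bias).
#' @export
nn_init <- function(seed = 1L, n_in = 4L, n_hidden = 32L) {
  with_seed(seed, {
    r1 <- sqrt(6 / (n_in + n_hidden))
    r2 <- sqrt(6 / (n_hidden + 1))
    structure(list(
      W = matrix(stats::runif(n_hidden * n_in, -r1, r1), n_hidden, n_in),
      k = rep(0, n_hidden),
      c = stats::runif(n_hidden, -r2, r2),
      b = 0), class = "nn_params")
  })
}

#' Forward pass
#'
#' @param params an `nn_params` object.
#' @param x numeric input vector of length `ncol(params$W)`, or a matrix
#'   with one column per sample.
#' @return predicted value(s), unclipped.
#' @export
nn_forward <- function(params, x) {
  if (is.matrix(x)) {
    if (nrow(x) != ncol(params$W)) stopf("input has %d rows, expected %d",
                                         nrow(x), ncol(params$W))
    a <- sigmoid(params$k + params$W %*% x)
    return(drop(params$b + crossprod(a, params$c)))
  }
  if (length(x) != ncol(params$W))
    stopf("input has length %d, expected %d", length(x), ncol(params$W))
  a <- sigmoid(params$k + drop(params$W %*% x))
  params$b + sum(params$c * a)
}

#' Gradient of the squared error for one sample
#'
#' Analytic gradient of `(y - target)^2` with respect to every parameter.
#' Kept exported because the finite-difference check of this gradient is
#' the central correctness test of a hand-written network.
#'
#' @param params an `nn_params` object.
#' @param x input vector.
#' @param target scalar target.
#' @return list with fields `W`, `k`, `c`, `b` (same shapes as `params`).
#' @export
nn_gradient <- function(params, x, target) {
  v <- params$k + drop(params$W %*% x)
  a <- sigmoid(v)
  y <- params$b + sum(params$c * a)
  e <- 2 * (y - target)
  gv <- e * params$c * a * (1 - a)
  list(W = tcrossprod(gv, x), k = gv, c = e * a, b = e)
}

# Fit min-max normalization bounds on training features (rows = samples).
fit_minmax <- function(X) {
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  span <- hi - lo
  span[span == 0] <- 1  # constant feature maps to 0
  list(lo = lo, span = span)
}

apply_minmax <- function(X, nb) sweep(sweep(X, 2L, nb$lo), 2L, nb$span, `/`)

#' Train the MMSE network
#'
#' Per-sample SGD on squared error for `epochs` passes over the data, with
#' the visit order reshuffled each epoch from a seeded stream. Inputs are
#' min-max normalized to \[0, 1\] with bounds fit on the training set only.
#'
#' @param x samples x 4 numeric feature matrix (log10 panel expression).
#' @param y numeric MMSE targets in \[0, 30\].
#' @param lr learning rate (default 0.05).
#' @param epochs training epochs (default 2000).
#' @param seed integer seed for initialization and visit order.
#' @param n_hidden hidden units (default 32).
#' @return object of class `mmse_nn`: list with `params`, `norm` (min-max
#'   bounds), `loss_trace` (mean squared error per epoch) and the config.
#' @export
nn_train <- function(x, y, lr = 0.05, epochs = 2000L, seed = 1L,
                     n_hidden = 32L) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stopf("need at least 2 training pairs")
  if (length(y) != nrow(x)) stopf("feature/target length mismatch")
  if (any(y < 0 | y > 30)) stopf("MMSE targets must lie in [0, 30]")
  nb <- fit_minmax(x)
  Z <- apply_minmax(x, nb)
  p <- nn_init(seed, n_in = ncol(x), n_hidden = n_hidden)
  W <- p$W; k <- p$k; cc <- p$c; b <- p$b
  n <- nrow(Z)
  trace <- numeric(epochs)
  with_seed(derive_seed(seed, 7L), {
    for (ep in seq_len(epochs)) {
      for (i in sample.int(n)) {
        xi <- Z[i, ]
        v <- k + drop(W %*% xi)
        a <- sigmoid(v)
        e <- 2 * ((b + sum(cc * a)) - y[i])
        gv <- e * cc * a * (1 - a)
        W <- W - lr * tcrossprod(gv, xi)
        k <- k - lr * gv
        cc <- cc - lr * (e * a)
        b <- b - lr * e
      }
      pred <- drop(b + crossprod(sigmoid(k + W %*% t(Z)), cc))
      trace[ep] <- mean((pred - y)^2)
      if (!is.finite(trace[ep]))
        stopf("training diverged at epoch %d; try a smaller learning rate",
              ep)
    }
  })
  structure(list(params = structure(list(W = W, k = k, c = cc, b = b),
                                    class = "nn_params"),
                 norm = nb, loss_trace = trace,
                 config = list(lr = lr, epochs = epochs, seed = seed,
                               n_hidden = n_hidden)),
            class = "mmse_nn")
}

#' @export
predict.mmse_nn <- function(object, newdata, ...) {
  Z <- apply_minmax(as.matrix(newdata), object$norm)
  nn_forward(object$params, t(Z))
}

#' Evaluate MMSE predictions
#'
#' Pearson and Spearman correlation between predictions and targets, with
#' the two-sided Pearson p value. Predictions are additionally clipped to
#' \[0, 30\] for reporting; the unclipped values are retained.
#'
#' @param model a fitted [nn_train()] model.
#' @param x samples x 4 test feature matrix.
#' @param y true MMSE values (>= 3 test pairs).
#' @return object of class `regression_eval`: list with `predicted`,
#'   `predicted_clipped`, `true`, `pearson_r`, `spearman_r`, `p_value`,
#'   `mse`.
#' @export
nn_evaluate <- function(model, x, y) {
  if (length(y) < 3L) stopf("need at least 3 test pairs")
  pred <- predict(model, x)
  if (stats::sd(pred) == 0 || stats::sd(y) == 0) {
    warnf("degenerate correlation (constant predictions or targets); reported as 0")
    pr <- sr <- 0; pv <- NA_real_
  } else {
    ct <- stats::cor.test(pred, y, method = "pearson")
    pr <- unname(ct$estimate); pv <- ct$p.value
    sr <- stats::cor(pred, y, method = "spearman")
  }
  structure(list(predicted = pred,
                 predicted_clipped = pmin(pmax(pred, 0), 30),
                 true = y, pearson_r = pr, spearman_r = sr, p_value = pv,
                 mse = mean((pred - y)^2)),
            class = "regression_eval")
}

#' @export
print.regression_eval <- function(x, ...) {
  cat(sprintf("<regression_eval> pearson r = %.3f, spearman r = %.3f, p = %.3g, mse = %.3f\n",
              x$pearson_r, x$spearman_r, x$p_value, x$mse))
  invisible(x)
}
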