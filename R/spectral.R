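# The core statistic: per-group uncentered Gram (inner-product) matrices of
# the gene panel, their fraction-normalized eigendecomposition, and
# cross-group comparison of leading eigenvalue fractions and leading
# directions.
#
# The Gram matrix is deliberately UNCENTERED and UNSCALED: R[i, j] is the
# plain dot product of the log10 expression rows of genes i and j. This is
# what distinguishes the coordination statistic from covariance PCA — the
# shared mean component of the panel is part of the signal.

#' Uncentered Gram matrix of a gene panel
#'
#' @param X numeric matrix (genes x samples) of log10 panel expression.
#' @param group optional group label carried into downstream results.
#' @param centered if `TRUE`, rows are mean-centered first. Diagnostic only;
#'   the coordination statistic is defined on uncentered data and the
#'   default is `FALSE`.
#' @return object of class `gram_matrix`: list with `R` (s x s symmetric),
#'   `group`, `n` (sample count), `s`, and `profile` (the panel's mean
#'   expression profile, `rowMeans(X)`, used downstream to anchor
#'   eigenvector signs).
#' @export
gram_matrix <- function(X, group = NA_character_, centered = FALSE) {
  if (inherits(X, "expr_matrix")) X <- X$values
  if (!is.matrix(X) || !is.numeric(X)) stopf("`X` must be a numeric matrix")
  if (!all(is.finite(X))) stopf("`X` contains non-finite entries")
  if (nrow(X) < 2L || ncol(X) < 2L)
    stopf("need at least 2 genes and 2 samples (got %d x %d)",
          nrow(X), ncol(X))
  profile <- rowMeans(X)
  if (centered) X <- X - profile
  R <- tcrossprod(X)
  R <- (R + t(R)) / 2  # enforce exact symmetry before decomposition
  structure(list(R = R, group = group, n = ncol(X), s = nrow(X),
                 profile = profile, centered = centered),
            class = "gram_matrix")
}

#' Eigendecompose a Gram matrix
#'
#' Eigenvalues are reported as fractions of their sum (so they lie in
#' \[0, 1\] and sum to 1), in descending order. Three eigenvector variants
#' are kept:
#' \describe{
#'   \item{`vectors_raw`}{as returned by the symmetric eigensolver. Used for
#'     alignment checks against externally printed vectors.}
#'   \item{`vectors`}{reporting convention: each column flipped so its
#'     largest-magnitude component is positive (eigenvectors are defined
#'     only up to sign).}
#'   \item{`vectors_profile`}{data-anchored convention: each column flipped
#'     so its dot product with the panel's mean expression profile is
#'     nonnegative. Because X and -X give the same Gram matrix, only this
#'     convention can carry a planted direction flip between groups; it is
#'     the one [compare_leading_vectors()] prefers.}
#' }
#'
#' Tied eigenvalues (relative gap below 1e-12) are ordered within the tied
#' block by descending first-component magnitude; eigenvectors inside a tied
#' block are non-unique.
#'
#' @param gm a [gram_matrix()].
#' @return object of class `spectral_result`.
#' @export
eigendecompose <- function(gm) {
  stopifnot(inherits(gm, "gram_matrix"))
  R <- gm$R
  tr <- sum(diag(R))
  if (tr <= .Machine$double.eps * nrow(R))
    stopf("degenerate panel: trace of the Gram matrix is zero")
  smallest_ok <- -1e-9 * tr
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < smallest_ok)
    stopf("Gram matrix is not positive semi-definite (min eigenvalue %g)",
          min(e$values))
  vals <- pmax(e$values, 0)  # clamp tiny negative round-off
  vecs <- e$vectors
  # tie handling: reorder within numerically tied blocks
  s <- length(vals)
  i <- 1L
  while (i < s) {
    j <- i
    while (j < s && abs(vals[j + 1L] - vals[i]) <= 1e-12 * tr) j <- j + 1L
    if (j > i) {
      blk <- i:j
      ord <- blk[order(abs(vecs[1L, blk]), decreasing = TRUE)]
      vals[blk] <- vals[ord]
      vecs[, blk] <- vecs[, ord]
    }
    i <- j + 1L
  }
  fractions <- vals / sum(vals)
  flip <- function(V, signs) sweep(V, 2L, signs, `*`)
  sign_or_one <- function(x) ifelse(x < 0, -1, 1)
  # reporting convention: largest-|component| positive
  max_sign <- apply(vecs, 2L, function(v) sign_or_one(v[which.max(abs(v))]))
  vectors <- flip(vecs, max_sign)
  vectors_profile <- NULL
  if (!is.null(gm$profile)) {
    d <- drop(crossprod(vecs, gm$profile))
    prof_sign <- ifelse(abs(d) < 1e-12, max_sign, sign_or_one(d))
    vectors_profile <- flip(vecs, prof_sign)
  }
  dimnames(vectors) <- dimnames(vecs) <- list(rownames(R), NULL)
  if (!is.null(vectors_profile)) rownames(vectors_profile) <- rownames(R)
  structure(list(group = gm$group, fractions = fractions, values = vals,
                 vectors = vectors, vectors_raw = vecs,
                 vectors_profile = vectors_profile,
                 sign_convention = "max_abs_positive",
                 profile = gm$profile, n = gm$n, s = gm$s),
            class = "spectral_result")
}

#' @export
print.spectral_result <- function(x, ...) {
  cat(sprintf("<spectral_result> group = %s, n = %d\n  fractions: %s\n",
              x$group, x$n,
              paste(sprintf("%.4f", x$fractions), collapse = ", ")))
  invisible(x)
}

#' Leading eigenvalue fraction
#'
#' The coordination statistic: the largest Gram eigenvalue divided by the
#' eigenvalue sum. For an s-gene panel it lies in \[1/s, 1\]; values near 1
#' mean the panel's joint expression is concentrated along one direction.
#'
#' @param sr a [spectral_result()][eigendecompose].
#' @return numeric scalar.
#' @export
leading_fraction <- function(sr) {
  stopifnot(inherits(sr, "spectral_result"))
  sr$fractions[1L]
}

# Pull the leading eigenvector from a spectral result (preferring the
# profile-anchored sign) or accept a plain numeric vector as-is.
leading_vector <- function(x, prefer_profile = TRUE) {
  if (inherits(x, "spectral_result")) {
    if (prefer_profile && !is.null(x$vectors_profile))
      return(x$vectors_profile[, 1L])
    return(x$vectors_raw[, 1L])
  }
  if (is.matrix(x)) return(x[, 1L])
  if (is.numeric(x)) return(x)
  stopf("expected a spectral_result or a numeric vector")
}

#' Alignment of two groups' leading directions
#'
#' Dot product between the leading eigenvectors of two spectral results; a
#' negative alignment flags a sign reversal of the panel's dominant
#' direction between the groups. When both results carry a mean expression
#' profile, vectors are first oriented against their own group's profile
#' (the only sign convention under which a reversal is identifiable from
#' data, since X and -X share a Gram matrix); plain numeric vectors (for
#' example externally printed eigenvector columns) are compared as given.
#'
#' @param a,b [spectral_result][eigendecompose] objects or numeric leading
#'   vectors of equal length.
#' @param prefer_profile use the profile-anchored sign convention when
#'   available (default `TRUE`).
#' @return list with `alignment` (in \[-1, 1\]) and `reversed`
#'   (`alignment < 0`).
#' @export
compare_leading_vectors <- function(a, b, prefer_profile = TRUE) {
  va <- leading_vector(a, prefer_profile)
  vb <- leading_vector(b, prefer_profile)
  if (length(va) != length(vb))
    stopf("panel sizes differ: %d vs %d", length(va), length(vb))
  alignment <- sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2)))
  list(alignment = alignment, reversed = alignment < 0)
}

#' Coordination trajectory across ordered severity groups
#'
#' Collects per-group leading fractions, consecutive deltas, the full
#' leading-direction alignment matrix and reversal flags relative to the
#' first group.
#'
#' @param results ordered list of [spectral_result][eigendecompose] objects
#'   sharing panel size and order (for example control, incipient, moderate,
#'   severe).
#' @return object of class `coordination_comparison`.
#' @export
coordination_trajectory <- function(results) {
  if (length(results) < 2L) stopf("need at least 2 groups")
  ss <- vapply(results, function(r) r$s, integer(1))
  if (length(unique(ss)) != 1L) stopf("inconsistent panel sizes across groups")
  labels <- vapply(results, function(r) as.character(r$group), character(1))
  if (anyNA(labels) || any(labels == "NA"))
    labels <- paste0("group_", seq_along(results))
  lead <- vapply(results, leading_fraction, numeric(1))
  names(lead) <- labels
  k <- length(results)
  A <- diag(1, k)
  dimnames(A) <- list(labels, labels)
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
    A[i, j] <- compare_leading_vectors(results[[i]], results[[j]])$alignment
  reversed <- A[1L, ] < 0
  structure(list(groups = labels, leading_fractions = lead,
                 deltas = diff(lead), alignment = A, reversed = reversed),
            class = "coordination_comparison")
}

#' @export
print.coordination_comparison <- function(x, ...) {
  cat("<coordination_comparison>\n  leading fractions:",
      paste(sprintf("%s=%.3f", x$groups, x$leading_fractions),
            collapse = ", "), "\n")
  if (any(x$reversed))
    cat("  sign reversal vs", x$groups[1L], "in:",
        paste(x$groups[x$reversed], collapse = ", "), "\n")
  invisible(x)
}

#' Bootstrap confidence interval for the leading fraction
#'
#' Stability extension for the small per-group sample sizes (n of 7-9):
#' resamples samples (columns) with replacement and recomputes the leading
#' fraction of the uncentered Gram spectrum.
#'
#' @param X numeric panel matrix (genes x samples), log10 scale.
#' @param n_boot number of bootstrap replicates.
#' @param level confidence level.
#' @param seed integer seed.
#' @return list with `estimate`, `lower`, `upper`, `replicates`.
#' @export
bootstrap_leading_fraction <- function(X, n_boot = 1000L, level = 0.95,
                                       seed = 1L) {
  est <- leading_fraction(eigendecompose(gram_matrix(X)))
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(ncol(X), replace = TRUE)
      leading_fraction(eigendecompose(gram_matrix(X[, idx, drop = FALSE])))
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE)
  list(estimate = est, lower = ci[1L], upper = ci[2L], replicates = reps)
}
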