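# Gene-wise two-sample testing and up/down classification.

#' Two-sample t test
#'
#' Thin wrapper around [stats::t.test()] with explicit handling of the
#' degenerate zero-variance cases. Two-sided; the statistic is oriented as
#' `mean(x) - mean(y)`, so swapping the arguments negates `t` and leaves `p`
#' unchanged.
#'
#' @param x,y numeric vectors, length >= 2 each.
#' @param variant `"welch"` (unequal variances, the default — the safe
#'   choice at group sizes of 7-9) or `"student"` (pooled variance).
#' @return list with `t` and `p`.
#' @export
two_sample_ttest <- function(x, y, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  if (length(x) < 2L || length(y) < 2L)
    stopf("each group needs at least 2 observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stopf("non-finite observations")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, p = 1))
    warnf("zero variance in both groups with unequal means; p reported as 0")
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0))
  }
  tt <- stats::t.test(x, y, var.equal = (variant == "student"),
                      alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Screen genes for differential expression
#'
#' Gene-wise independent t tests between a case and a control matrix, with
#' up/down calls at a raw significance threshold (strict inequality
#' `p < alpha`). No multiple-testing correction is applied by default,
#' mirroring the original raw-threshold screen; `adjust = "BH"` is available
#' as an extension.
#'
#' @param case,control [expr_matrix()] objects over the same gene set.
#' @param alpha significance threshold in (0, 1); default 0.05.
#' @param variant t-test variant, see [two_sample_ttest()].
#' @param adjust `"none"` (default) or `"BH"` (Benjamini-Hochberg; calls are
#'   then made on adjusted p values).
#' @return data.frame with one row per gene: `gene_id`, `t`, `p`,
#'   `direction` (`up`/`down`/`unchanged`; up means case mean above control
#'   mean), `mean_case`, `mean_control`. Counts of up/down calls are
#'   attached as attribute `"counts"`.
#' @export
screen_genes <- function(case, control, alpha = 0.05,
                         variant = c("welch", "student"),
                         adjust = c("none", "BH")) {
  variant <- match.arg(variant)
  adjust <- match.arg(adjust)
  stopifnot(inherits(case, "expr_matrix"), inherits(control, "expr_matrix"))
  if (!is_scalar_number(alpha) || alpha < 0 || alpha >= 1)
    stopf("`alpha` must be in [0, 1)")
  if (!setequal(gene_ids(case), gene_ids(control)))
    stopf("case and control matrices cover different gene sets")
  genes <- gene_ids(case)
  ctrl <- control$values[match(genes, gene_ids(control)), , drop = FALSE]
  n <- length(genes)
  t_stat <- p_val <- mc <- mn <- numeric(n)
  for (i in seq_len(n)) {
    r <- two_sample_ttest(case$values[i, ], ctrl[i, ], variant = variant)
    t_stat[i] <- r$t; p_val[i] <- r$p
    mc[i] <- mean(case$values[i, ]); mn[i] <- mean(ctrl[i, ])
  }
  p_call <- if (adjust == "BH") stats::p.adjust(p_val, "BH") else p_val
  direction <- ifelse(p_call < alpha & mc > mn, "up",
               ifelse(p_call < alpha & mc < mn, "down", "unchanged"))
  out <- data.frame(gene_id = genes, t = t_stat, p = p_val,
                    direction = factor(direction,
                                       levels = c("up", "down", "unchanged")),
                    mean_case = mc, mean_control = mn,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- c(n_up = sum(direction == "up"),
                           n_down = sum(direction == "down"))
  out
}
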