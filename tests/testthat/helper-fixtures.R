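# Shared fixture builders and independent oracles used across test files.

# A small raw expression matrix with named genes/samples.
make_expr <- function(values, genes = NULL, samples = NULL, scale = "raw") {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(values)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expr_matrix(values, scale = scale)
}

# Welch / Student t computed directly from the textbook formulas,
# independent of stats::t.test.
oracle_ttest <- function(x, y, variant = "welch") {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  if (variant == "welch") {
    se2 <- vx / nx + vy / ny
    t <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  }
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

# Pearson r from the raw definition (no stats::cor).
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# AUC as the normalized Mann-Whitney U statistic (midranks handle ties).
oracle_auc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  u <- sum(rank(c(pos, neg))[seq_along(pos)]) -
    length(pos) * (length(pos) + 1) / 2
  u / (length(pos) * length(neg))
}

# Metadata frame shaped like the 9/7/8/7 severity cohort.
make_severity_metadata <- function(sizes = c(control = 9, incipient = 7,
                                             moderate = 8, severe = 7),
                                   ids = NULL) {
  n <- sum(sizes)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_len(n))
  data.frame(sample_id = ids,
             group = rep(names(sizes), times = sizes),
             stringsAsFactors = FALSE)
}
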