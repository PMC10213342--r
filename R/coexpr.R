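# Simplified weighted co-expression module stage: Spearman correlation,
# soft-threshold adjacency, scale-free fit across candidate powers,
# average-linkage module detection with eigengene merging, and module-trait
# correlation.
#
# This is deliberately NOT a faithful port of the WGCNA package. Clustering
# runs on 1 - adjacency (not topological overlap) and the dynamic tree cut
# is replaced by a static cut plus a minimum-size filter, a within-module
# coherence floor, and iterative eigengene merging. These deviations are
# documented in the methods vignette.

#' Spearman correlation matrix between genes
#'
#' @param X an [expr_matrix()] or numeric genes x samples matrix with at
#'   least 3 samples. Ties are handled by average ranks. Constant genes get
#'   correlation 0 (with a warning) rather than NA.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(X) {
  if (inherits(X, "expr_matrix")) X <- X$values
  if (ncol(X) < 3L) stopf("need at least 3 samples")
  if (!all(is.finite(X))) stopf("non-finite expression values")
  const <- apply(X, 1L, function(r) max(r) == min(r))
  rho <- suppressWarnings(stats::cor(t(X), method = "spearman"))
  if (any(const)) {
    warnf("%d constant gene(s); their correlations set to 0", sum(const))
    rho[const, ] <- 0
    rho[, const] <- 0
  }
  diag(rho) <- 1
  rho
}

#' Soft-threshold adjacency
#'
#' Raises the absolute correlation to an integer power beta:
#' `a_ij = |corr_ij|^beta`. The published formula omits the absolute value,
#' but at the even default beta = 8 the two agree exactly; the unsigned form
#' is used so odd powers stay in \[0, 1\].
#'
#' @param corr correlation matrix.
#' @param beta integer soft power >= 1 (default 8).
#' @return adjacency matrix in \[0, 1\] with unit diagonal; `beta` attached
#'   as an attribute.
#' @export
soft_adjacency <- function(corr, beta = 8L) {
  if (!is_scalar_number(beta) || beta < 1) stopf("`beta` must be >= 1")
  if (max(abs(corr)) > 1 + 1e-8) stopf("`corr` is not a correlation matrix")
  a <- abs(corr)^beta
  diag(a) <- 1
  attr(a, "beta") <- as.integer(beta)
  a
}

#' Scale-free topology fit across candidate soft powers
#'
#' For each candidate beta, computes the connectivity of every gene
#' (row sum of the adjacency minus the diagonal), bins connectivities, and
#' regresses log10 frequency on log10 mean connectivity per bin. The fit
#' index is the signed R-squared (negated when the slope is positive, since
#' a scale-free degree distribution has a negative log-log slope). The
#' chosen power is the smallest candidate whose fit reaches `rsq_cut`.
#'
#' @param corr correlation matrix.
#' @param betas integer candidate powers.
#' @param rsq_cut fit threshold (default 0.8).
#' @param n_bins connectivity bins (default 10).
#' @return list with `beta` (NA with a warning if no candidate reaches the
#'   threshold) and `fit_table` (data.frame: beta, fit_rsq, slope,
#'   mean_connectivity).
#' @export
pick_soft_power <- function(corr, betas = c(1:10, 12L, 14L, 16L, 18L, 20L),
                            rsq_cut = 0.8, n_bins = 10L) {
  if (any(betas < 1)) stopf("candidate powers must be >= 1")
  rows <- lapply(betas, function(b) {
    a <- soft_adjacency(corr, b)
    k <- rowSums(a) - 1
    data.frame(beta = b, fit_rsq = scale_free_fit(k, n_bins),
               slope = attr(scale_free_fit(k, n_bins), "slope"),
               mean_connectivity = mean(k))
  })
  tab <- do.call(rbind, rows)
  ok <- which(tab$fit_rsq >= rsq_cut)
  beta <- if (length(ok)) tab$beta[ok[1L]] else NA_integer_
  if (is.na(beta))
    warnf("no candidate power reaches scale-free fit %.2f (best %.2f)",
          rsq_cut, max(tab$fit_rsq))
  list(beta = beta, fit_table = tab)
}

# Signed scale-free fit R^2 for a connectivity vector.
scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(unique(k)) < 3L) {
    out <- 0
    attr(out, "slope") <- NA_real_
    return(out)
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  kmean <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3L) {
    out <- 0
    attr(out, "slope") <- NA_real_
    return(out)
  }
  fit <- stats::lm(log10(freq[keep]) ~ log10(kmean[keep]))
  slope <- unname(stats::coef(fit)[2L])
  r2 <- summary(fit)$r.squared
  out <- -sign(slope) * r2
  attr(out, "slope") <- slope
  out
}

#' Module eigengene
#'
#' The per-sample first right singular vector of the gene-standardized
#' module submatrix — one representative expression value per sample. The
#' sign is fixed so the eigengene correlates positively with the module's
#' mean standardized expression profile.
#'
#' @param Xm numeric genes x samples submatrix with >= 2 genes.
#' @return numeric vector, one value per sample (unit norm).
#' @export
module_eigengene <- function(Xm) {
  if (inherits(Xm, "expr_matrix")) Xm <- Xm$values
  if (nrow(Xm) < 2L) stopf("a module needs at least 2 genes")
  sds <- apply(Xm, 1L, stats::sd)
  if (all(sds == 0)) stopf("constant module submatrix")
  if (any(sds == 0)) {
    warnf("dropping %d constant gene(s) from the eigengene computation",
          sum(sds == 0))
    Xm <- Xm[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
    if (nrow(Xm) < 2L) stopf("fewer than 2 varying genes in module")
  }
  Z <- (Xm - rowMeans(Xm)) / sds
  v <- svd(Z, nu = 0L, nv = 1L)$v[, 1L]
  ref <- colMeans(Z)
  s <- sum(v * ref)
  if (s < 0) v <- -v else if (s == 0 && v[which.max(abs(v))] < 0) v <- -v
  v
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering on the distance `1 - adjacency`,
#' cut statically at `cut_height` (default 0.995: at the default soft power
#' the distances of structureless gene pairs pile up within 1e-4 of 1, well
#' above the cut, while coherently co-expressed blocks finish merging far
#' below it). Clusters below `min_size`, and clusters whose mean within-
#' cluster adjacency falls below `min_coherence` (a guard that sends
#' structureless noise clusters to the sink, standing in for the dynamic
#' tree cut's coherence behaviour), are assigned to the sink module
#' `"unassigned"`. When the expression matrix is supplied, modules whose
#' eigengenes correlate above `1 - merge_cut` are then merged iteratively
#' until stable. Final labels are `module_1`, `module_2`, ... in decreasing
#' size order.
#'
#' @param a adjacency matrix from [soft_adjacency()].
#' @param expr optional genes x samples matrix (or [expr_matrix()]) used for
#'   eigengene merging; without it the merge step is skipped.
#' @param min_size minimum module size (default 30).
#' @param merge_cut eigengene merge cut height in (0, 1) (default 0.25:
#'   modules with eigengene correlation above 0.75 merge).
#' @param cut_height static tree cut height (default 0.995).
#' @param min_coherence minimum mean within-cluster adjacency (default 0.01).
#' @return object of class `module_assignment`: data.frame `gene_id`,
#'   `module`; sizes as attribute `"sizes"`.
#' @export
detect_modules <- function(a, expr = NULL, min_size = 30L, merge_cut = 0.25,
                           cut_height = 0.995, min_coherence = 0.01) {
  if (min_size < 2L) stopf("`min_size` must be >= 2")
  if (merge_cut <= 0 || merge_cut >= 1) stopf("`merge_cut` must be in (0, 1)")
  if (inherits(expr, "expr_matrix")) expr <- expr$values
  genes <- rownames(a)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(a)))
  if (nrow(a) < min_size) {
    warnf("fewer genes (%d) than `min_size`; all genes unassigned", nrow(a))
    return(new_module_assignment(genes, rep("unassigned", nrow(a))))
  }
  h <- stats::hclust(stats::as.dist(1 - a), method = "average")
  cl <- stats::cutree(h, h = cut_height)
  # size + coherence filter
  lab <- rep("unassigned", length(cl))
  for (cid in unique(cl)) {
    idx <- which(cl == cid)
    if (length(idx) < min_size) next
    sub <- a[idx, idx, drop = FALSE]
    coh <- (sum(sub) - length(idx)) / (length(idx)^2 - length(idx))
    if (coh < min_coherence) next
    lab[idx] <- paste0("pre_", cid)
  }
  # eigengene merging
  if (!is.null(expr)) {
    repeat {
      mods <- setdiff(unique(lab), "unassigned")
      if (length(mods) < 2L) break
      eg <- vapply(mods, function(m)
        module_eigengene(expr[lab == m, , drop = FALSE]),
        numeric(ncol(expr)))
      cc <- stats::cor(eg)
      diag(cc) <- -Inf
      top <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
      if (cc[top[1L], top[2L]] <= 1 - merge_cut) break
      lab[lab == mods[top[2L]]] <- mods[top[1L]]
    }
  }
  # deterministic final labels by decreasing size (ties by first gene index)
  mods <- setdiff(unique(lab), "unassigned")
  if (length(mods)) {
    sizes <- vapply(mods, function(m) sum(lab == m), integer(1))
    first <- vapply(mods, function(m) which(lab == m)[1L], integer(1))
    mods <- mods[order(-sizes, first)]
    final <- lab
    for (i in seq_along(mods))
      final[lab == mods[i]] <- paste0("module_", i)
    lab <- final
  }
  new_module_assignment(genes, lab)
}

new_module_assignment <- function(genes, modules) {
  out <- data.frame(gene_id = genes, module = modules,
                    stringsAsFactors = FALSE)
  sizes <- sort(table(modules), decreasing = TRUE)
  structure(out, sizes = sizes, class = c("module_assignment", "data.frame"))
}

#' @export
print.module_assignment <- function(x, ...) {
  s <- attr(x, "sizes")
  cat(sprintf("<module_assignment> %d genes, %d module(s): %s\n",
              nrow(x), sum(names(s) != "unassigned"),
              paste(sprintf("%s=%d", names(s), s), collapse = ", ")))
  invisible(x)
}

#' Eigengenes for every detected module
#'
#' @param assignment a [detect_modules()] result.
#' @param expr genes x samples matrix (or [expr_matrix()]) covering the
#'   assignment's genes.
#' @return samples x modules numeric matrix (sink excluded).
#' @export
module_eigengenes <- function(assignment, expr) {
  if (inherits(expr, "expr_matrix")) expr <- expr$values
  mods <- setdiff(unique(assignment$module), "unassigned")
  if (!length(mods)) stopf("no modules to summarize")
  eg <- vapply(mods, function(m) {
    idx <- match(assignment$gene_id[assignment$module == m], rownames(expr))
    module_eigengene(expr[idx, , drop = FALSE])
  }, numeric(ncol(expr)))
  rownames(eg) <- colnames(expr)
  eg
}

#' Module-trait correlation
#'
#' Pearson correlation (with two-sided p values) between module eigengenes
#' and numerically coded clinical traits, the standard module-trait
#' relationship summary. Constant traits get correlation 0 and p 1 with a
#' warning.
#'
#' @param eigengenes samples x modules matrix from [module_eigengenes()].
#' @param traits samples x traits numeric data.frame or matrix (group coded
#'   1-4, sex 0/1, Braak as ordinal integers).
#' @return object of class `module_trait`: list with matrices `cor` and `p`
#'   (modules x traits).
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  traits <- as.matrix(traits)
  if (!is.numeric(traits)) stopf("traits must be numerically coded")
  if (nrow(traits) != nrow(eigengenes))
    stopf("eigengenes and traits cover different sample counts")
  mods <- colnames(eigengenes)
  trs <- colnames(traits)
  cm <- pm <- matrix(NA_real_, length(mods), length(trs),
                     dimnames = list(mods, trs))
  const_tr <- vapply(seq_along(trs), function(j) {
    y <- traits[, j]
    stats::sd(y[is.finite(y)]) == 0
  }, logical(1))
  for (j in which(const_tr))
    warnf("constant trait %s; correlation set to 0", trs[j])
  for (i in seq_along(mods)) for (j in seq_along(trs)) {
    x <- eigengenes[, i]; y <- traits[, j]
    ok <- is.finite(x) & is.finite(y)
    if (const_tr[j]) {
      cm[i, j] <- 0; pm[i, j] <- 1
    } else {
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      cm[i, j] <- unname(ct$estimate); pm[i, j] <- ct$p.value
    }
  }
  structure(list(cor = cm, p = pm), class = "module_trait")
}
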