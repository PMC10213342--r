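# Log transformation and severity-group partition of the expression matrix.

#' Log-transform raw expression values
#'
#' Applies `x = log10(g + 1)` elementwise. This is the only normalization in
#' the pipeline: it compresses the dynamic range of microarray intensities
#' so samples become comparable. The transform refuses to run twice; the
#' scale flag is the sole authority on whether a matrix is already logged
#' (no value heuristics).
#'
#' @param m an [expr_matrix()] with `scale = "raw"`.
#' @return an [expr_matrix()] with `scale = "log10"`.
#' @export
log_transform <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "raw")
    stopf("matrix is already on the log10 scale; refusing to transform again")
  if (any(m$values < 0)) {
    bad <- which(m$values < 0, arr.ind = TRUE)[1L, ]
    stopf("negative raw value at row %s, column %s",
          rownames(m$values)[bad[1L]], colnames(m$values)[bad[2L]])
  }
  expr_matrix(log10(m$values + 1), scale = "log10")
}

#' Partition an expression matrix by severity group
#'
#' Splits columns by the metadata's group assignment. Column order within
#' each group preserves the original sample order of the matrix, so the
#' partition is invariant to metadata row order.
#'
#' @param m an [expr_matrix()].
#' @param meta metadata data.frame (columns `sample_id`, `group`).
#' @return named list of [expr_matrix()] objects, one per group present, in
#'   severity order; group sizes attached as attribute `"sizes"`.
#' @export
partition_by_group <- function(m, meta) {
  stopifnot(inherits(m, "expr_matrix"))
  missing_samples <- setdiff(sample_ids(m), meta$sample_id)
  if (length(missing_samples))
    stopf("sample(s) absent from metadata: %s",
          paste(missing_samples, collapse = ", "))
  grp <- as.character(meta$group[match(sample_ids(m), meta$sample_id)])
  present <- unique(grp)
  present <- c(intersect(.group_levels, present),
               setdiff(present, .group_levels))
  out <- list()
  for (g in present) {
    cols <- sample_ids(m)[which(grp == g)]
    if (!length(cols)) stopf("group %s has zero samples", g)
    out[[g]] <- expr_matrix(m$values[, cols, drop = FALSE], scale = m$scale)
  }
  meta_groups <- unique(as.character(meta$group))
  empty <- setdiff(meta_groups, present)
  if (length(empty)) stopf("group %s has zero samples", empty[1L])
  attr(out, "sizes") <- vapply(out, function(x) ncol(x$values), integer(1))
  out
}

#' Extract the gene-panel submatrix
#'
#' Returns the panel rows, in panel order, as a plain numeric matrix
#' (genes x samples).
#'
#' @param m an [expr_matrix()] whose rownames are gene symbols.
#' @param panel a [gene_panel()].
#' @return numeric matrix with `length(panel$symbols)` rows.
#' @export
extract_panel <- function(m, panel = gene_panel()) {
  stopifnot(inherits(m, "expr_matrix"))
  ids <- canonicalize_symbols(gene_ids(m), panel)
  idx <- match(panel$symbols, ids)
  if (anyNA(idx))
    stopf("panel symbol(s) missing from matrix: %s",
          paste(panel$symbols[is.na(idx)], collapse = ", "))
  sub <- m$values[idx, , drop = FALSE]
  rownames(sub) <- panel$symbols
  sub
}

#' Build per-group panel matrices
#'
#' Convenience wrapper running the standard preprocessing path: log
#' transform (if raw), metadata join, severity partition and panel
#' extraction. The result holds one 4 x n log10 matrix per group.
#'
#' @param m an [expr_matrix()] (raw or log10).
#' @param meta metadata data.frame.
#' @param panel a [gene_panel()].
#' @return object of class `grouped_panel`: list with `panel`, `groups`
#'   (named list of panel matrices) and `sizes`.
#' @export
grouped_panel <- function(m, meta, panel = gene_panel()) {
  if (m$scale == "raw") m <- log_transform(m)
  joined <- join_metadata(m, meta)
  parts <- partition_by_group(joined$expression, joined$metadata)
  groups <- lapply(parts, extract_panel, panel = panel)
  structure(list(panel = panel, groups = groups,
                 sizes = vapply(groups, ncol, integer(1))),
            class = "grouped_panel")
}

#' @export
print.grouped_panel <- function(x, ...) {
  cat(sprintf("<grouped_panel> %d genes (%s); groups: %s\n",
              length(x$panel$symbols),
              paste(x$panel$symbols, collapse = ", "),
              paste(sprintf("%s=%d", names(x$sizes), x$sizes), collapse = ", ")))
  invisible(x)
}
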