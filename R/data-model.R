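# Domain types and I/O for expression data: the expression matrix container,
# sample metadata with the severity-group coding, the four-gene panel
# definition, readers for plain TSV and GEO series-matrix layouts, and
# probe-to-symbol collapsing.

#' Construct an expression matrix
#'
#' A genes x samples numeric matrix together with a scale flag. Raw
#' intensities (`scale = "raw"`) must be nonnegative; `scale = "log10"`
#' marks values already transformed by `x = log10(g + 1)`.
#'
#' @param values numeric matrix with unique rownames (gene or probe IDs) and
#'   unique colnames (sample IDs).
#' @param scale `"raw"` or `"log10"`.
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, scale = c("raw", "log10")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stopf("expression matrix is empty (%d genes x %d samples)",
          nrow(values), ncol(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("`values` must carry gene rownames and sample colnames")
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stopf("duplicate gene IDs: %s", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stopf("duplicate sample IDs: %s", paste(dup_s, collapse = ", "))
  if (anyNA(values))
    stopf("missing values are not permitted in an expression matrix")
  if (scale == "raw" && any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stopf("raw expression must be nonnegative; first offender at row %s, column %s",
          rownames(values)[bad[1L]], colnames(values)[bad[2L]])
  }
  structure(list(values = values, scale = scale), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, scale = %s\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

gene_ids <- function(m) rownames(m$values)
sample_ids <- function(m) colnames(m$values)

#' Read an expression table
#'
#' Supports two layouts: `plain_tsv` (header row of sample IDs, first column
#' gene IDs) and `geo_series_matrix` (the table between
#' `!series_matrix_table_begin` / `!series_matrix_table_end` markers of a GEO
#' series-matrix file; all other `!` lines are ignored).
#'
#' @param path file path.
#' @param dialect `"plain_tsv"` or `"geo_series_matrix"`.
#' @param scale scale flag to attach: `"raw"` (default) for intensity
#'   tables, `"log10"` when the file stores already-transformed values.
#' @return an [expr_matrix()].
#' @export
read_expression <- function(path, dialect = c("plain_tsv", "geo_series_matrix"),
                            scale = c("raw", "log10")) {
  dialect <- match.arg(dialect)
  scale <- match.arg(scale)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (dialect == "plain_tsv") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
      stopf("no series-matrix table found in %s", path)
    body <- lines[(beg + 1L):(end - 1L)]
    df <- utils::read.delim(text = body, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    # series-matrix cells are commonly quoted
    df[[1L]] <- gsub('^"|"$', "", df[[1L]])
  }
  if (ncol(df) < 2L) stopf("expression table in %s has no sample columns", path)
  ids <- as.character(df[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stopf("duplicate gene IDs in %s: %s", path, paste(dup, collapse = ", "))
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(col) & !is.na(vals[[j]]) & vals[[j]] != "NA")
    if (length(bad))
      stopf("non-numeric cell at row %s (gene %s), column %s",
            bad[1L], ids[bad[1L]], colnames(vals)[j])
    vals[[j]] <- col
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  expr_matrix(m, scale = scale)
}

#' Write an expression matrix as TSV
#'
#' Layout mirrors the `plain_tsv` input dialect: first column `gene_id`,
#' remaining columns one per sample. Round-trips numeric values exactly for
#' finite decimal inputs (full double precision is written).
#'
#' @param m an [expr_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  stopifnot(inherits(m, "expr_matrix"))
  df <- data.frame(gene_id = gene_ids(m),
                   format(m$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", sample_ids(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Canonical severity-group coding. Lower-case keys; "incipient ad" tolerated.
.group_levels <- c("control", "incipient", "moderate", "severe")
.group_codes <- c(control = 1L, incipient = 2L, `incipient ad` = 2L,
                  moderate = 3L, severe = 4L)

#' Encode severity-group labels
#'
#' Maps group labels (case-insensitively) to the numeric severity coding
#' control = 1, incipient = 2, moderate = 3, severe = 4.
#'
#' @param group character vector of group labels.
#' @return integer vector of codes.
#' @export
encode_group <- function(group) {
  key <- tolower(trimws(as.character(group)))
  unknown <- setdiff(unique(key), names(.group_codes))
  if (length(unknown))
    stopf("unknown group label(s) %s; allowed: %s",
          paste(sQuote(unknown), collapse = ", "),
          paste(.group_levels, collapse = ", "))
  unname(.group_codes[key])
}

#' Read a sample-metadata table
#'
#' Expects a TSV with at least `sample_id` and `group` columns; `mmse`,
#' `nft`, `braak`, `age`, `sex`, `pmi` are carried through when present.
#' Group labels are mapped case-insensitively to the 1-4 severity coding.
#'
#' @param path file path.
#' @return a data.frame with columns `sample_id`, `group` (factor over the
#'   four severity levels), `group_code` (integer 1-4) and any optional
#'   clinical columns found.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("sample_id", "group")
  miss <- setdiff(req, colnames(df))
  if (length(miss))
    stopf("metadata is missing required column(s): %s",
          paste(miss, collapse = ", "))
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    stopf("duplicate sample IDs in metadata: %s", paste(dup, collapse = ", "))
  code <- encode_group(df$group)
  df$group <- factor(.group_levels[code], levels = .group_levels)
  df$group_code <- code
  if ("mmse" %in% colnames(df)) {
    mmse <- suppressWarnings(as.numeric(df$mmse))
    bad <- which(!is.na(mmse) & (mmse < 0 | mmse > 30))
    if (length(bad))
      stopf("MMSE out of range [0, 30] for sample(s): %s",
            paste(df$sample_id[bad], collapse = ", "))
    df$mmse <- mmse
  }
  df
}

#' Define a gene panel
#'
#' The default panel is the four-gene chaperone network BAG2, HSC70 (gene
#' symbol HSPA8), STUB1 and MAPT, in that fixed order. The order is recorded
#' in all downstream outputs: eigenvector components, extracted submatrices
#' and feature sums are always reported in panel order.
#'
#' @param symbols ordered character vector of panel gene symbols.
#' @param aliases named character vector mapping alternative symbols to panel
#'   symbols (default maps HSPA8 to HSC70).
#' @return an object of class `gene_panel`.
#' @export
gene_panel <- function(symbols = c("BAG2", "HSC70", "STUB1", "MAPT"),
                       aliases = c(HSPA8 = "HSC70")) {
  symbols <- as.character(symbols)
  if (anyDuplicated(symbols)) stopf("panel symbols must be unique")
  structure(list(symbols = symbols, aliases = aliases), class = "gene_panel")
}

# Replace alias symbols with their canonical panel symbol.
canonicalize_symbols <- function(symbols, panel) {
  hit <- symbols %in% names(panel$aliases)
  symbols[hit] <- unname(panel$aliases[symbols[hit]])
  symbols
}

#' Collapse probes to gene symbols
#'
#' Microarray platforms measure several probe sets per gene; this collapses
#' an expression matrix with probe rownames to one row per symbol.
#'
#' Policies: `max_mean` keeps the probe with the largest mean expression
#' (a common collapsing convention); `listed_probe` keeps an explicitly
#' pinned probe per symbol (via `probes`); `mean_collapse` averages all
#' probes of a symbol.
#'
#' @param m an [expr_matrix()] with probe rownames.
#' @param mapping data.frame with columns `probe` and `symbol`.
#' @param policy collapsing policy.
#' @param probes named character vector `symbol -> probe` (required for
#'   `listed_probe`).
#' @param panel optional [gene_panel()] whose aliases are applied to the
#'   mapping's symbols.
#' @return an [expr_matrix()] with symbol rownames; the chosen probes are
#'   attached as attribute `"probe_provenance"`.
#' @export
map_probes_to_genes <- function(m, mapping,
                                policy = c("max_mean", "listed_probe",
                                           "mean_collapse"),
                                probes = NULL, panel = gene_panel()) {
  policy <- match.arg(policy)
  stopifnot(inherits(m, "expr_matrix"))
  if (!all(c("probe", "symbol") %in% colnames(mapping)))
    stopf("`mapping` needs columns `probe` and `symbol`")
  mapping$symbol <- canonicalize_symbols(as.character(mapping$symbol), panel)
  mapping <- mapping[mapping$probe %in% gene_ids(m), , drop = FALSE]
  symbols <- unique(mapping$symbol)
  if (!length(symbols)) stopf("no mapped probes present in the matrix")
  rows <- matrix(NA_real_, length(symbols), ncol(m$values),
                 dimnames = list(symbols, sample_ids(m)))
  chosen <- character(length(symbols))
  names(chosen) <- symbols
  for (s in symbols) {
    pr <- mapping$probe[mapping$symbol == s]
    if (!length(pr)) stopf("symbol %s has zero mapped probes in the matrix", s)
    sub <- m$values[pr, , drop = FALSE]
    if (policy == "max_mean") {
      pick <- pr[which.max(rowMeans(sub))]
      rows[s, ] <- m$values[pick, ]
      chosen[s] <- pick
    } else if (policy == "listed_probe") {
      if (is.null(probes) || is.na(probes[s]) || !nzchar(probes[s]))
        stopf("policy `listed_probe` requires a pinned probe for symbol %s", s)
      if (!probes[s] %in% pr)
        stopf("pinned probe %s is not mapped to symbol %s", probes[s], s)
      rows[s, ] <- m$values[probes[s], ]
      chosen[s] <- probes[s]
    } else {
      rows[s, ] <- colMeans(sub)
      chosen[s] <- paste(pr, collapse = "+")
    }
  }
  out <- expr_matrix(rows, scale = m$scale)
  attr(out, "probe_provenance") <- chosen
  out
}

#' Join metadata to an expression matrix
#'
#' Inner join on sample IDs, preserving the column order of the expression
#' matrix. Metadata rows without a matching sample (and vice versa) are
#' dropped with a warning reporting the counts.
#'
#' @param m an [expr_matrix()].
#' @param meta metadata data.frame as returned by [read_metadata()].
#' @return list with the subset `expression` and row-aligned `metadata`.
#' @export
join_metadata <- function(m, meta) {
  stopifnot(inherits(m, "expr_matrix"))
  shared <- intersect(sample_ids(m), meta$sample_id)
  drop_m <- setdiff(sample_ids(m), shared)
  drop_meta <- setdiff(meta$sample_id, shared)
  if (length(drop_m) || length(drop_meta))
    warnf("join dropped %d expression sample(s) and %d metadata row(s)",
          length(drop_m), length(drop_meta))
  if (!length(shared)) stopf("no samples shared between expression and metadata")
  keep <- sample_ids(m)[sample_ids(m) %in% shared]
  list(expression = expr_matrix(m$values[, keep, drop = FALSE], scale = m$scale),
       metadata = meta[match(keep, meta$sample_id), , drop = FALSE])
}
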