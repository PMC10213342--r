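# Synthetic-data generators. Every statistical structure the analysis
# assumes is planted here with a known truth, so all pipeline stages are
# testable without downloading any study data. All generators are pure
# functions of their seed.

# Orthonormal basis whose first column is `first` (unit-normalized).
orthonormal_with <- function(first, n) {
  first <- first / sqrt(sum(first^2))
  Q <- qr.Q(qr(cbind(first, matrix(stats::rnorm(n * (n - 1L)), n))))
  Q[, 1L] <- first
  Q
}

# A near-uniform strictly positive unit vector.
positive_direction <- function(n, jitter = 0.3) {
  v <- 1 + stats::runif(n, 0, jitter)
  v / sqrt(sum(v^2))
}

#' Configuration for the planted-spectrum panel generator
#'
#' Defaults mirror the study conditions: four panel genes over severity
#' groups of sizes 9/7/8/7 with leading eigenvalue fractions drifting
#' slightly over the first three stages and jumping in the severe stage
#' (0.56, 0.58, 0.60, 0.79); the remaining spectrum mass is split 50/30/20
#' across the trailing eigenvalues. Leading directions default to a shared
#' positive direction (no planted reversal).
#'
#' @param spectra named list of length-4 nonincreasing nonnegative fraction
#'   vectors summing to 1, one per group; or `NULL` for the defaults.
#' @param directions named list of unit 4-vectors (leading gene-space
#'   direction per group; a sign flip plants a reversal), or `NULL` to draw
#'   one shared positive direction.
#' @param sizes group sizes (default `c(9, 7, 8, 7)`).
#' @param noise elementwise Gaussian noise SD added to the log-scale matrix
#'   (default 0.02; the planted matrices have unit total Gram trace).
#' @param seed integer seed.
#' @return list of class `panel_sim_config`.
#' @export
panel_sim_config <- function(spectra = NULL, directions = NULL,
                             sizes = c(control = 9L, incipient = 7L,
                                       moderate = 8L, severe = 7L),
                             noise = 0.02, seed = 1L) {
  if (is.null(names(sizes)))
    names(sizes) <- .group_levels[seq_along(sizes)]
  if (is.null(spectra)) {
    lead <- c(0.56, 0.58, 0.60, 0.79)[seq_along(sizes)]
    spectra <- lapply(lead, function(f1) c(f1, (1 - f1) * c(0.5, 0.3, 0.2)))
    names(spectra) <- names(sizes)
  }
  for (g in names(spectra)) {
    fr <- spectra[[g]]
    if (abs(sum(fr) - 1) > 1e-9 || any(fr < 0) || is.unsorted(rev(fr)))
      stopf("spectrum for group %s must be nonincreasing, nonnegative, sum 1", g)
  }
  structure(list(spectra = spectra, directions = directions, sizes = sizes,
                 noise = noise, seed = seed),
            class = "panel_sim_config")
}

#' Simulate a gene panel with planted Gram spectra
#'
#' For each group, builds `X = sum_k sqrt(mu_k) q_k w_k'` + noise, where the
#' `q_k` are orthonormal gene-space directions (the first being the planted
#' leading direction), the `w_k` orthonormal sample-space vectors (the first
#' strictly positive, so the mean expression profile carries the leading
#' direction's sign), and `mu_k` proportional to the target fractions with
#' unit total trace. At zero noise the uncentered Gram spectrum of `X`
#' equals the target exactly.
#'
#' Spectra are planted in the uncentered Gram sense — the planted leading
#' direction includes the mean component, matching the coordination
#' statistic's definition.
#'
#' In `"raw"` mode the log-scale matrix is back-transformed through
#' `g = 10^x - 1` so the pipeline's log step round-trips exactly; this
#' requires an entrywise-nonnegative `x`, which the generator attains by
#' re-drawing the orthonormal complements (an additive shift would alter
#' the spectrum). Raw mode therefore needs a positive leading direction and
#' a reasonably concentrated spectrum, and errors when the requested
#' spectrum cannot be realized nonnegatively.
#'
#' @param config a [panel_sim_config()].
#' @param mode `"log"` (default; returns the log10-scale matrix, exact
#'   planting) or `"raw"`.
#' @param max_tries rejection draws per group in raw mode.
#' @return list with `expression` (an [expr_matrix()]), `metadata`
#'   (data.frame `sample_id`, `group`, `group_code`) and `truth` (the
#'   planted spectra and leading directions).
#' @export
simulate_panel <- function(config = panel_sim_config(),
                           mode = c("log", "raw"), max_tries = 2000L) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "panel_sim_config"))
  s <- 4L
  with_seed(config$seed, {
    directions <- config$directions
    if (is.null(directions)) {
      shared <- positive_direction(s)
      directions <- rep(list(shared), length(config$sizes))
      names(directions) <- names(config$sizes)
    }
    blocks <- list()
    truth_dir <- list()
    for (g in names(config$sizes)) {
      n <- config$sizes[[g]]
      if (n < s) stopf("group %s has %d samples; need >= %d for exact spectra",
                       g, n, s)
      mu <- config$spectra[[g]]  # unit total trace
      q1 <- directions[[g]]
      q1 <- q1 / sqrt(sum(q1^2))
      X <- NULL
      for (try in seq_len(max_tries)) {
        Q <- orthonormal_with(q1, s)
        W <- orthonormal_with(positive_direction(n), n)
        Xc <- matrix(0, s, n)
        for (k in seq_len(s)) Xc <- Xc + sqrt(mu[k]) * Q[, k] %*% t(W[, k])
        if (mode == "log" || min(Xc) >= 0) { X <- Xc; break }
      }
      if (is.null(X))
        stopf("group %s: could not realize the requested spectrum with nonnegative log values in %d tries",
              g, max_tries)
      if (config$noise > 0)
        X <- X + matrix(stats::rnorm(s * n, 0, config$noise), s, n)
      if (mode == "raw" && min(X) < 0)
        X[X < 0] <- 0  # clip rare noise-induced negatives
      blocks[[g]] <- X
      truth_dir[[g]] <- q1
    }
    panel <- gene_panel()
    vals <- do.call(cbind, blocks)
    rownames(vals) <- panel$symbols
    colnames(vals) <- sprintf("S%02d", seq_len(ncol(vals)))
    grp <- rep(names(config$sizes), times = config$sizes)
    canonical <- all(names(config$sizes) %in% .group_levels)
    meta <- data.frame(
      sample_id = colnames(vals),
      group = if (canonical) factor(grp, levels = .group_levels)
              else factor(grp, levels = names(config$sizes)),
      group_code = if (canonical) encode_group(grp)
                   else match(grp, names(config$sizes)),
      stringsAsFactors = FALSE)
    if (mode == "raw") vals <- 10^vals - 1
    list(expression = expr_matrix(vals,
                                  scale = if (mode == "raw") "raw" else "log10"),
         metadata = meta,
         truth = list(spectra = config$spectra, directions = truth_dir,
                      sizes = config$sizes))
  })
}

#' Simulate MMSE scores linearly tied to the panel
#'
#' `MMSE_i = clip(intercept + coeffs . x_i + N(0, noise_sd), 0, 30)`,
#' rounded to integers. With `coeffs = NULL` the coefficients are
#' calibrated deterministically from the supplied panel so the noiseless
#' linear predictor has mean 18 and SD 7 (a realistic MMSE spread across
#' a mixed-severity cohort) along the fixed direction (2, 1, 1, 1).
#'
#' @param panel an [expr_matrix()] on the log10 scale, 4 genes, or a 4 x n
#'   matrix.
#' @param coeffs length-4 coefficient vector or `NULL` (auto-calibrated).
#' @param intercept scalar intercept (ignored when auto-calibrating).
#' @param noise_sd Gaussian noise SD (default 1).
#' @param seed integer seed.
#' @return data.frame `sample_id`, `mmse` (integer in \[0, 30\]); the
#'   noiseless values and coefficients are attached as attribute `"truth"`.
#' @export
simulate_mmse <- function(panel, coeffs = NULL, intercept = 0, noise_sd = 1,
                          seed = 1L) {
  X <- if (inherits(panel, "expr_matrix")) panel$values else panel
  if (nrow(X) != 4L) stopf("panel must have 4 genes")
  lin0 <- drop(crossprod(X, c(2, 1, 1, 1) / sqrt(7)))
  if (is.null(coeffs)) {
    sd0 <- stats::sd(lin0)
    scale <- if (sd0 > 0) 7 / sd0 else 0
    coeffs <- scale * c(2, 1, 1, 1) / sqrt(7)
    intercept <- 18 - mean(scale * lin0)
  }
  linear <- drop(crossprod(X, coeffs)) + intercept
  mmse <- with_seed(seed, linear + stats::rnorm(ncol(X), 0, noise_sd))
  mmse <- as.integer(round(pmin(pmax(mmse, 0), 30)))
  ids <- colnames(X)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_len(ncol(X)))
  out <- data.frame(sample_id = ids, mmse = mmse, stringsAsFactors = FALSE)
  attr(out, "truth") <- list(coeffs = coeffs, intercept = intercept,
                             linear = linear, noise_sd = noise_sd)
  out
}

#' Simulate a two-class classification cohort
#'
#' Generates control and patient classes whose (sum, SD) feature
#' distributions are bivariate normal with a mean shift of `delta` standard
#' deviations along EACH feature axis (total Mahalanobis separation
#' `delta * sqrt(2)` for independent axes). Panel values are
#' back-constructed from the features along the fixed zero-mean unit-
#' variance pattern (1, -1, 1, -1), so running [extract_features()] on the
#' panel recovers the sampled features exactly (population SD convention).
#'
#' Default class sizes 180/181 mirror the external training cohort design.
#'
#' @param n_control,n_patient class sizes.
#' @param delta per-feature standardized class separation (>= 0).
#' @param mean_sum,mean_sd control-class feature means (log10 scale).
#' @param sd_sum,sd_sd feature standard deviations.
#' @param seed integer seed.
#' @return list with `expression` ([expr_matrix()], log10), `labels`
#'   (factor control/patient), `features` (data.frame) and `truth`.
#' @export
simulate_classification_cohort <- function(n_control = 180L,
                                           n_patient = 181L,
                                           delta = 1.5,
                                           mean_sum = 10, mean_sd = 0.5,
                                           sd_sum = 0.8, sd_sd = 0.12,
                                           seed = 1L) {
  if (delta < 0) stopf("`delta` must be >= 0")
  with_seed(seed, {
    n <- n_control + n_patient
    lab <- factor(rep(c("control", "patient"), c(n_control, n_patient)),
                  levels = c("control", "patient"))
    shift <- ifelse(lab == "patient", delta, 0)
    sum_f <- stats::rnorm(n, mean_sum + shift * sd_sum, sd_sum)
    sd_f <- stats::rnorm(n, mean_sd + shift * sd_sd, sd_sd)
    sd_f <- pmax(sd_f, 1e-3)  # a standard deviation cannot be negative
    pattern <- c(1, -1, 1, -1)  # zero mean, unit population SD
    vals <- t(outer(sum_f / 4, rep(1, 4)) + outer(sd_f, pattern))
    rownames(vals) <- gene_panel()$symbols
    colnames(vals) <- sprintf("C%03d", seq_len(n))
    features <- data.frame(sample_id = colnames(vals), sum_expr = sum_f,
                           sd_expr = sd_f, stringsAsFactors = FALSE)
    list(expression = expr_matrix(vals, scale = "log10"),
         labels = lab, features = features,
         truth = list(delta = delta, mahalanobis = delta * sqrt(2)))
  })
}

#' Simulate background genes organized into correlated modules
#'
#' Each module has a latent factor; member genes load on it with
#' `gene = sqrt(rho) * factor + sqrt(1 - rho) * noise` (pairwise
#' correlation `rho` at unit loadings). Independent noise genes are
#' appended. Supplying `factors` (for example a clinical group code) ties a
#' module's factor to a trait.
#'
#' @param k_modules number of modules (>= 1).
#' @param genes_per_module genes per module (default 40).
#' @param within_cor target within-module correlation `rho` (default 0.8).
#' @param n_noise independent noise genes (default 40).
#' @param n_samples samples (default 30).
#' @param loads per-gene loading multipliers (scalar or vector recycled per
#'   module; 0 makes a module pure noise).
#' @param factors optional n_samples x k_modules matrix of latent factors;
#'   `NULL` draws standard normal factors.
#' @param seed integer seed.
#' @return list with `expression` ([expr_matrix()], log10 scale),
#'   `truth` (gene -> module membership, factors).
#' @export
simulate_background_modules <- function(k_modules = 3L,
                                        genes_per_module = 40L,
                                        within_cor = 0.8, n_noise = 40L,
                                        n_samples = 30L, loads = 1,
                                        factors = NULL, seed = 1L) {
  if (k_modules < 1L) stopf("`k_modules` must be >= 1")
  with_seed(seed, {
    if (is.null(factors))
      factors <- matrix(stats::rnorm(n_samples * k_modules), n_samples)
    loads <- rep_len(loads, genes_per_module)
    rows <- list(); truth <- character(0)
    for (m in seq_len(k_modules)) {
      f <- factors[, m]
      block <- t(vapply(seq_len(genes_per_module), function(g) {
        loads[g] * (sqrt(within_cor) * f +
                      sqrt(1 - within_cor) * stats::rnorm(n_samples)) +
          (1 - abs(sign(loads[g]))) * stats::rnorm(n_samples)
      }, numeric(n_samples)))
      rows[[m]] <- block
      truth <- c(truth, rep(paste0("true_", m), genes_per_module))
    }
    if (n_noise > 0) {
      rows[[k_modules + 1L]] <-
        matrix(stats::rnorm(n_noise * n_samples), n_noise)
      truth <- c(truth, rep("noise", n_noise))
    }
    vals <- do.call(rbind, rows)
    rownames(vals) <- sprintf("gene_%03d", seq_len(nrow(vals)))
    colnames(vals) <- sprintf("S%02d", seq_len(n_samples))
    names(truth) <- rownames(vals)
    list(expression = expr_matrix(vals, scale = "log10"),
         truth = list(membership = truth, factors = factors,
                      within_cor = within_cor))
  })
}

#' Write a synthetic GEO-style series-matrix file
#'
#' Emits a minimal series-matrix dialect file (bang-prefixed header lines
#' plus the quoted table between the begin/end markers) for round-trip
#' testing of the reader. The file is synthetic and carries a comment line
#' saying so.
#'
#' @param m an [expr_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_series_matrix <- function(m, path) {
  stopifnot(inherits(m, "expr_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("!Series_title\t\"synthetic fixture\"",
               "!series_matrix_table_begin"), con)
  header <- paste(c("\"ID_REF\"", paste0('"', sample_ids(m), '"')),
                  collapse = "\t")
  writeLines(header, con)
  for (i in seq_len(nrow(m$values))) {
    writeLines(paste(c(paste0('"', gene_ids(m)[i], '"'),
                       format(m$values[i, ], digits = 17, trim = TRUE,
                              scientific = FALSE)),
                     collapse = "\t"), con)
  }
  writeLines("!series_matrix_table_end", con)
  invisible(path)
}
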