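# End-to-end orchestration: preprocess -> spectral -> differential
# expression -> modules -> MMSE network -> classifier, with one JSON report.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. Either supply file paths
#' (`expression_path`, `metadata_path`) or leave them `NULL` to run on
#' synthetic data generated from the stage-scoped seeds.
#'
#' @param expression_path,metadata_path input TSV paths, or `NULL` for
#'   synthetic inputs.
#' @param dialect expression file dialect, see [read_expression()].
#' @param panel a [gene_panel()].
#' @param alpha differential-expression threshold.
#' @param de_variant t-test variant.
#' @param beta,min_size,merge_cut co-expression stage settings.
#' @param nn NN settings (list: `lr`, `epochs`, `test_fraction`).
#' @param svm classifier settings (list: `sigma2`, `C`, `delta`).
#' @param seed base seed; stage seeds are derived from it.
#' @param out_dir output directory or `NULL` (no files written).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression_path = NULL, metadata_path = NULL,
                            dialect = "plain_tsv", panel = gene_panel(),
                            alpha = 0.05, de_variant = "welch",
                            beta = 8L, min_size = 30L, merge_cut = 0.25,
                            nn = list(lr = 0.05, epochs = 2000L,
                                      test_fraction = 0.25),
                            svm = list(sigma2 = 0.5, C = 1, delta = 1.5),
                            seed = 1L, out_dir = NULL) {
  structure(list(expression_path = expression_path,
                 metadata_path = metadata_path, dialect = dialect,
                 panel = panel, alpha = alpha, de_variant = de_variant,
                 beta = beta, min_size = min_size, merge_cut = merge_cut,
                 nn = nn, svm = svm, seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the six stages in sequence and returns a single report. With
#' file inputs, the spectral, differential-expression and module stages run
#' on the supplied cohort and the predictive stages split it; with
#' synthetic inputs each stage runs on the generator that plants its
#' assumed structure. Any stage failure is re-raised with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_report` with blocks `preprocess`,
#'   `spectral`, `de`, `modules`, `nn`, `svm`, plus `config_echo` and
#'   `timestamp`. When `config$out_dir` is set the report is also written
#'   as JSON alongside per-group eigenvector TSVs.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage %s failed: %s", name, conditionMessage(e)))
  }
  report <- list()

  # --- preprocess ---------------------------------------------------------
  synthetic <- is.null(config$expression_path)
  pre <- stage("preprocess", {
    if (synthetic) {
      sim <- simulate_panel(panel_sim_config(seed = derive_seed(config$seed, 1L)))
      expr <- sim$expression
      meta <- sim$metadata
      meta$mmse <- simulate_mmse(expr, seed = derive_seed(config$seed, 2L))$mmse
    } else {
      expr <- read_expression(config$expression_path, config$dialect)
      meta <- read_metadata(config$metadata_path)
    }
    gp <- grouped_panel(expr, meta, config$panel)
    list(gp = gp, expr = expr, meta = meta)
  })
  report$preprocess <- list(synthetic = synthetic,
                            group_sizes = as.list(pre$gp$sizes),
                            n_genes = nrow(pre$expr$values))

  # --- spectral coordination ---------------------------------------------
  spec <- stage("spectral", {
    srs <- lapply(names(pre$gp$groups), function(g)
      eigendecompose(gram_matrix(pre$gp$groups[[g]], group = g)))
    names(srs) <- names(pre$gp$groups)
    list(srs = srs, traj = coordination_trajectory(srs))
  })
  report$spectral <- list(
    leading_fractions = as.list(spec$traj$leading_fractions),
    deltas = as.list(spec$traj$deltas),
    alignment_first_vs_last = unname(
      spec$traj$alignment[1L, length(spec$srs)]),
    reversed = as.list(spec$traj$reversed),
    fractions = lapply(spec$srs, function(s) s$fractions),
    eigenvectors = lapply(spec$srs, function(s) {
      m <- s$vectors
      rownames(m) <- config$panel$symbols
      apply(m, 2L, identity, simplify = FALSE)
    }))

  # --- differential expression -------------------------------------------
  de <- stage("de", {
    logm <- if (pre$expr$scale == "raw") log_transform(pre$expr) else pre$expr
    joined <- join_metadata(logm, pre$meta)
    is_ctrl <- joined$metadata$group == "control"
    screen_genes(
      expr_matrix(joined$expression$values[, !is_ctrl, drop = FALSE],
                  scale = "log10"),
      expr_matrix(joined$expression$values[, is_ctrl, drop = FALSE],
                  scale = "log10"),
      alpha = config$alpha, variant = config$de_variant)
  })
  report$de <- c(as.list(attr(de, "counts")),
                 list(alpha = config$alpha, n_genes = nrow(de)))

  # --- co-expression modules ---------------------------------------------
  mods <- stage("modules", {
    if (synthetic) {
      bg <- simulate_background_modules(seed = derive_seed(config$seed, 3L))
      expr_mod <- bg$expression
    } else {
      expr_mod <- if (pre$expr$scale == "raw") log_transform(pre$expr) else pre$expr
    }
    adj <- soft_adjacency(spearman_matrix(expr_mod), beta = config$beta)
    asg <- detect_modules(adj, expr = expr_mod, min_size = config$min_size,
                          merge_cut = config$merge_cut)
    list(assignment = asg, expr = expr_mod)
  })
  sizes <- attr(mods$assignment, "sizes")
  report$modules <- list(n_modules = sum(names(sizes) != "unassigned"),
                         sizes = as.list(as.integer(sizes)) |>
                           stats::setNames(names(sizes)))

  # --- MMSE network -------------------------------------------------------
  nn <- stage("nn", {
    logm <- if (pre$expr$scale == "raw") log_transform(pre$expr) else pre$expr
    X <- t(extract_panel(logm, config$panel))
    ok <- !is.na(pre$meta$mmse)
    X <- X[ok, , drop = FALSE]
    y <- pre$meta$mmse[ok]
    n <- nrow(X)
    n_test <- max(3L, round(config$nn$test_fraction * n))
    idx <- with_seed(derive_seed(config$seed, 4L), sample.int(n))
    test <- idx[seq_len(n_test)]
    model <- nn_train(X[-test, , drop = FALSE], y[-test],
                      lr = config$nn$lr, epochs = config$nn$epochs,
                      seed = derive_seed(config$seed, 5L))
    list(eval = nn_evaluate(model, X[test, , drop = FALSE], y[test]),
         split = list(n_train = n - n_test, n_test = n_test))
  })
  report$nn <- list(pearson_r = nn$eval$pearson_r,
                    spearman_r = nn$eval$spearman_r,
                    p_value = nn$eval$p_value, mse = nn$eval$mse,
                    n_train = nn$split$n_train, n_test = nn$split$n_test)

  # --- classifier ---------------------------------------------------------
  svm_block <- stage("svm", {
    if (synthetic) {
      tr <- simulate_classification_cohort(delta = config$svm$delta,
                                           seed = derive_seed(config$seed, 6L))
      te <- simulate_classification_cohort(n_control = 16L, n_patient = 15L,
                                           delta = config$svm$delta,
                                           seed = derive_seed(config$seed, 8L))
      f_tr <- extract_features(tr$expression)
      f_te <- extract_features(te$expression)
      lab_tr <- tr$labels; lab_te <- te$labels
    } else {
      logm <- if (pre$expr$scale == "raw") log_transform(pre$expr) else pre$expr
      f_all <- extract_features(extract_panel(logm, config$panel))
      is_ctrl <- pre$meta$group[match(f_all$sample_id,
                                      pre$meta$sample_id)] == "control"
      lab <- factor(ifelse(is_ctrl, "control", "patient"),
                    levels = c("control", "patient"))
      idx <- with_seed(derive_seed(config$seed, 6L),
                       sample.int(nrow(f_all)))
      half <- floor(length(idx) / 2)
      f_tr <- f_all[idx[seq_len(half)], ]; lab_tr <- lab[idx[seq_len(half)]]
      f_te <- f_all[idx[-seq_len(half)], ]; lab_te <- lab[idx[-seq_len(half)]]
    }
    clf <- train_panel_classifier(f_tr, lab_tr, sigma2 = config$svm$sigma2,
                                  C = config$svm$C)
    scores <- predict(clf, f_te)
    roc <- roc_curve(scores, lab_te, positive = "patient")
    cc <- confusion_counts(scores, lab_te, positive = "patient")
    list(roc = roc, cc = cc)
  })
  report$svm <- list(auc = svm_block$roc$auc,
                     sensitivity = svm_block$cc$sensitivity,
                     specificity = svm_block$cc$specificity)

  report$config_echo <- config[setdiff(names(config), c("panel", "out_dir"))]
  report$config_echo$panel <- config$panel$symbols
  report$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  class(report) <- "pipeline_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (g in names(spec$srs)) {
      tab <- data.frame(gene = config$panel$symbols, spec$srs[[g]]$vectors)
      colnames(tab) <- c("gene", paste0("lambda_", seq_len(ncol(tab) - 1L)))
      utils::write.table(tab,
                         file.path(config$out_dir,
                                   paste0("eigenvectors_", g, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat("  leading fractions:",
      paste(sprintf("%s=%.3f", names(x$spectral$leading_fractions),
                    unlist(x$spectral$leading_fractions)), collapse = ", "),
      "\n")
  cat(sprintf("  DE: %d up, %d down (alpha = %g)\n",
              x$de$n_up, x$de$n_down, x$de$alpha))
  cat(sprintf("  modules: %d\n", x$modules$n_modules))
  cat(sprintf("  NN: pearson r = %.3f\n", x$nn$pearson_r))
  cat(sprintf("  SVM: AUC = %.3f\n", x$svm$auc))
  invisible(x)
}
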