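#!/usr/bin/env Rscript
# Per-group Gram-spectrum analysis of the four-gene chaperone panel: leading
# eigenvalue fractions across severity stages, eigenvector tables, the
# stage trajectory, and the comparison with the published control/severe
# eigenvectors.

suppressPackageStartupMessages(library(gramcoord))

dir.create("results", showWarnings = FALSE)
expr <- read_expression("results/data/expression_log10.tsv", scale = "log10")
meta <- read_metadata("results/data/metadata_log10.tsv")
gp <- grouped_panel(expr, meta)

srs <- lapply(names(gp$groups), function(g)
  eigendecompose(gram_matrix(gp$groups[[g]], group = g)))
names(srs) <- names(gp$groups)
traj <- coordination_trajectory(srs)

frac_tab <- data.frame(group = names(srs),
                       t(vapply(srs, function(s) s$fractions, numeric(4))))
colnames(frac_tab) <- c("group", paste0("lambda_", 1:4))
utils::write.table(frac_tab, "results/spectral_fractions.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
for (g in names(srs)) {
  tab <- data.frame(gene = gp$panel$symbols, srs[[g]]$vectors)
  colnames(tab) <- c("gene", paste0("lambda_", 1:4))
  utils::write.table(tab, sprintf("results/eigenvectors_%s.tsv", g),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

cat("Leading eigenvalue fraction by severity stage:\n")
print(round(traj$leading_fractions, 3))
cat("Consecutive deltas:", round(traj$deltas, 3), "\n")
cat("The jump concentrates in the final (severe) transition:",
    names(which.max(traj$deltas)), "\n")

# small-n uncertainty on the control and severe estimates
for (g in c("control", "severe")) {
  bs <- bootstrap_leading_fraction(gp$groups[[g]], n_boot = 1000,
                                   seed = 99L)
  cat(sprintf("  %s leading fraction %.3f (bootstrap 95%% CI %.3f-%.3f)\n",
              g, bs$estimate, bs$lower, bs$upper))
}

# published eigenvector comparison: the reported control-vs-severe
# alignment is strongly negative (a sign reversal of the dominant
# coordination direction)
rv <- reference_eigenvectors()
cmp <- compare_leading_vectors(rv$control[, 1], rv$severe[, 1])
cat(sprintf("Published control-vs-severe leading-vector alignment: %.4f (reversed: %s)\n",
            cmp$alignment, cmp$reversed))

jsonlite::write_json(
  list(leading_fractions = as.list(traj$leading_fractions),
       deltas = as.list(traj$deltas),
       alignment = traj$alignment,
       published_alignment = cmp$alignment),
  "results/spectral_summary.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
cat("Tables written under results/\n")
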