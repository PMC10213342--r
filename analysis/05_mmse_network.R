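#!/usr/bin/env Rscript
# Train the 4-32-1 network on the severity cohort's panel expression and
# MMSE, with a seeded shuffled 24/7 train/test split, and evaluate the
# held-out correlation.

suppressPackageStartupMessages(library(gramcoord))

dir.create("results", showWarnings = FALSE)
expr <- log_transform(read_expression("results/data/expression_raw.tsv"))
meta <- read_metadata("results/data/metadata.tsv")
joined <- join_metadata(expr, meta)

X <- t(extract_panel(joined$expression))
y <- joined$metadata$mmse
n <- nrow(X)
set.seed(31L)
idx <- sample(n)
test <- idx[seq_len(7)]   # 7 held-out samples, 24 for training
train <- setdiff(idx, test)

model <- nn_train(X[train, ], y[train], lr = 0.05, epochs = 2000L,
                  seed = 31L)
ev <- nn_evaluate(model, X[test, ], y[test])

pred_tab <- data.frame(sample_id = rownames(X)[test],
                       mmse_true = y[test],
                       mmse_pred = round(ev$predicted, 2),
                       mmse_pred_clipped = round(ev$predicted_clipped, 2))
utils::write.table(pred_tab, "results/nn_predictions.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf("Trained on %d samples for %d epochs (final training MSE %.3f)\n",
            length(train), model$config$epochs,
            utils::tail(model$loss_trace, 1)))
cat(sprintf("Held-out (n = %d): Pearson r = %.3f (p = %.3g), Spearman r = %.3f, MSE = %.2f\n",
            length(test), ev$pearson_r, ev$p_value, ev$spearman_r, ev$mse))
jsonlite::write_json(list(pearson_r = ev$pearson_r,
                          spearman_r = ev$spearman_r,
                          p_value = ev$p_value, mse = ev$mse,
                          n_train = length(train), n_test = length(test),
                          test_samples = rownames(X)[test]),
                     "results/nn_summary.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
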