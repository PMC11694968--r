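#!/usr/bin/env Rscript
# Step 5 — best-model selection.
# Applies the three-step rule: per model and learning mode, pick the feature
# count with the highest mean training GMEAN; then rank those group winners
# by mean testing GMEAN. Writes the selection report and a metrics table
# (one column per group winner, train and test blocks).

suppressPackageStartupMessages(library(injurycast))

sw <- utils::read.csv("results/sweep_summary.csv", stringsAsFactors = FALSE)
sel <- select_best(sw)
write_best_model_report(sel, "results/best_models.json")

g <- sel$groups
tab <- data.frame(
  model = g$model, learning = g$learning, n_features = g$p,
  train_sensitivity = round(100 * g$train_sensitivity_mean, 2),
  train_specificity = round(100 * g$train_specificity_mean, 2),
  train_accuracy = round(100 * g$train_accuracy_mean, 2),
  train_auc = round(g$train_auc_mean, 2),
  train_gmean = round(100 * g$train_gmean_mean, 2),
  test_sensitivity = round(100 * g$test_sensitivity_mean, 2),
  test_specificity = round(100 * g$test_specificity_mean, 2),
  test_accuracy = round(100 * g$test_accuracy_mean, 2),
  test_auc = round(g$test_auc_mean, 2),
  test_gmean = round(100 * g$test_gmean_mean, 2))
utils::write.csv(tab, "results/best_model_metrics.csv", row.names = FALSE)

cat("Group winners by test GMEAN:\n")
print(tab[, c("model", "learning", "n_features", "train_gmean", "test_gmean")])
cat(sprintf("\nOverall best: %s (%s) with %d features, test GMEAN %.2f%%.\n",
            sel$best$model, sel$best$learning, sel$best$p,
            100 * sel$best$test_gmean_mean))
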