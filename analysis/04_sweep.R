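#!/usr/bin/env Rscript
# Step 4 — the wrapper sweep.
# Trains every model x learning mode x top-p combination with repeated
# player-disjoint two-fold validation: k-means centroid undersampling of the
# training split, ROC-elbow thresholds fitted on training data, and the full
# metric suite on both splits. This driver runs a scaled protocol
# (p in {10, 20, 40, 80}, 5 repetitions); the reference protocol sweeps
# p = 10..260 at 500 repetitions (78,000 runs) with the same code path.

suppressPackageStartupMessages(library(injurycast))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L

sessions <- read_sessions_csv("results/data/sessions.csv")
injuries <- read_injury_log_csv("results/data/injuries.csv")
ds <- build_dataset(sessions, injuries)

grid <- sweep_grid(p_grid = c(10L, 20L, 40L, 80L), repetitions = 5L, seed = seed)
cat(sprintf("Sweeping %d runs (%d coordinates x %d repetitions)...\n",
            nrow(enumerate_runs(grid)),
            length(grid$models) * length(grid$modes) * length(grid$p_grid),
            grid$repetitions))
sw <- run_sweep(ds, grid)

utils::write.csv(sw, "results/sweep_summary.csv", row.names = FALSE)
utils::write.csv(attr(sw, "records"), "results/sweep_records.csv", row.names = FALSE)

for (m in grid$models) {
  s <- sw[sw$model == m, ]
  cat(sprintf("%-8s best mean test GMEAN %.3f (cost-sensitive) vs %.3f (traditional)\n",
              m,
              max(s$test_gmean_mean[s$learning == "cost_sensitive"]),
              max(s$test_gmean_mean[s$learning == "traditional"])))
}
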