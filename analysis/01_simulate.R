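#!/usr/bin/env Rscript
# Step 1 — simulate a season.
# Draws the default synthetic cohort (34 players, 36-week season, ~6 training
# days and ~1 match a week, 300 correlated GPS-style metrics, 18 expected
# injuries under the load-spike hazard) and writes the raw layers:
# exercise-level session records, the injury log, and the configuration.

suppressPackageStartupMessages(library(injurycast))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
cfg <- sim_config(seed = seed)
season <- generate_season(cfg)

write_sessions_csv(season$sessions, "results/data/sessions.csv")
write_injury_log_csv(season$injuries, "results/data/injuries.csv")
write_sim_config(cfg, "results/data/sim_config.yaml")

ctx <- injury_context_summary(season$injuries)
cat(sprintf("Simulated %d exercise records for %d players over %d days.\n",
            nrow(season$sessions), cfg$n_players,
            as.integer(cfg$season_end - cfg$season_start) + 1L))
cat(sprintf("Injuries: %d (%d in matches, %.2f%%; %d in training).\n",
            ctx$n_total, ctx$n_match, ctx$pct_match, ctx$n_training))
cat(sprintf("Calibrated baseline hazard: %.3e per active player-day.\n",
            attr(season, "effective_baseline")))
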