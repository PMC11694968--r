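#!/usr/bin/env Rscript
# Step 2 — build the player-day table.
# Aggregates exercises to one record per player per day, drops the GPS
# quality columns (HDOP, satellite count), inserts all-zero dummy days over
# the shared season calendar, and one-hot encodes the descriptive variables.

suppressPackageStartupMessages(library(injurycast))

sessions <- read_sessions_csv("results/data/sessions.csv")
injuries <- read_injury_log_csv("results/data/injuries.csv")
cfg <- read_sim_config("results/data/sim_config.yaml")

prep <- prepare_player_days(sessions, injuries,
                            calendar_start = cfg$season_start,
                            calendar_end = cfg$season_end)
write_player_day_csv(prep, "results/player_days.csv")

cat(sprintf("Player-day table: %d rows (%d players x %d days), %d feature columns.\n",
            nrow(prep), length(unique(prep$player_id)),
            as.integer(cfg$season_end - cfg$season_start) + 1L,
            length(setdiff(names(prep), c("player_id", "date", "is_dummy", "injury")))))
cat(sprintf("Dummy (rest) rows: %d (%.1f%%); injury rows: %d (%.3f%% of player-days).\n",
            sum(prep$is_dummy), 100 * mean(prep$is_dummy),
            sum(prep$injury), 100 * mean(prep$injury)))
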