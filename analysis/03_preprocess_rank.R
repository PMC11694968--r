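#!/usr/bin/env Rscript
# Step 3 — preprocess and rank features.
# Fits winsorization bounds on injured records only, clips every record,
# standardizes each column, removes zero-variance columns, and ranks the
# survivors by greedy mRMR (F-statistic relevance / mean |correlation|
# redundancy, quotient scoring).

suppressPackageStartupMessages(library(injurycast))

prep <- read_player_day_csv("results/player_days.csv")
pp <- preprocess_features(prep)
nz <- drop_zero_variance(pp$table)
ranking <- mrmr_rank(
  as.matrix(nz[, setdiff(names(nz), c("player_id", "date", "is_dummy", "injury"))]),
  nz$injury)

write_winsor_bounds_json(pp$bounds, "results/winsor_bounds.json")
write_standardizer_json(pp$standardizer, "results/standardizer.json")
write_ranking_csv(ranking, "results/feature_ranking.csv")
write_player_day_csv(nz, "results/player_days_preprocessed.csv")

cat(sprintf("Winsorized %d metrics (%d no-clip); dropped %d zero-variance columns.\n",
            nrow(pp$bounds), sum(!pp$bounds$clip),
            length(attr(nz, "removed"))))
cat(sprintf("Ranked %d features by mRMR; top 5: %s.\n",
            nrow(ranking), paste(head(ranking$name, 5), collapse = ", ")))
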