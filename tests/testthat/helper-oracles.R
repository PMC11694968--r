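# Shared fixtures and independent brute-force oracles. Oracles are written
# as plain loops against the definitions, deliberately sharing no code with
# the implementation they check.

# Scaled cohort used throughout the suite: 20 players, a 12-week autumn
# block, 40 metrics, 12 expected injuries.
scaled_config <- function(seed = 1L, ...) {
  args <- list(n_players = 20, season_end = as.Date("2020-11-29"),
               n_metrics = 40, target_injuries = 12, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# Minimal cohort for fast unit checks.
micro_config <- function(seed = 1L, ...) {
  scaled_config(seed, n_players = 8, season_end = as.Date("2020-10-18"),
                n_metrics = 15, target_injuries = 6, ...)
}

# Generate a season whose injury log spans at least `min_injured` players.
season_with_injuries <- function(cfg, min_injured = 2L, max_tries = 20L) {
  for (k in seq_len(max_tries)) {
    season <- generate_season(cfg)
    if (length(unique(season$injuries$player_id)) >= min_injured) return(season)
    cfg$seed <- cfg$seed + 1000L
  }
  stop("could not draw a season with enough injured players")
}

# Elementwise clip with bounds recomputed from scratch (loops, no pmin/pmax).
oracle_winsorize <- function(x, injured) {
  med <- median(injured)
  s <- sd(injured)
  if (is.na(s) || s == 0) return(x)
  lo <- med - (floor(abs(min(injured)) / s) + 1) * s
  hi <- med + (floor(abs(max(injured)) / s) + 1) * s
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    out[i] <- if (x[i] < lo) lo else if (x[i] > hi) hi else x[i]
  }
  out
}

# Exhaustive ROC elbow: every distinct score plus a supremum point, double
# loop over candidates and observations.
oracle_elbow <- function(y, s) {
  cand <- c(sort(unique(s)), max(s) + 1)
  best <- NA_real_
  best_d <- Inf
  for (thr in cand) {
    tp <- fp <- 0
    for (i in seq_along(s)) {
      if (s[i] >= thr) {
        if (y[i] == 1) tp <- tp + 1 else fp <- fp + 1
      }
    }
    sens <- tp / sum(y == 1)
    fpr <- fp / sum(y == 0)
    d <- sqrt((1 - sens)^2 + fpr^2)
    if (d < best_d - 1e-12) {
      best_d <- d
      best <- thr
    }
  }
  best
}

# Greedy mRMR (FCQ) recomputed independently: relevance via stats::aov,
# redundancy via explicit pairwise correlation loops.
oracle_mrmr_order <- function(X, y) {
  nm <- colnames(X)
  rel <- sapply(seq_len(ncol(X)), function(j) {
    summary(stats::aov(X[, j] ~ factor(y)))[[1]][["F value"]][1]
  })
  names(rel) <- nm
  picked <- character(0)
  remaining <- nm
  while (length(remaining) > 0) {
    if (length(picked) == 0) {
      crit <- rel[remaining]
    } else {
      crit <- sapply(remaining, function(f) {
        red <- mean(sapply(picked, function(g) abs(cor(X[, f], X[, g]))))
        rel[f] / max(red, 1e-12)
      })
    }
    best <- remaining[order(-crit, remaining)][1]
    picked <- c(picked, best)
    remaining <- setdiff(remaining, best)
  }
  picked
}

# AUC by counting concordant/tied positive-negative pairs.
oracle_auc <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# Hand evaluation of the daily hazard formula for a short history.
oracle_hazard <- function(loads, d, baseline, spike_coef, rest_gap_coef) {
  if (loads[d] == 0) return(0)
  prev <- loads[max(1, d - 7):(d - 1)]
  z <- 0
  if (length(prev) >= 2 && sd(prev) > 0) {
    z <- max((loads[d] - mean(prev)) / sd(prev), 0)
  }
  gap <- d >= 3 && loads[d - 1] == 0 && loads[d - 2] == 0
  min(baseline * exp(spike_coef * z) * exp(rest_gap_coef * gap), 1)
}
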