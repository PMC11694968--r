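#' Configuration for a synthetic football season
#'
#' Bundles the cohort, calendar, metric and injury-hazard parameters of the
#' synthetic season generator. Defaults describe a single-club professional
#' cohort: 34 players over a 36-week season (September to May) with six
#' training days and roughly one match per week, several hundred correlated
#' nonnegative GPS-style load metrics, and an expected 18 noncontact injuries
#' (a fraction of player-days in the 0.2--0.4% range).
#'
#' The injury hazard is a construct of the generator (observational injury
#' data carry no generative mechanism): each active day's probability is a
#' baseline scaled up by `exp(spike_coef * z)` for a positive load z-spike
#' relative to the previous week and by `exp(rest_gap_coef)` when the session
#' follows two or more idle days. See [injury_probability()].
#'
#' @param n_players number of players in the squad.
#' @param position_weights named proportions over the five field positions;
#'   must sum to 1.
#' @param season_start,season_end calendar dates bounding the season.
#' @param sessions_per_week training days per week.
#' @param matches_per_week matches per week (occasional extra midweek matches
#'   are drawn on top, emulating cup fixtures).
#' @param n_metrics number of GPS-like metric columns (a few of them are
#'   deliberate rescaled duplicates so redundancy handling is exercised; two
#'   GPS-quality columns, HDOP and satellite count, are always appended).
#' @param metric_corr common-factor correlation level of the metrics, in
#'   `[0, 1)`.
#' @param baseline_hazard per-active-player-day injury probability before
#'   hazard multipliers.
#' @param spike_coef multiplicative hazard effect per unit of positive load
#'   z-spike.
#' @param rest_gap_coef log-hazard increment for training after >= 2 idle days.
#' @param target_injuries expected number of injuries over the season; when
#'   non-`NA`, [generate_season()] rescales the baseline so the summed daily
#'   probabilities equal this count. `NA` uses `baseline_hazard` as is.
#' @param seed integer seed making the season reproducible.
#' @return a `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_players = 4, season_end = as.Date("2020-10-05"),
#'                   n_metrics = 8, target_injuries = 2)
sim_config <- function(n_players = 34,
                       position_weights = c(defender = 11, attacking_midfielder = 9,
                                            forward = 7, defensive_midfielder = 4,
                                            midfielder = 3) / 34,
                       season_start = as.Date("2020-09-07"),
                       season_end = as.Date("2021-05-19"),
                       sessions_per_week = 6,
                       matches_per_week = 1,
                       n_metrics = 300,
                       metric_corr = 0.5,
                       baseline_hazard = 0.003,
                       spike_coef = 0.4,
                       rest_gap_coef = 0.3,
                       target_injuries = 18,
                       seed = 1L) {
  if (!is.numeric(position_weights) || is.null(names(position_weights)) ||
      any(position_weights < 0) || abs(sum(position_weights) - 1) > 1e-8) {
    stop("`position_weights` must be named, nonnegative and sum to 1", call. = FALSE)
  }
  assert_scalar(baseline_hazard, "baseline_hazard")
  if (baseline_hazard <= 0 || baseline_hazard >= 1) {
    stop("`baseline_hazard` must be in (0, 1)", call. = FALSE)
  }
  if (metric_corr < 0 || metric_corr >= 1) {
    stop("`metric_corr` must be in [0, 1)", call. = FALSE)
  }
  cfg <- list(
    n_players = as.integer(n_players),
    position_weights = position_weights,
    season_start = as.Date(season_start),
    season_end = as.Date(season_end),
    sessions_per_week = as.integer(sessions_per_week),
    matches_per_week = as.integer(matches_per_week),
    n_metrics = as.integer(n_metrics),
    metric_corr = metric_corr,
    baseline_hazard = baseline_hazard,
    spike_coef = spike_coef,
    rest_gap_coef = rest_gap_coef,
    target_injuries = if (is.null(target_injuries)) NA_real_ else as.numeric(target_injuries),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

# Metric name vector: a realistic GPS head, generic tails, and rescaled
# duplicates of the first few so mRMR redundancy handling can be exercised.
metric_names <- function(n_metrics) {
  base <- c("player_load", "total_distance_m", "hsr_distance_m",
            "sprint_distance_m", "max_velocity_ms", "max_acceleration_ms2",
            "accel_band1_efforts", "accel_band2_efforts", "accel_band3_efforts",
            "vel_band1_distance_m", "vel_band2_distance_m", "vel_band3_distance_m",
            "decel_band1_efforts", "decel_band2_efforts", "impact_count",
            "metabolic_power_mean")
  n_dup <- if (n_metrics >= 12) 3L else 0L
  n_base <- n_metrics - n_dup
  if (n_base <= length(base)) {
    nm <- base[seq_len(n_base)]
  } else {
    nm <- c(base, sprintf("metric_%03d", seq_len(n_base - length(base))))
  }
  if (n_dup > 0) nm <- c(nm, paste0(nm[seq_len(n_dup)], "_alt"))
  nm
}

# Rolling 7-day window hazard multiplier components for one player's daily
# load series: positive z-spike and rest-gap indicator per day.
.hazard_components <- function(loads) {
  n <- length(loads)
  spike <- numeric(n)
  gap <- logical(n)
  for (d in seq_len(n)) {
    if (loads[d] <= 0) next
    lo <- max(1L, d - 7L)
    prev <- if (d > 1L) loads[lo:(d - 1L)] else numeric(0)
    if (length(prev) >= 2L) {
      s <- sample_sd(prev)
      if (s > 0) spike[d] <- max((loads[d] - mean(prev)) / s, 0)
    }
    gap[d] <- d >= 3L && loads[d - 1L] == 0 && loads[d - 2L] == 0
  }
  list(spike = spike, gap = gap)
}

#' Daily injury probability under the load-spike hazard model
#'
#' The hazard for an active day (nonzero load) is
#' `baseline_hazard * exp(spike_coef * max(z, 0)) * exp(rest_gap_coef * gap)`,
#' clipped to `[0, 1]`, where `z` is the day's load standardized against the
#' mean and sample standard deviation of the previous (up to) 7 days --- rest
#' days count as zero load --- and `gap` indicates an active day following at
#' least two consecutive idle days. Days with zero load carry zero hazard:
#' injuries occur during sessions only. With fewer than two prior days, or a
#' degenerate (zero-variance) window, the z-spike is 0.
#'
#' @param load_history numeric vector of daily loads (0 on idle days).
#' @param day_index which day of the history to evaluate.
#' @param config a [sim_config()].
#' @return a probability in `[0, 1]`.
#' @export
injury_probability <- function(load_history, day_index, config) {
  if (any(load_history < 0)) stop("daily loads must be nonnegative", call. = FALSE)
  if (day_index < 1L || day_index > length(load_history)) {
    stop("`day_index` outside the history", call. = FALSE)
  }
  if (load_history[day_index] <= 0) return(0)
  comp <- .hazard_components(load_history)
  p <- config$baseline_hazard *
    exp(config$spike_coef * comp$spike[day_index]) *
    exp(config$rest_gap_coef * as.numeric(comp$gap[day_index]))
  min(max(p, 0), 1)
}

# Team calendar: per calendar day, is it a training day, a match day, or rest.
.team_calendar <- function(config) {
  days <- seq(config$season_start, config$season_end, by = "day")
  n <- length(days)
  type <- rep(NA_character_, n)
  week <- (seq_len(n) - 1L) %/% 7L
  for (w in unique(week)) {
    idx <- which(week == w)
    n_match <- min(config$matches_per_week + as.integer(stats::runif(1) < 0.06),
                   length(idx))
    match_idx <- if (n_match > 0) sample(idx, n_match) else integer(0)
    rest <- setdiff(idx, match_idx)
    n_train <- min(config$sessions_per_week, length(rest))
    train_idx <- if (n_train > 0) sample(rest, n_train) else integer(0)
    type[match_idx] <- "match"
    type[train_idx] <- "training"
  }
  data.frame(date = days, session_type = type, stringsAsFactors = FALSE)
}

#' Generate a synthetic season of exercise-level session records
#'
#' Draws a seeded synthetic season: a team calendar of training days and
#' matches, per-player irregular attendance, multi-exercise days, correlated
#' log-normal GPS-style metrics scaled by session intensity (matches are more
#' intense than training), descriptive variables, and an injury log drawn from
#' the load-spike hazard of [injury_probability()]. When
#' `config$target_injuries` is set, the baseline hazard is rescaled by a
#' scalar root-solve so the summed daily probabilities equal the target; the
#' effective baseline is returned in `attr(, "effective_baseline")`.
#'
#' @param config a [sim_config()].
#' @return a list with `sessions` (one row per player-exercise), `injuries`
#'   (player, date, context) and `config`.
#' @export
generate_season <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  empty <- list(
    sessions = data.frame(), injuries = data.frame(
      player_id = character(0), date = as.Date(character(0)),
      context = character(0), stringsAsFactors = FALSE),
    config = config)
  if (config$n_players <= 0L || config$season_end < config$season_start) {
    return(empty)
  }

  players <- sprintf("P%02d", seq_len(config$n_players))
  positions <- sample(names(config$position_weights), config$n_players,
                      replace = TRUE, prob = config$position_weights)
  corridors <- sample(c("left", "centre", "right"), config$n_players, replace = TRUE)
  age_years <- stats::rnorm(config$n_players, 26.27, 3.28)
  birth_dates <- config$season_start - round(age_years * 365.25)

  cal <- .team_calendar(config)
  session_days <- cal[!is.na(cal$session_type), , drop = FALSE]
  if (nrow(session_days) == 0L) return(empty)

  nm <- metric_names(config$n_metrics)
  n_dup <- sum(grepl("_alt$", nm))
  n_base <- length(nm) - n_dup
  mu <- stats::runif(n_base, 1.5, 6.0)
  sg <- stats::runif(n_base, 0.3, 0.7)
  mu[1] <- 4.0; sg[1] <- 0.45   # player_load ~ exp(4) a.u.
  dup_scale <- stats::runif(n_dup, 0.5, 100)

  # Attendance and exercise counts per player x session day
  rows <- list()
  for (i in seq_along(players)) {
    attend_p <- ifelse(session_days$session_type == "match", 0.70, 0.85)
    attended <- stats::runif(nrow(session_days)) < attend_p
    sd_i <- session_days[attended, , drop = FALSE]
    if (nrow(sd_i) == 0L) next
    n_ex <- ifelse(sd_i$session_type == "match",
                   1L + stats::rbinom(nrow(sd_i), 1L, 0.5),
                   1L + stats::rpois(nrow(sd_i), 2.2))
    rows[[i]] <- data.frame(
      player_id = players[i],
      date = rep(sd_i$date, n_ex),
      session_type = rep(sd_i$session_type, n_ex),
      stringsAsFactors = FALSE)
  }
  sess <- do.call(rbind, rows)
  if (is.null(sess) || nrow(sess) == 0L) return(empty)
  ord <- order(sess$player_id, sess$date)
  sess <- sess[ord, , drop = FALSE]
  ex_idx <- stats::ave(seq_len(nrow(sess)),
                       paste(sess$player_id, sess$date),
                       FUN = seq_along)
  sess$exercise_idx <- as.integer(ex_idx)

  # Correlated log-normal metrics: common row factor + independent noise,
  # scaled up on match days.
  n <- nrow(sess)
  rho <- config$metric_corr
  common <- stats::rnorm(n)
  z <- sqrt(rho) * matrix(common, n, n_base) +
    sqrt(1 - rho) * matrix(stats::rnorm(n * n_base), n, n_base)
  # a match is the heaviest single session of the week: a training *day* sums
  # several short drills, a match day is one ~90-minute maximal effort
  intensity <- ifelse(sess$session_type == "match", 4.0, 1.0)
  metrics <- exp(sweep(sweep(z, 2, sg, `*`), 2, mu, `+`)) * intensity
  if (n_dup > 0) {
    metrics <- cbind(metrics, sweep(metrics[, seq_len(n_dup), drop = FALSE],
                                    2, dup_scale, `*`))
  }
  colnames(metrics) <- nm
  # GPS-quality columns, later dropped by the preparation stage
  quality <- cbind(hdop_avg = stats::runif(n, 1, 2),
                   satellite_count_max = sample(8:14, n, replace = TRUE))

  row_i <- match(sess$player_id, players)
  desc <- data.frame(
    position = positions[row_i],
    corridor = corridors[row_i],
    age_months = as.integer(floor(as.numeric(sess$date - birth_dates[row_i]) / 30.4375)),
    day_of_week = weekdays(sess$date),
    stringsAsFactors = FALSE)
  is_match <- sess$session_type == "match"
  # Match descriptors are day-level facts, identical for a day's exercises
  mdays <- unique(sess$date[is_match])
  mres <- sample(c("win", "draw", "loss"), length(mdays), replace = TRUE,
                 prob = c(0.45, 0.25, 0.30))
  mloc <- sample(c("home", "away"), length(mdays), replace = TRUE)
  mcmp <- sample(c("league", "cup"), length(mdays), replace = TRUE,
                 prob = c(0.9, 0.1))
  mi <- match(sess$date, mdays)
  desc$match_result <- ifelse(is_match, mres[mi], NA_character_)
  desc$match_location <- ifelse(is_match, mloc[mi], NA_character_)
  desc$match_competition <- ifelse(is_match, mcmp[mi], NA_character_)
  desc$duration_min <- round(ifelse(is_match, stats::runif(n, 45, 95),
                                    stats::runif(n, 10, 40)), 1)

  sessions <- cbind(sess[, c("player_id", "date", "session_type", "exercise_idx")],
                    desc, as.data.frame(metrics), as.data.frame(quality))
  rownames(sessions) <- NULL

  # Injury draw from the hazard model on per-player daily load series
  all_days <- cal$date
  load_col <- nm[1]
  daily <- tapply(sessions[[load_col]],
                  list(factor(sessions$player_id, levels = players),
                       factor(as.character(sessions$date), levels = as.character(all_days))),
                  sum)
  daily[is.na(daily)] <- 0

  mult <- matrix(0, nrow(daily), ncol(daily))
  for (i in seq_len(nrow(daily))) {
    comp <- .hazard_components(daily[i, ])
    active <- daily[i, ] > 0
    logm <- config$spike_coef * comp$spike[active] +
      config$rest_gap_coef * as.numeric(comp$gap[active])
    mult[i, active] <- exp(pmin(logm, 700))   # keep finite for the root-solve
  }
  b <- config$baseline_hazard
  if (is.finite(config$target_injuries) && sum(mult) > 0) {
    f <- function(bb) sum(pmin(bb * mult, 1)) - config$target_injuries
    upper <- 1
    if (f(upper) < 0) {
      b <- upper
    } else {
      b <- stats::uniroot(f, c(0, upper), tol = 1e-12)$root
    }
  }
  prob <- pmin(b * mult, 1)
  hit <- matrix(stats::runif(length(prob)) < prob, nrow(prob), ncol(prob))

  inj <- which(hit, arr.ind = TRUE)
  injuries <- data.frame(
    player_id = players[inj[, 1]],
    date = all_days[inj[, 2]],
    stringsAsFactors = FALSE)
  if (nrow(injuries) > 0) {
    key <- paste(injuries$player_id, injuries$date)
    skey <- paste(sessions$player_id, sessions$date)
    injuries$context <- sessions$session_type[match(key, skey)]
    injuries <- injuries[order(injuries$date, injuries$player_id), , drop = FALSE]
    rownames(injuries) <- NULL
  } else {
    injuries$context <- character(0)
  }

  out <- list(sessions = sessions, injuries = injuries, config = config)
  attr(out, "effective_baseline") <- b
  attr(out, "expected_injuries") <- sum(prob)
  out
}

#' Summarize injury context proportions from an injury log
#'
#' Counts injuries by context (match vs training) and reports the percentage
#' occurring in matches, the headline epidemiological split of a season
#' report.
#'
#' @param injuries data.frame with a `context` column of
#'   `"match"`/`"training"` values.
#' @return list with `n_total`, `n_match`, `n_training` and `pct_match`
#'   (percentage, two decimals).
#' @export
#' @examples
#' log <- data.frame(context = rep(c("match", "training"), c(10, 8)))
#' injury_context_summary(log)$pct_match  # 55.56
injury_context_summary <- function(injuries) {
  n_total <- nrow(injuries)
  n_match <- sum(injuries$context == "match")
  list(n_total = n_total,
       n_match = n_match,
       n_training = sum(injuries$context == "training"),
       pct_match = if (n_total > 0) round(100 * n_match / n_total, 2) else NA_real_)
}

#' @rdname season_io
#' @export
write_sessions_csv <- function(sessions, path) {
  utils::write.csv(sessions, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Session and injury-log CSV readers/writers
#'
#' One row per player-exercise; dates ISO-8601; match-only descriptors blank
#' on training rows. Reading restores the written frame exactly (dates as
#' `Date`, blanks as `NA`).
#'
#' @param sessions,injuries data.frames as produced by [generate_season()].
#' @param path file path.
#' @name season_io
#' @export
read_sessions_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  x$date <- as.Date(x$date)
  x
}

#' @rdname season_io
#' @export
write_injury_log_csv <- function(injuries, path) {
  utils::write.csv(injuries, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname season_io
#' @export
read_injury_log_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                       colClasses = c(player_id = "character"))
  x$date <- as.Date(x$date)
  x
}

#' @rdname season_io
#' @param config a [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$season_start <- as.character(x$season_start)
  x$season_end <- as.character(x$season_end)
  x$position_weights <- as.list(x$position_weights)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname season_io
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$position_weights <- unlist(x$position_weights)
  do.call(sim_config, x)
}
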