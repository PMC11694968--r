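# Hand-built exercise-level fixture: 2 players, mixed session types.
toy_sessions <- function() {
  data.frame(
    player_id = c("A", "A", "A", "B", "B"),
    date = as.Date(c("2020-09-07", "2020-09-07", "2020-09-09",
                     "2020-09-07", "2020-09-07")),
    session_type = c("training", "training", "match", "training", "match"),
    exercise_idx = c(1L, 2L, 1L, 1L, 2L),
    distance = c(3, 4, 10, 2, 8),
    max_vel = c(6.1, 7.2, 8.0, 5.5, 7.7),
    avg_rate = c(10, 30, 12, 20, 40),
    hdop_avg = c(1.1, 1.2, 1.0, 1.4, 1.3),
    position = "defender",
    corridor = "left",
    age_months = c(300L, 300L, 300L, 280L, 280L),
    day_of_week = "Monday",
    match_result = c(NA, NA, "win", NA, "loss"),
    match_location = c(NA, NA, "home", NA, "away"),
    match_competition = c(NA, NA, "league", NA, "league"),
    duration_min = c(30, 20, 90, 25, 90),
    stringsAsFactors = FALSE)
}

test_that("metrics aggregate to daily records by their declared functions", {
  out <- aggregate_sessions(toy_sessions())
  expect_equal(nrow(out), 3)
  a1 <- out[out$player_id == "A" & out$date == as.Date("2020-09-07"), ]
  expect_equal(a1$distance, 7)          # 3 + 4
  expect_equal(a1$max_vel, 7.2)         # max(6.1, 7.2)
  expect_equal(a1$avg_rate, 20)         # mean(10, 30)
  expect_equal(a1$n_exercises, 2)
  expect_equal(a1$duration_min, 50)
  expect_equal(a1$session_type, "training")
})

test_that("a multi-exercise day equals per-function brute-force recomputation", {
  set.seed(7)
  rec <- data.frame(
    player_id = "Z", date = as.Date("2020-10-01"), session_type = "training",
    exercise_idx = 1:5,
    load_sum = stats::runif(5, 0, 50),
    peak_speed = stats::runif(5, 4, 9),
    work_rate = stats::runif(5, 1, 3),
    stringsAsFactors = FALSE)
  out <- aggregate_sessions(rec)
  expect_equal(out$load_sum, sum(rec$load_sum))
  expect_equal(out$peak_speed, max(rec$peak_speed))
  expect_equal(out$work_rate, mean(rec$work_rate))
})

test_that("aggregation ignores the order of exercise records", {
  rec <- toy_sessions()
  perm <- rec[sample(nrow(rec)), ]
  a <- aggregate_sessions(rec)
  b <- aggregate_sessions(perm)
  expect_equal(a, b)
})

test_that("a match exercise makes the whole day a match day", {
  out <- aggregate_sessions(toy_sessions())
  b <- out[out$player_id == "B", ]
  expect_equal(b$session_type, "match")
  expect_equal(b$match_result, "loss")
})

test_that("injury labels join on player and date", {
  log <- data.frame(player_id = "A", date = as.Date("2020-09-09"),
                    context = "match", stringsAsFactors = FALSE)
  out <- aggregate_sessions(toy_sessions(), injury_log = log)
  expect_equal(out$injury[out$player_id == "A" & out$date == as.Date("2020-09-09")], 1L)
  expect_equal(sum(out$injury), 1L)
})

test_that("quality and void columns are dropped, others survive", {
  tab <- data.frame(player_id = "A", date = as.Date("2020-09-07"),
                    load = 5, hdop_avg = 1.2, satellite_count_max = 10,
                    all_missing = NA_real_, keep_too = 3, injury = 0L)
  out <- drop_invalid_metrics(tab)
  expect_setequal(names(out), c("player_id", "date", "load", "keep_too", "injury"))
  expect_setequal(attr(out, "dropped"),
                  c("hdop_avg", "satellite_count_max", "all_missing"))
  expect_error(drop_invalid_metrics(tab[, c("player_id", "date", "hdop_avg", "injury")]),
               "all feature columns")
  expect_error(drop_invalid_metrics(tab, character(0)), "nonempty")
})

test_that("dummy days complete every player's calendar with zero rows", {
  tab <- data.frame(
    player_id = c("A", "A", "B"),
    date = as.Date(c("2020-09-07", "2020-09-09", "2020-09-08")),
    load = c(5, 7, 3), position = "defender",
    injury = c(0L, 1L, 0L), stringsAsFactors = FALSE)
  out <- insert_dummy_days(tab, as.Date("2020-09-07"), as.Date("2020-09-09"))
  expect_equal(nrow(out), 6)                       # 2 players x 3 days
  gap <- out[out$player_id == "A" & out$date == as.Date("2020-09-08"), ]
  expect_equal(gap$load, 0)
  expect_true(is.na(gap$position))
  expect_equal(gap$is_dummy, 1L)
  expect_equal(gap$injury, 0L)
  # original rows untouched
  expect_equal(out$load[out$player_id == "A" & out$date == as.Date("2020-09-09")], 7)
  expect_false(anyDuplicated(paste(out$player_id, out$date)) > 0)
})

test_that("a complete calendar is returned unchanged apart from flags", {
  tab <- data.frame(player_id = "A", date = as.Date("2020-09-07") + 0:2,
                    load = 1:3, injury = 0L, stringsAsFactors = FALSE)
  out <- insert_dummy_days(tab)
  expect_equal(out$load, 1:3)
  expect_equal(out$is_dummy, rep(0L, 3))
})

test_that("dummy-day row count is exactly players x calendar length", {
  season <- generate_season(micro_config(seed = 21))
  agg <- aggregate_sessions(season$sessions)
  out <- insert_dummy_days(agg, season$config$season_start,
                           season$config$season_end)
  n_days <- as.numeric(season$config$season_end - season$config$season_start) + 1
  expect_equal(nrow(out), length(unique(agg$player_id)) * n_days)
})

test_that("one-hot groups are complete and sum to presence", {
  tab <- data.frame(
    player_id = c("A", "A", "B"), date = as.Date("2020-09-07") + 0:2,
    session_type = c("training", NA, "match"),
    position = c("defender", NA, "forward"),
    is_dummy = c(0L, 1L, 0L), injury = 0L, stringsAsFactors = FALSE)
  out <- encode_descriptive(tab, c("session_type", "position"))
  st_cols <- grep("^session_type\\.", names(out), value = TRUE)
  expect_length(st_cols, 2)
  sums <- rowSums(out[, st_cols])
  expect_equal(sums[out$is_dummy == 0], c(1, 1), ignore_attr = TRUE)
  expect_equal(sums[out$is_dummy == 1], 0, ignore_attr = TRUE)
})

test_that("indicator columns count one per observed level", {
  n <- 30
  set.seed(2)
  tab <- data.frame(
    player_id = "A", date = as.Date("2020-09-07") + seq_len(n),
    f2 = sample(letters[1:2], n, TRUE),
    f3 = sample(letters[1:3], n, TRUE),
    f5 = sample(letters[1:5], n, TRUE),
    injury = 0L, stringsAsFactors = FALSE)
  out <- encode_descriptive(tab, c("f2", "f3", "f5"))
  expect_length(grep("^f[235]\\.", names(out)), 10)
})

test_that("values outside a supplied level schema warn and encode to zero", {
  tab <- data.frame(player_id = "A", date = as.Date("2020-09-07"),
                    pos = "goalkeeper", injury = 0L, stringsAsFactors = FALSE)
  expect_warning(
    out <- encode_descriptive(tab, "pos", levels = list(pos = c("defender", "forward"))),
    "unseen")
  expect_equal(unname(unlist(out[, grep("^pos\\.", names(out))])), c(0, 0))
})

test_that("the prepared table round-trips through the CSV dialect", {
  season <- season_with_injuries(micro_config(seed = 33))
  prep <- prepare_player_days(season$sessions, season$injuries)
  expect_true(all(vapply(prep[, feature_cols(prep)], is.numeric, TRUE)))
  path <- tempfile(fileext = ".csv")
  write_player_day_csv(prep, path)
  back <- read_player_day_csv(path)
  expect_equal(back, prep, tolerance = 1e-12, ignore_attr = TRUE)
})
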