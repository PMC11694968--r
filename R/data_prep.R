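#' Aggregation rules mapping exercise metrics to daily values
#'
#' Exercise-level metrics are collapsed to one record per player per day with
#' a per-metric aggregation function. Explicit mappings win; unmapped metrics
#' fall back to a name heuristic: metrics named like maxima (`max`, `peak`)
#' take the daily maximum, rates and averages (`rate`, `mean`, `avg`, `hdop`)
#' the daily mean, and counts, distances, durations and loads the daily sum.
#' Names matching none of the cues aggregate by `sum` with a warning.
#'
#' @param mapping named character vector, metric name -> one of
#'   `"sum"`, `"mean"`, `"max"`.
#' @param default fallback rule: `"suffix"` (the heuristic above) or a fixed
#'   function name.
#' @return an `aggregation_spec` list.
#' @export
aggregation_spec <- function(mapping = character(0),
                             default = c("suffix", "sum", "mean", "max")) {
  default <- match.arg(default)
  if (length(mapping) > 0 &&
      (!all(mapping %in% c("sum", "mean", "max")) || is.null(names(mapping)))) {
    stop("`mapping` must be a named vector of \"sum\"/\"mean\"/\"max\"", call. = FALSE)
  }
  structure(list(mapping = mapping, default = default),
            class = "aggregation_spec")
}

# Resolve the aggregation function name for each metric column.
resolve_aggregation <- function(metric_names, spec) {
  fun <- spec$mapping[metric_names]
  names(fun) <- metric_names
  miss <- is.na(fun)
  if (!any(miss)) return(fun)
  if (spec$default != "suffix") {
    fun[miss] <- spec$default
    return(fun)
  }
  nm <- tolower(metric_names[miss])
  pick <- rep(NA_character_, sum(miss))
  pick[grepl("max|peak", nm)] <- "max"
  pick[is.na(pick) & grepl("rate|mean|avg|average|hdop", nm)] <- "mean"
  pick[is.na(pick) &
         grepl("count|effort|distance|duration|load|impact|sprint|metric_|band",
               nm)] <- "sum"
  if (anyNA(pick)) {
    warning(sprintf("no aggregation cue for %s; defaulting to sum",
                    paste(metric_names[miss][is.na(pick)], collapse = ", ")),
            call. = FALSE)
    pick[is.na(pick)] <- "sum"
  }
  fun[miss] <- pick
  fun
}

# Descriptive (non-metric) columns of a session frame.
.DESC_COLS <- c("position", "corridor", "age_months", "day_of_week",
                "match_result", "match_location", "match_competition",
                "duration_min")

#' Collapse exercise-level records into a one-row-per-player-day table
#'
#' Groups session records by player and date, aggregates each metric with its
#' rule from [aggregation_spec()], computes the session descriptives (number
#' of exercises, total duration), resolves within-day session-type conflicts
#' as match > training (a match day's identity dominates; its match
#' descriptors are day-level facts), and attaches the binary injury label
#' from the injury log.
#'
#' @param records session data.frame (one row per player-exercise) with
#'   `player_id`, `date`, `session_type`, `exercise_idx`, metric columns and
#'   descriptive columns.
#' @param spec an [aggregation_spec()].
#' @param injury_log optional data.frame with `player_id` and `date`; matching
#'   rows get `injury = 1`.
#' @return a player-day data.frame keyed by (`player_id`, `date`) with
#'   aggregated metrics, descriptive variables, `n_exercises`, `duration_min`
#'   and `injury`.
#' @export
aggregate_sessions <- function(records, spec = aggregation_spec(),
                               injury_log = NULL) {
  if (nrow(records) == 0L) stop("no session records to aggregate", call. = FALSE)
  key <- paste(records$player_id, records$date)
  ukey <- !duplicated(key)
  g <- match(key, key[ukey])
  n_groups <- sum(ukey)

  reserved <- c("player_id", "date", "session_type", "exercise_idx", .DESC_COLS)
  metric_cols <- setdiff(names(records)[vapply(records, is.numeric, TRUE)],
                         reserved)
  fun <- resolve_aggregation(metric_cols, spec)

  out <- data.frame(player_id = records$player_id[ukey],
                    date = records$date[ukey],
                    stringsAsFactors = FALSE)
  sum_cols <- names(fun)[fun == "sum"]
  if (length(sum_cols) > 0) {
    s <- rowsum(as.matrix(records[, sum_cols, drop = FALSE]), g, reorder = FALSE)
    dimnames(s) <- list(NULL, sum_cols)
    out[sum_cols] <- as.data.frame(s)
  }
  cnt <- as.vector(rowsum(rep(1, nrow(records)), g, reorder = FALSE))
  mean_cols <- names(fun)[fun == "mean"]
  if (length(mean_cols) > 0) {
    s <- rowsum(as.matrix(records[, mean_cols, drop = FALSE]), g, reorder = FALSE)
    dimnames(s) <- list(NULL, mean_cols)
    out[mean_cols] <- as.data.frame(s / cnt)
  }
  max_cols <- names(fun)[fun == "max"]
  if (length(max_cols) > 0) {
    idx <- split(seq_len(nrow(records)), g)
    for (cc in max_cols) {
      v <- records[[cc]]
      out[[cc]] <- vapply(idx, function(ii) max(v[ii]), numeric(1))
    }
  }

  out$n_exercises <- cnt
  if ("duration_min" %in% names(records)) {
    out$duration_min <- as.vector(
      rowsum(records$duration_min, g, reorder = FALSE))
  }
  # Day identity: match dominates training when both appear
  idx <- split(seq_len(nrow(records)), g)
  st <- vapply(idx, function(ii) {
    tt <- records$session_type[ii]
    if (any(tt == "match")) "match" else tt[1]
  }, character(1))
  out$session_type <- st
  first_of <- function(col) {
    v <- records[[col]]
    vapply(idx, function(ii) {
      vv <- v[ii][!is.na(v[ii])]
      if (length(vv) > 0) as.character(vv[1]) else NA_character_
    }, character(1))
  }
  for (cc in intersect(c("position", "corridor", "day_of_week"), names(records))) {
    out[[cc]] <- first_of(cc)
  }
  if ("age_months" %in% names(records)) {
    out$age_months <- vapply(idx, function(ii) max(records$age_months[ii]),
                             numeric(1))
  }
  for (cc in intersect(c("match_result", "match_location", "match_competition"),
                       names(records))) {
    v <- first_of(cc)
    v[st != "match"] <- NA_character_
    out[[cc]] <- v
  }

  out$injury <- 0L
  if (!is.null(injury_log) && nrow(injury_log) > 0) {
    out$injury <- as.integer(paste(out$player_id, out$date) %in%
                               paste(injury_log$player_id, injury_log$date))
  }
  out <- out[order(out$player_id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop GPS-quality and invalid metric columns
#'
#' Removes columns whose names match any of the given patterns
#' (case-insensitive; by default the satellite-count and HDOP quality
#' indicators) and columns that carry no usable data (entirely missing, or
#' numeric with no finite value).
#'
#' @param table player-day data.frame.
#' @param drop_patterns character vector of name patterns (regular
#'   expressions).
#' @return the table without the dropped columns; removed names in
#'   `attr(, "dropped")`.
#' @export
drop_invalid_metrics <- function(table, drop_patterns = c("hdop", "satellite")) {
  if (length(drop_patterns) == 0L) stop("`drop_patterns` must be nonempty", call. = FALSE)
  candidates <- setdiff(names(table), .KEY_COLS)
  by_name <- candidates[Reduce(`|`, lapply(drop_patterns, function(p) {
    grepl(p, candidates, ignore.case = TRUE)
  }))]
  invalid <- candidates[vapply(candidates, function(cc) {
    v <- table[[cc]]
    all(is.na(v)) || (is.numeric(v) && !any(is.finite(v)))
  }, logical(1))]
  drop <- union(by_name, invalid)
  keep <- setdiff(names(table), drop)
  if (length(setdiff(keep, .KEY_COLS)) == 0L) {
    stop("all feature columns would be dropped", call. = FALSE)
  }
  out <- table[, keep, drop = FALSE]
  attr(out, "dropped") <- drop
  out
}

#' Insert all-zero dummy days for a continuous per-player calendar
#'
#' Every player receives exactly one row for every calendar day in
#' `[calendar_start, calendar_end]`. Days without a session are filled with
#' dummy rows: zero for every numeric variable and blank (`NA`) for every
#' categorical one --- a record denoting a day with no physical activity ---
#' with `is_dummy = 1` and `injury = 0`. The zeroing deliberately includes
#' descriptive numerics such as age, giving the models an unambiguous
#' no-activity signature at the cost of physically meaningful values on rest
#' days.
#'
#' @param table player-day data.frame with unique (`player_id`, `date`) keys.
#' @param calendar_start,calendar_end dates bounding the common calendar;
#'   default to the table's date range.
#' @return the table with dummy rows added and an `is_dummy` column, ordered
#'   by player then date.
#' @export
insert_dummy_days <- function(table,
                              calendar_start = min(table$date),
                              calendar_end = max(table$date)) {
  if (calendar_start > calendar_end) {
    stop("`calendar_start` must not exceed `calendar_end`", call. = FALSE)
  }
  key <- paste(table$player_id, table$date)
  if (anyDuplicated(key)) stop("duplicate (player_id, date) keys", call. = FALSE)
  table$is_dummy <- 0L
  days <- seq(as.Date(calendar_start), as.Date(calendar_end), by = "day")
  players <- unique(table$player_id)
  grid_key <- as.vector(outer(players, as.character(days), paste))
  missing_key <- setdiff(grid_key, key)
  if (length(missing_key) > 0) {
    parts <- regmatches(missing_key, regexpr(" ", missing_key), invert = TRUE)
    dummy <- data.frame(
      player_id = vapply(parts, `[`, "", 1L),
      date = as.Date(vapply(parts, `[`, "", 2L)),
      stringsAsFactors = FALSE)
    for (cc in setdiff(names(table), c("player_id", "date"))) {
      dummy[[cc]] <- if (is.numeric(table[[cc]])) 0 else NA_character_
    }
    dummy$is_dummy <- 1L
    dummy$injury <- 0L
    table <- rbind(table, dummy[, names(table)])
  }
  table <- table[order(table$player_id, table$date), , drop = FALSE]
  rownames(table) <- NULL
  table
}

#' One-hot encode the categorical descriptive variables
#'
#' Each categorical field is replaced by one 0/1 indicator column per
#' observed level (no level is dropped), so an indicator group sums to 1 on
#' rows where the field is present and to 0 on dummy rows, where categoricals
#' are blank. Level sets can be supplied to encode new data against a fixed
#' schema; values outside the supplied levels produce all-zero indicators
#' with a warning.
#'
#' @param table player-day data.frame.
#' @param categorical_fields character vector of column names to encode;
#'   defaults to the character columns present.
#' @param levels optional named list of level vectors per field.
#' @return the table with indicator columns (named `field.level`) in place of
#'   the categorical ones; the level schema in `attr(, "encoding")`.
#' @export
encode_descriptive <- function(table,
                               categorical_fields = NULL,
                               levels = NULL) {
  if (is.null(categorical_fields)) {
    categorical_fields <- setdiff(
      names(table)[vapply(table, is.character, TRUE)], .KEY_COLS)
  }
  miss <- setdiff(categorical_fields, names(table))
  if (length(miss) > 0) {
    stop(sprintf("categorical fields not present: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  schema <- list()
  for (field in categorical_fields) {
    v <- table[[field]]
    lv <- if (!is.null(levels[[field]])) levels[[field]] else sort(unique(v[!is.na(v)]))
    unseen <- setdiff(unique(v[!is.na(v)]), lv)
    if (length(unseen) > 0) {
      warning(sprintf("unseen level(s) in `%s`: %s (encoded as all-zero)",
                      field, paste(unseen, collapse = ", ")), call. = FALSE)
    }
    ind <- vapply(lv, function(l) as.numeric(!is.na(v) & v == l),
                  numeric(nrow(table)))
    if (nrow(table) == 1L) ind <- matrix(ind, nrow = 1L)
    colnames(ind) <- paste(field, gsub("[^A-Za-z0-9]+", "_", lv), sep = ".")
    pos <- match(field, names(table))
    table <- cbind(table[, seq_len(pos - 1L), drop = FALSE],
                   as.data.frame(ind),
                   table[, setdiff(seq_along(table), seq_len(pos)), drop = FALSE])
    schema[[field]] <- lv
  }
  attr(table, "encoding") <- schema
  table
}

#' Full preparation chain: sessions to a numeric player-day table
#'
#' Aggregation, quality-column dropping, dummy-day insertion over the global
#' season calendar (one continuous time scale shared by all players) and
#' one-hot encoding, in that order.
#'
#' @inheritParams aggregate_sessions
#' @inheritParams drop_invalid_metrics
#' @param calendar_start,calendar_end global calendar range; default to the
#'   session date range.
#' @return a fully numeric player-day data.frame with `is_dummy` and
#'   `injury` columns.
#' @export
prepare_player_days <- function(records, injury_log = NULL,
                                spec = aggregation_spec(),
                                drop_patterns = c("hdop", "satellite"),
                                calendar_start = min(records$date),
                                calendar_end = max(records$date)) {
  table <- aggregate_sessions(records, spec, injury_log)
  table <- drop_invalid_metrics(table, drop_patterns)
  table <- insert_dummy_days(table, calendar_start, calendar_end)
  encode_descriptive(table)
}

#' @rdname player_day_io
#' @export
write_player_day_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Player-day table CSV reader/writer
#'
#' ISO-8601 dates, blank for missing; reading restores column types (`date`
#' as `Date`, indicators numeric).
#'
#' @param table player-day data.frame.
#' @param path file path.
#' @name player_day_io
#' @export
read_player_day_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                       check.names = FALSE,
                       colClasses = c(player_id = "character"))
  x$date <- as.Date(x$date)
  x
}
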