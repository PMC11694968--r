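#' Fit adaptive winsorization bounds on injured players' records
#'
#' For each metric the clipping bounds are placed an adaptive whole number of
#' standard deviations away from the median:
#' `L = median - (floor(|min|/sd) + 1) * sd` and
#' `U = median + (floor(|max|/sd) + 1) * sd`,
#' with median, sample standard deviation, minimum and maximum computed from
#' injured records only --- injury events can legitimately sit at abnormal
#' load values, and those values must not be treated as outliers. By
#' construction each bound keeps at least one standard deviation of room
#' around the median. The absolute values in the floor terms keep the bounds
#' on the correct side of the median even for negative extrema (raw GPS
#' metrics are nonnegative, so that branch is rarely exercised). Metrics with
#' zero standard deviation are marked no-clip.
#'
#' @param injured_rows player-day data.frame restricted to `injury == 1`.
#' @param cols metric columns to fit; default all feature columns.
#' @return a `winsor_bounds` data.frame with one row per metric: `metric`,
#'   `median`, `sd`, `min`, `max`, `lower`, `upper`, `clip`.
#' @export
fit_winsor_bounds <- function(injured_rows, cols = feature_cols(injured_rows)) {
  if (nrow(injured_rows) == 0L) {
    stop("no injured records: winsorization bounds are undefined", call. = FALSE)
  }
  stats_per <- lapply(cols, function(cc) {
    x <- injured_rows[[cc]]
    med <- stats::median(x)
    s <- sample_sd(x)
    mn <- min(x)
    mx <- max(x)
    if (s > 0) {
      lower <- med - (floor(abs(mn) / s) + 1) * s
      upper <- med + (floor(abs(mx) / s) + 1) * s
      clip <- TRUE
    } else {
      lower <- med
      upper <- med
      clip <- FALSE
    }
    data.frame(metric = cc, median = med, sd = s, min = mn, max = mx,
               lower = lower, upper = upper, clip = clip,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, stats_per)
  rownames(out) <- NULL
  class(out) <- c("winsor_bounds", "data.frame")
  out
}

#' Clip a player-day table into its winsorization bounds
#'
#' Values below a metric's lower bound are replaced by the bound, values
#' above the upper bound by the upper bound, everything else is untouched.
#' Although the bounds come from injured records only, clipping is applied to
#' all records, injured or not (dummy-day zeros included). Metrics marked
#' no-clip pass through.
#'
#' @param table player-day data.frame.
#' @param bounds a [fit_winsor_bounds()] result covering columns of `table`.
#' @return the table with clipped metric columns.
#' @export
winsorize <- function(table, bounds) {
  missing_cols <- setdiff(bounds$metric, names(table))
  if (length(missing_cols) > 0) {
    stop(sprintf("bounds refer to unknown column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (i in which(bounds$clip)) {
    cc <- bounds$metric[i]
    table[[cc]] <- pmin(pmax(table[[cc]], bounds$lower[i]), bounds$upper[i])
  }
  table
}

#' Fit a per-column z-score standardizer
#'
#' Records each column's arithmetic mean and sample standard deviation on the
#' fitting table (conventionally the full winsorized table, dummy rows
#' included). Columns with zero standard deviation are flagged
#' non-transformable and pass through [standardize()] unchanged.
#'
#' @param table player-day data.frame.
#' @param cols columns to fit; default all feature columns.
#' @return a `standardizer` data.frame: `metric`, `mean`, `sd`, `transform`.
#' @export
fit_standardizer <- function(table, cols = feature_cols(table)) {
  if (nrow(table) == 0L) stop("empty table", call. = FALSE)
  out <- data.frame(
    metric = cols,
    mean = vapply(cols, function(cc) mean(table[[cc]]), numeric(1)),
    sd = vapply(cols, function(cc) sample_sd(table[[cc]]), numeric(1)),
    stringsAsFactors = FALSE)
  out$transform <- out$sd > 0
  rownames(out) <- NULL
  class(out) <- c("standardizer", "data.frame")
  out
}

#' Apply a fitted standardizer
#'
#' Transforms each covered column to `(x - mean) / sd`; on the fitting table
#' this yields mean 0 and standard deviation 1. Flagged constant columns are
#' returned unchanged.
#'
#' @param table player-day data.frame.
#' @param s a [fit_standardizer()] result.
#' @return the standardized table; skipped constant columns in
#'   `attr(, "constant")`.
#' @export
standardize <- function(table, s) {
  missing_cols <- setdiff(s$metric, names(table))
  if (length(missing_cols) > 0) {
    stop(sprintf("standardizer refers to unknown column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (i in which(s$transform)) {
    cc <- s$metric[i]
    table[[cc]] <- (table[[cc]] - s$mean[i]) / s$sd[i]
  }
  attr(table, "constant") <- s$metric[!s$transform]
  table
}

#' Winsorize and standardize a prepared player-day table
#'
#' The faithful protocol: bounds fitted on the complete table's injured rows,
#' clipping applied to every record, then standardization fitted on the full
#' winsorized table --- all before any train/test split. A leakage-free
#' variant (refitting inside training folds) is available through the
#' evaluation harness.
#'
#' @param table prepared numeric player-day data.frame with an `injury`
#'   column.
#' @param cols feature columns to transform.
#' @return list with the transformed `table`, the `bounds` and the
#'   `standardizer`.
#' @export
preprocess_features <- function(table, cols = feature_cols(table)) {
  bounds <- fit_winsor_bounds(table[table$injury == 1, , drop = FALSE], cols)
  table <- winsorize(table, bounds)
  s <- fit_standardizer(table, cols)
  list(table = standardize(table, s), bounds = bounds, standardizer = s)
}

#' @rdname preprocess_io
#' @export
write_winsor_bounds_json <- function(bounds, path) {
  jsonlite::write_json(as.data.frame(bounds), path, digits = NA)
  invisible(path)
}

#' JSON persistence of preprocessing parameters
#'
#' Winsorization bounds and standardizer parameters round-trip through JSON
#' for reproducibility of a fitted pipeline.
#'
#' @param bounds,s fitted objects.
#' @param path file path.
#' @name preprocess_io
#' @export
read_winsor_bounds_json <- function(path) {
  x <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  class(x) <- c("winsor_bounds", "data.frame")
  x
}

#' @rdname preprocess_io
#' @export
write_standardizer_json <- function(s, path) {
  jsonlite::write_json(as.data.frame(s), path, digits = NA)
  invisible(path)
}

#' @rdname preprocess_io
#' @export
read_standardizer_json <- function(path) {
  x <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  class(x) <- c("standardizer", "data.frame")
  x
}
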