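#' injurycast: daily noncontact-injury prediction from GPS training load
#'
#' End-to-end pipeline: synthetic season generation, exercise-to-day
#' aggregation with dummy days, injured-only adaptive winsorization and
#' standardization, mRMR feature ranking, cost-sensitive classifiers with
#' k-means centroid undersampling, player-disjoint two-fold validation with
#' ROC-elbow thresholds, and GMEAN-based model selection.
#'
#' @keywords internal
"_PACKAGE"

# Columns of a player-day table that are never features.
.KEY_COLS <- c("player_id", "date", "is_dummy", "injury")

#' Derive a reproducible child seed from a base seed and a label
#'
#' Any single run of the sweep harness can be re-derived in isolation by
#' hashing the base seed together with its coordinate labels. The hash is a
#' simple polynomial rolling hash kept below 2^31 so it is a valid R seed.
#'
#' @param seed integer base seed.
#' @param ... labels (character or numeric scalars) identifying the run.
#' @return a single integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, ...) {
  label <- paste(c(seed, ...), collapse = "|")
  h <- 0
  m <- 2147483647
  for (code in utf8ToInt(label)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# Names of the numeric feature columns of a player-day table.
feature_cols <- function(table) {
  setdiff(names(table), .KEY_COLS)
}

# Numeric feature matrix of a player-day table (post-encoding).
feature_matrix <- function(table, cols = feature_cols(table)) {
  as.matrix(table[, cols, drop = FALSE])
}

# Stop unless x is a single finite number.
assert_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

# Sample standard deviation that returns 0 (not NA) for length-1 input.
sample_sd <- function(x) {
  if (length(x) < 2L) return(0)
  stats::sd(x)
}
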