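#' Remove constant (zero-variance) feature columns
#'
#' Exactly the columns whose values are all identical are dropped; they carry
#' no information and break correlation-based ranking.
#'
#' @param table player-day data.frame.
#' @param cols candidate columns; default all feature columns.
#' @return the table without constant columns; removed names in
#'   `attr(, "removed")`.
#' @export
drop_zero_variance <- function(table, cols = feature_cols(table)) {
  constant <- cols[vapply(cols, function(cc) {
    v <- table[[cc]]
    all(v == v[1])
  }, logical(1))]
  if (length(constant) == length(cols)) {
    stop("all feature columns are constant", call. = FALSE)
  }
  out <- table[, setdiff(names(table), constant), drop = FALSE]
  attr(out, "removed") <- constant
  out
}

# One-way ANOVA F statistic of each column of X against binary y,
# vectorized across columns.
.f_relevance <- function(X, y) {
  n <- nrow(X)
  g1 <- y == 1
  n1 <- sum(g1)
  n0 <- n - n1
  m1 <- colMeans(X[g1, , drop = FALSE])
  m0 <- colMeans(X[!g1, , drop = FALSE])
  m <- colMeans(X)
  ssb <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
  ssw <- colSums(sweep(X[g1, , drop = FALSE], 2, m1)^2) +
    colSums(sweep(X[!g1, , drop = FALSE], 2, m0)^2)
  ssb / (ssw / (n - 2))
}

# Equal-width binning mutual information helpers for the "miq" variant.
.discretize <- function(x, bins) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(1L, length(x)))
  cut(x, breaks = seq(r[1], r[2], length.out = bins + 1L),
      include.lowest = TRUE, labels = FALSE)
}

.mi <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p)
  pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
}

#' Greedy minimum-redundancy maximum-relevance feature ranking
#'
#' Ranks features by greedy mRMR: the first feature maximizes relevance to
#' the binary label; every subsequent feature maximizes the quotient of its
#' relevance and its mean redundancy with the already-selected set. The
#' default `"fcq"` variant scores relevance by the one-way ANOVA F statistic
#' and redundancy by mean absolute Pearson correlation, the natural choice
#' for continuous features (the mutual-information original presumes discrete
#' variables); `"miq"` is the mutual-information quotient with equal-width
#' binning. Ties break lexicographically by feature name, making the ranking
#' fully deterministic; the first feature's redundancy is 0 and the quotient
#' guards division with `max(redundancy, 1e-12)`.
#'
#' @param X numeric feature matrix (no zero-variance columns).
#' @param y binary 0/1 label vector.
#' @param n_rank how many features to rank; default all.
#' @param method `"fcq"` (default) or `"miq"`.
#' @param bins bin count for `"miq"` discretization.
#' @return a `feature_ranking` data.frame: `rank`, `name`, `relevance`,
#'   `redundancy`, `score`.
#' @export
mrmr_rank <- function(X, y, n_rank = ncol(X),
                      method = c("fcq", "miq"), bins = 10L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (length(unique(y)) < 2L) stop("`y` must contain both classes", call. = FALSE)
  if (n_rank < 1L || n_rank > ncol(X)) {
    stop("`n_rank` outside the feature count", call. = FALSE)
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance columns present; apply drop_zero_variance() first",
         call. = FALSE)
  }
  nm <- colnames(X)
  eps <- 1e-12

  if (method == "fcq") {
    rel <- .f_relevance(X, y)
    red_mat <- abs(stats::cor(X))
  } else {
    D <- apply(X, 2, .discretize, bins = bins)
    rel <- apply(D, 2, .mi, b = y)
    red_mat <- matrix(NA_real_, ncol(X), ncol(X))  # filled lazily
  }
  names(rel) <- nm

  selected <- integer(0)
  rows <- vector("list", n_rank)
  remaining <- seq_len(ncol(X))
  for (step in seq_len(n_rank)) {
    if (step == 1L) {
      red <- rep(0, length(remaining))
    } else if (method == "fcq") {
      red <- colMeans(red_mat[selected, remaining, drop = FALSE])
    } else {
      red <- vapply(remaining, function(j) {
        for (s in selected) {
          if (is.na(red_mat[s, j])) {
            red_mat[s, j] <<- red_mat[j, s] <<- .mi(D[, s], D[, j])
          }
        }
        mean(red_mat[selected, j])
      }, numeric(1))
    }
    score <- rel[remaining] / pmax(red, eps)
    crit <- if (step == 1L) rel[remaining] else score
    best <- remaining[order(-crit, nm[remaining])[1L]]
    pos <- match(best, remaining)
    rows[[step]] <- data.frame(
      rank = step, name = nm[best], relevance = unname(rel[best]),
      redundancy = unname(red[pos]), score = unname(score[pos]),
      stringsAsFactors = FALSE)
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "method") <- method
  class(out) <- c("feature_ranking", "data.frame")
  out
}

#' First p features of an mRMR ranking
#'
#' Top-p subsets are nested by construction: `top_p(r, p1)` is a prefix of
#' `top_p(r, p2)` whenever `p1 < p2`, which is what makes the wrapper sweep
#' over the p-grid cheap.
#'
#' @param ranking a [mrmr_rank()] result.
#' @param p subset size, `1 <= p <= nrow(ranking)`.
#' @return character vector of the first `p` feature names.
#' @export
top_p <- function(ranking, p) {
  if (p <= 0L) stop("`p` must be positive", call. = FALSE)
  if (p > nrow(ranking)) stop("`p` exceeds the ranked feature count", call. = FALSE)
  ranking$name[seq_len(p)]
}

#' @rdname ranking_io
#' @export
write_ranking_csv <- function(ranking, path) {
  utils::write.csv(as.data.frame(ranking), path, row.names = FALSE)
  invisible(path)
}

#' Feature-ranking CSV export/import
#'
#' Columns `rank`, `name`, `relevance`, `redundancy`, `score`.
#'
#' @param ranking a [mrmr_rank()] result.
#' @param path file path.
#' @name ranking_io
#' @export
read_ranking_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(x) <- c("feature_ranking", "data.frame")
  x
}
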