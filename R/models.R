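#' Classifier specification with the pipeline's default hyperparameters
#'
#' Defaults follow the pipeline's reference settings: an RBF-kernel SVM with
#' squared-L2 regularization (`cost = 1`) and Platt-scaled probabilities; a
#' feedforward network with one hidden layer of 10 tanh units, dropout
#' probability 0.6 before the sigmoid output, 20 epochs of Adam at learning
#' rate 0.001 with class-weighted binary cross-entropy and a squared-L2
#' penalty; and an AdaBoost ensemble of at most 50 one-level decision stumps.
#' Any override of a default is reported with a message.
#'
#' @param kind `"svm"`, `"fnn"` or `"adaboost"`.
#' @param cost_sensitive logical; when `TRUE`, class weights inversely
#'   proportional to class frequencies enter the fit, otherwise both classes
#'   weigh 1.
#' @param seed integer seed for the stochastic parts of training.
#' @param ... hyperparameter overrides (svm: `cost`; fnn: `hidden_units`,
#'   `dropout`, `epochs`, `learning_rate`, `batch_size`, `l2`, `loss`
#'   (`"bce"` or `"squared"`); adaboost: `max_stumps`).
#' @return a `model_spec` list.
#' @export
model_spec <- function(kind = c("svm", "fnn", "adaboost"),
                       cost_sensitive = TRUE, seed = 1L, ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    svm = list(cost = 1.0),
    fnn = list(hidden_units = 10L, dropout = 0.6, epochs = 20L,
               learning_rate = 0.001, batch_size = 32L, l2 = 1e-4,
               loss = "bce"),
    adaboost = list(max_stumps = 50L))
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop(sprintf("unknown hyperparameter(s) for %s: %s", kind,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (length(overrides) > 0) {
    message(sprintf("model_spec(%s): overriding %s", kind,
                    paste(names(overrides), collapse = ", ")))
    defaults[names(overrides)] <- overrides
  }
  structure(list(kind = kind, cost_sensitive = cost_sensitive,
                 seed = as.integer(seed), hyper = defaults),
            class = "model_spec")
}

#' Class weights inversely proportional to class frequencies
#'
#' In cost-sensitive mode class `c` weighs `N / (2 * n_c)`, so the rarer
#' class (injury) carries proportionally more cost; traditional
#' (cost-insensitive) mode weighs both classes 1.
#'
#' @param y binary 0/1 label vector.
#' @param cost_sensitive logical.
#' @return named numeric vector `c("0" = w0, "1" = w1)`.
#' @export
#' @examples
#' compute_class_weights(rep(c(0, 1), c(90, 10)))  # 0.5556, 5
compute_class_weights <- function(y, cost_sensitive = TRUE) {
  if (!cost_sensitive) return(c("0" = 1, "1" = 1))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("cost-sensitive weights need both classes present", call. = FALSE)
  }
  n <- n0 + n1
  c("0" = n / (2 * n0), "1" = n / (2 * n1))
}

#' Configuration for k-means centroid undersampling
#'
#' @param ratio target injured:noninjured ratio after resampling; the
#'   noninjured class is compressed to `round(n_injured / ratio)` centroids.
#' @param k cluster-count metadata recorded with the configuration; with
#'   `use_k = TRUE` exactly `k` centroids are requested instead of the
#'   ratio-driven count.
#' @param use_k logical, see `k`.
#' @param seed integer seed for the k-means initialization.
#' @return an `undersample_config` list.
#' @export
undersample_config <- function(ratio = 0.40, k = 8L, use_k = FALSE, seed = 1L) {
  if (ratio <= 0 || ratio > 1) stop("`ratio` must be in (0, 1]", call. = FALSE)
  structure(list(ratio = ratio, k = as.integer(k), use_k = use_k,
                 seed = as.integer(seed)),
            class = "undersample_config")
}

#' Undersample noninjured records by k-means centroids
#'
#' Injured rows are kept verbatim; the noninjured feature rows are replaced
#' by the centroids of a k-means clustering of the noninjured feature matrix,
#' labelled 0. The centroid count comes from the configured
#' injured:noninjured ratio. If the requested centroid count reaches the
#' available (distinct) noninjured rows, the table passes through unchanged
#' with a warning.
#'
#' @param train player-day data.frame with an `injury` column.
#' @param cfg an [undersample_config()].
#' @param cols feature columns; default all.
#' @return the resampled table; centroid rows carry synthetic
#'   `player_id = "centroid_<i>"` keys.
#' @export
kmeans_undersample <- function(train, cfg = undersample_config(),
                               cols = feature_cols(train)) {
  inj <- train[train$injury == 1, , drop = FALSE]
  non <- train[train$injury == 0, , drop = FALSE]
  if (nrow(inj) == 0L || nrow(non) == 0L) {
    stop("undersampling needs both classes in the training data", call. = FALSE)
  }
  n_centroids <- if (cfg$use_k) cfg$k else round(nrow(inj) / cfg$ratio)
  M <- feature_matrix(non, cols)
  n_distinct <- nrow(unique(M))
  if (n_centroids >= nrow(non) || n_centroids > n_distinct) {
    warning("requested centroid count >= available noninjured rows; passing through",
            call. = FALSE)
    return(train)
  }
  set.seed(derive_seed(cfg$seed, "kmeans_undersample"))
  km <- stats::kmeans(M, centers = n_centroids, iter.max = 100L, nstart = 1L)
  cent <- as.data.frame(km$centers)
  out <- inj[, c("player_id", "date", intersect(c("is_dummy"), names(train)),
                 cols, "injury"), drop = FALSE]
  crow <- data.frame(player_id = sprintf("centroid_%03d", seq_len(n_centroids)),
                     date = as.Date(NA), stringsAsFactors = FALSE)
  if ("is_dummy" %in% names(out)) crow$is_dummy <- 0L
  crow <- cbind(crow, cent)
  crow$injury <- 0L
  out <- rbind(out, crow[, names(out)])
  rownames(out) <- NULL
  out
}

#' Train a classifier on a standardized feature matrix
#'
#' Dispatches on the specification kind. Class weights (see
#' [compute_class_weights()]) enter each model the way its algorithm admits
#' cost sensitivity: scaling the per-class margin penalty for the SVM,
#' weighting the per-sample loss for the network, and setting the initial
#' sample weights of the boosting loop so misclassified injury records gain
#' influence faster. Training is deterministic given the spec's seed.
#'
#' @param spec a [model_spec()].
#' @param X numeric feature matrix with column names (standardized).
#' @param y binary 0/1 labels.
#' @param weights optional class weights; computed from `spec$cost_sensitive`
#'   and `y` when omitted.
#' @return a `trained_classifier` object for [predict_proba()].
#' @export
train_classifier <- function(spec, X, y, weights = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite feature values", call. = FALSE)
  if (length(unique(y)) < 2L) stop("training labels are single-class", call. = FALSE)
  if (is.null(weights)) weights <- compute_class_weights(y, spec$cost_sensitive)

  fit <- switch(spec$kind,
    svm = svm_platt_fit(X, y, weights, cost = spec$hyper$cost,
                        seed = spec$seed),
    fnn = fnn_fit(X, y, weights,
                  hidden_units = spec$hyper$hidden_units,
                  dropout = spec$hyper$dropout,
                  epochs = spec$hyper$epochs,
                  learning_rate = spec$hyper$learning_rate,
                  batch_size = spec$hyper$batch_size,
                  l2 = spec$hyper$l2, loss = spec$hyper$loss,
                  seed = spec$seed),
    adaboost = adaboost_fit(X, y, weights,
                            max_stumps = spec$hyper$max_stumps))
  structure(list(kind = spec$kind, fit = fit, features = colnames(X),
                 spec = spec),
            class = "trained_classifier")
}

#' Predicted injury probabilities
#'
#' Maps feature rows to probabilities strictly inside (0, 1): Platt-scaled
#' decision values for the SVM, the sigmoid output unit for the network, and
#' the logistic transform of the (doubled) weighted stump vote for AdaBoost.
#'
#' @param model a [train_classifier()] result.
#' @param X feature matrix whose columns cover the training schema.
#' @return numeric vector of probabilities, one per row of `X`.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "trained_classifier"))
  X <- as.matrix(X)
  if (!all(model$features %in% colnames(X))) {
    stop("feature schema mismatch with the trained model", call. = FALSE)
  }
  X <- X[, model$features, drop = FALSE]
  p <- switch(model$kind,
    svm = svm_platt_predict(model$fit, X),
    fnn = fnn_predict(model$fit, X),
    adaboost = adaboost_predict(model$fit, X))
  unname(pmin(pmax(p, 1e-9), 1 - 1e-9))
}
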