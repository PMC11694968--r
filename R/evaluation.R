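#' Player-disjoint two-fold split stratified on injured players
#'
#' Players injured at least once are shuffled (seeded) and split in half.
#' Fold f's training rows are those of one injured half; its testing rows are
#' the other injured half's rows plus every never-injured player's rows. The
#' split is subject-independent --- each player's rows sit entirely on one
#' side of each fold --- every training player carries at least one injury,
#' and the two folds' training player sets partition the injured players.
#'
#' @param table player-day data.frame with `player_id` and `injury`.
#' @param seed integer seed for the injured-player shuffle.
#' @return list of two folds, each with `fold`, `train_players`,
#'   `test_players`, `train_idx`, `test_idx`.
#' @export
make_folds <- function(table, seed = 1L) {
  injured_players <- sort(unique(table$player_id[table$injury == 1]))
  if (length(injured_players) < 2L) {
    stop("need at least 2 injured players to build folds", call. = FALSE)
  }
  clean_players <- setdiff(unique(table$player_id), injured_players)
  set.seed(seed)
  shuffled <- sample(injured_players)
  half <- ceiling(length(shuffled) / 2)
  half_a <- sort(shuffled[seq_len(half)])
  half_b <- sort(shuffled[-seq_len(half)])
  fold_of <- function(f, train_p, other_p) {
    test_p <- sort(c(other_p, clean_players))
    list(fold = f,
         train_players = train_p,
         test_players = test_p,
         train_idx = which(table$player_id %in% train_p),
         test_idx = which(table$player_id %in% test_p))
  }
  list(fold_of(1L, half_a, half_b), fold_of(2L, half_b, half_a))
}

#' ROC-elbow threshold: the operating point nearest the top-left corner
#'
#' Candidate thresholds are the distinct predicted scores plus a supremum
#' point above the largest score (the all-negative classifier); a score is
#' called positive when it is at or above the threshold. The returned
#' threshold minimizes the Euclidean distance
#' `sqrt((1 - sensitivity)^2 + FPR^2)` to the ideal corner; ties resolve to
#' the lower threshold, favoring sensitivity --- missing an injury costs more
#' than a false alarm.
#'
#' @param y_true binary 0/1 labels.
#' @param scores predicted probabilities in (0, 1).
#' @return the selected threshold (a numeric scalar).
#' @export
elbow_threshold <- function(y_true, scores) {
  if (length(unique(y_true)) < 2L) {
    stop("both classes are needed to trace a ROC curve", call. = FALSE)
  }
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  cand <- sort(unique(scores))
  cand <- c(cand, cand[length(cand)] + 1)
  best_thr <- NA_real_
  best_d <- Inf
  for (thr in cand) {
    pred <- as.numeric(scores >= thr)
    sens <- sum(pred == 1 & y_true == 1) / n_pos
    fpr <- sum(pred == 1 & y_true == 0) / n_neg
    d <- sqrt((1 - sens)^2 + fpr^2)
    if (d < best_d - 1e-12) {
      best_d <- d
      best_thr <- thr
    }
  }
  best_thr
}

#' Confusion-matrix metrics for binary predictions
#'
#' Sensitivity is the proportion of injuries identified correctly
#' (`TP / (TP + FN)`), specificity the proportion of noninjuries identified
#' correctly (`TN / (TN + FP)`), accuracy the overall agreement. A metric
#' whose denominator class is absent is returned as `NA` with its name
#' listed in `undefined`, never as a silent zero.
#'
#' @param y_true,y_pred binary 0/1 vectors of equal length.
#' @return list with `sensitivity`, `specificity`, `accuracy`, the confusion
#'   counts, and `undefined`.
#' @export
confusion_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` differ in length", call. = FALSE)
  }
  tp <- sum(y_true == 1 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  undefined <- character(0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else { undefined <- c(undefined, "sensitivity"); NA_real_ }
  spec <- if (tn + fp > 0) tn / (tn + fp) else { undefined <- c(undefined, "specificity"); NA_real_ }
  list(sensitivity = sens, specificity = spec,
       accuracy = (tp + tn) / length(y_true),
       tp = tp, fp = fp, tn = tn, fn = fn, undefined = undefined)
}

#' Geometric mean of sensitivity and specificity
#'
#' `GMEAN = sqrt(sensitivity * specificity)`: the balanced selection
#' criterion for imbalanced classification. It is 0 whenever either input is
#' 0 and never exceeds the arithmetic mean.
#'
#' @param sensitivity,specificity proportions in `[0, 1]`.
#' @return a proportion in `[0, 1]`.
#' @export
#' @examples
#' gmean(0.7857, 0.6502)  # 0.7147...
gmean <- function(sensitivity, specificity) {
  if (any(!is.finite(c(sensitivity, specificity))) ||
      sensitivity < 0 || sensitivity > 1 || specificity < 0 || specificity > 1) {
    stop("inputs must be proportions in [0, 1]", call. = FALSE)
  }
  sqrt(sensitivity * specificity)
}

#' Rank-based AUC (ties averaged)
#'
#' The Mann-Whitney estimate: the probability that a random injury record
#' scores above a random noninjury record, counting ties as one half.
#'
#' @param y_true binary 0/1 labels containing both classes.
#' @param scores numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(y_true, scores) {
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes are required for AUC", call. = FALSE)
  r <- rank(scores)
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate scores on a split with a fixed threshold
#'
#' Applies the threshold (fitted on training data) to the split's scores and
#' assembles the metric suite: sensitivity, specificity, accuracy, AUC and
#' GMEAN, plus the threshold used. GMEAN is `NA` when either ingredient is
#' undefined for the split.
#'
#' @param y_true binary labels of the split.
#' @param scores predicted probabilities.
#' @param threshold decision threshold (scores `>=` threshold are positive).
#' @return an `eval_metrics` list.
#' @export
eval_metrics <- function(y_true, scores, threshold) {
  cm <- confusion_metrics(y_true, as.numeric(scores >= threshold))
  gm <- if (is.na(cm$sensitivity) || is.na(cm$specificity)) NA_real_ else
    gmean(cm$sensitivity, cm$specificity)
  a <- if (length(unique(y_true)) < 2L) NA_real_ else auc(y_true, scores)
  structure(list(sensitivity = cm$sensitivity, specificity = cm$specificity,
                 accuracy = cm$accuracy, auc = a, gmean = gm,
                 threshold = threshold, undefined = cm$undefined),
            class = "eval_metrics")
}
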