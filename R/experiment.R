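#' Build the modelling dataset from raw session records
#'
#' Runs the full preparation and preprocessing chain --- aggregation to
#' player-days, quality-column dropping, dummy-day insertion, one-hot
#' encoding, injured-only winsorization, standardization, zero-variance
#' filtering --- and ranks the surviving features by mRMR. This is the
#' faithful protocol: preprocessing and ranking are fitted on the complete
#' dataset before any split (the leakage-free alternative refits them inside
#' training folds, see [run_config()]).
#'
#' @param sessions exercise-level session data.frame.
#' @param injuries injury-log data.frame.
#' @param agg_spec an [aggregation_spec()].
#' @param drop_patterns quality-column name patterns to drop.
#' @param method mRMR variant passed to [mrmr_rank()].
#' @return a `pipeline_dataset` list: `prepared` (numeric player-day table
#'   before winsorization), `table` (preprocessed, zero-variance columns
#'   removed), `ranking`, `bounds`, `standardizer`.
#' @export
build_dataset <- function(sessions, injuries,
                          agg_spec = aggregation_spec(),
                          drop_patterns = c("hdop", "satellite"),
                          method = "fcq") {
  prepared <- prepare_player_days(sessions, injuries, spec = agg_spec,
                                  drop_patterns = drop_patterns)
  pp <- preprocess_features(prepared)
  nz <- drop_zero_variance(pp$table)
  ranking <- mrmr_rank(feature_matrix(nz), nz$injury, method = method)
  structure(list(prepared = prepared, table = nz, ranking = ranking,
                 bounds = pp$bounds, standardizer = pp$standardizer),
            class = "pipeline_dataset")
}

# Fold-local preprocessing and ranking for the leakage-free variant:
# winsor bounds from the fold's injured training rows, standardizer from its
# training rows, ranking from the standardized training rows.
.fold_refit <- function(prepared, fold, method = "fcq") {
  cols <- feature_cols(prepared)
  train <- prepared[fold$train_idx, , drop = FALSE]
  bounds <- fit_winsor_bounds(train[train$injury == 1, , drop = FALSE], cols)
  w_all <- winsorize(prepared, bounds)
  s <- fit_standardizer(w_all[fold$train_idx, , drop = FALSE], cols)
  table <- standardize(w_all, s)
  tr <- table[fold$train_idx, , drop = FALSE]
  keep <- cols[vapply(cols, function(cc) stats::sd(tr[[cc]]) > 0, logical(1))]
  ranking <- mrmr_rank(feature_matrix(tr, keep), tr$injury, method = method)
  list(table = table, ranking = ranking)
}

#' Run one sweep coordinate: model x learning mode x feature count
#'
#' For each repetition, injured players are reshuffled into player-disjoint
#' folds; per fold, the training split is undersampled to k-means centroids,
#' the classifier is trained on the top-p mRMR features, the ROC-elbow
#' threshold is fitted on the (full, pre-undersampling) training split, and
#' both splits are scored with that threshold. Every random ingredient is
#' seeded from `derive_seed(seed, coordinate, repetition)`, so any single run
#' is re-derivable in isolation.
#'
#' @param dataset a [build_dataset()] result.
#' @param kind classifier kind (`"svm"`, `"fnn"`, `"adaboost"`).
#' @param mode `"cost_sensitive"` or `"traditional"`.
#' @param p number of top-ranked features to use.
#' @param repetitions number of repeated shuffles.
#' @param seed base seed.
#' @param us_cfg an [undersample_config()]; its seed field is re-derived per
#'   run.
#' @param leakage_free refit preprocessing and ranking inside each training
#'   fold instead of using the whole-dataset fits.
#' @return data.frame of run records, one row per (fold, repetition), with
#'   `train_`/`test_`-prefixed metric columns.
#' @export
run_config <- function(dataset, kind, mode = "cost_sensitive", p = 20L,
                       repetitions = 1L, seed = 1L,
                       us_cfg = undersample_config(),
                       leakage_free = FALSE) {
  stopifnot(inherits(dataset, "pipeline_dataset"))
  cost_sensitive <- match.arg(mode, c("cost_sensitive", "traditional")) ==
    "cost_sensitive"
  if (!leakage_free && p > nrow(dataset$ranking)) {
    stop("`p` exceeds the number of ranked features", call. = FALSE)
  }
  records <- vector("list", repetitions * 2L)
  k <- 0L
  for (rep_i in seq_len(repetitions)) {
    rs <- derive_seed(seed, kind, mode, p, rep_i)
    folds <- make_folds(dataset$table, rs)
    for (fold in folds) {
      if (leakage_free) {
        refit <- .fold_refit(dataset$prepared, fold)
        table <- refit$table
        feats <- top_p(refit$ranking, min(p, nrow(refit$ranking)))
      } else {
        table <- dataset$table
        feats <- top_p(dataset$ranking, p)
      }
      train <- table[fold$train_idx, , drop = FALSE]
      test <- table[fold$test_idx, , drop = FALSE]

      cfg <- us_cfg
      cfg$seed <- derive_seed(rs, "undersample", fold$fold)
      res <- kmeans_undersample(train, cfg, cols = feats)
      # costs reflect the original split's imbalance, not the rebalanced
      # frequencies the undersampled set presents to the optimizer
      weights <- compute_class_weights(train$injury, cost_sensitive)
      spec <- model_spec(kind, cost_sensitive = cost_sensitive,
                         seed = derive_seed(rs, "fit", fold$fold))
      model <- train_classifier(spec, feature_matrix(res, feats), res$injury,
                                weights)

      train_scores <- predict_proba(model, feature_matrix(train, feats))
      thr <- elbow_threshold(train$injury, train_scores)
      m_train <- eval_metrics(train$injury, train_scores, thr)
      test_scores <- predict_proba(model, feature_matrix(test, feats))
      m_test <- eval_metrics(test$injury, test_scores, thr)

      k <- k + 1L
      records[[k]] <- data.frame(
        model = kind, learning = mode, p = p,
        repetition = rep_i, fold = fold$fold,
        train_sensitivity = m_train$sensitivity,
        train_specificity = m_train$specificity,
        train_accuracy = m_train$accuracy,
        train_auc = m_train$auc, train_gmean = m_train$gmean,
        test_sensitivity = m_test$sensitivity,
        test_specificity = m_test$specificity,
        test_accuracy = m_test$accuracy,
        test_auc = m_test$auc, test_gmean = m_test$gmean,
        threshold = thr, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, records[seq_len(k)])
  rownames(out) <- NULL
  out
}

#' Sweep grid over models, learning modes and feature counts
#'
#' @param models classifier kinds to sweep.
#' @param modes learning modes.
#' @param p_grid feature counts; the reference protocol uses
#'   `seq(10, 260, 10)`.
#' @param repetitions repeated shuffles per coordinate (the reference
#'   protocol uses 500; the default 25 keeps routine runs light).
#' @param seed base seed.
#' @return a `sweep_grid` list.
#' @export
sweep_grid <- function(models = c("svm", "fnn", "adaboost"),
                       modes = c("cost_sensitive", "traditional"),
                       p_grid = seq(10L, 260L, by = 10L),
                       repetitions = 25L, seed = 1L) {
  if (length(models) == 0L || length(modes) == 0L || length(p_grid) == 0L) {
    stop("empty sweep grid", call. = FALSE)
  }
  structure(list(models = models, modes = modes, p_grid = as.integer(p_grid),
                 repetitions = as.integer(repetitions),
                 seed = as.integer(seed)),
            class = "sweep_grid")
}

#' Enumerate every run a grid implies
#'
#' One row per (model, mode, p, repetition); the row count is exactly
#' `|models| * |modes| * |p_grid| * repetitions`. The reference grid of 3
#' models, 2 modes and 26 feature counts at 500 repetitions enumerates
#' 78,000 runs.
#'
#' @param grid a [sweep_grid()].
#' @return data.frame of run coordinates.
#' @export
enumerate_runs <- function(grid) {
  stopifnot(inherits(grid, "sweep_grid"))
  expand.grid(repetition = seq_len(grid$repetitions), p = grid$p_grid,
              learning = grid$modes, model = grid$models,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[
                , c("model", "learning", "p", "repetition")]
}

# Fold-averaged per-repetition metrics -> mean/SD per coordinate.
.METRICS <- c("sensitivity", "specificity", "accuracy", "auc", "gmean")

aggregate_records <- function(records) {
  cols <- c(paste0("train_", .METRICS), paste0("test_", .METRICS))
  key <- interaction(records$model, records$learning, records$p, drop = TRUE)
  out <- lapply(split(records, key), function(r) {
    per_rep <- lapply(split(r, r$repetition), function(rr) {
      colMeans(rr[, cols, drop = FALSE])
    })
    M <- do.call(rbind, per_rep)
    row <- data.frame(model = r$model[1], learning = r$learning[1],
                      p = r$p[1], n_runs = nrow(r),
                      stringsAsFactors = FALSE)
    for (cc in cols) {
      row[[paste0(cc, "_mean")]] <- mean(M[, cc])
      row[[paste0(cc, "_sd")]] <- sample_sd(M[, cc])
    }
    row
  })
  out <- do.call(rbind, out)
  out <- out[order(out$model, out$learning, out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full sweep and aggregate to mean +/- SD per coordinate
#'
#' Executes [run_config()] for every coordinate of the grid. Each
#' repetition's two folds are averaged first (the reported GMEAN is the
#' between-fold average); the table then carries the mean and standard
#' deviation of every metric over repetitions, the stability summary.
#'
#' @param dataset a [build_dataset()] result.
#' @param grid a [sweep_grid()].
#' @param ... passed on to [run_config()] (undersampling configuration,
#'   leakage mode).
#' @return aggregated sweep data.frame with the raw run records in
#'   `attr(, "records")`.
#' @export
run_sweep <- function(dataset, grid, ...) {
  runs <- enumerate_runs(grid)
  coords <- unique(runs[, c("model", "learning", "p")])
  records <- vector("list", nrow(coords))
  for (i in seq_len(nrow(coords))) {
    records[[i]] <- run_config(dataset, kind = coords$model[i],
                               mode = coords$learning[i], p = coords$p[i],
                               repetitions = grid$repetitions,
                               seed = grid$seed, ...)
  }
  records <- do.call(rbind, records)
  out <- aggregate_records(records)
  attr(out, "records") <- records
  out
}

#' Three-step best-model selection on a sweep table
#'
#' Per (model, learning) group the feature count maximizing mean training
#' GMEAN is chosen (ties resolve to the smaller p, favoring parsimony); the
#' group winners are then ranked by mean testing GMEAN, whose top row is the
#' overall best model.
#'
#' @param sweep_table an aggregated [run_sweep()] table.
#' @return list with `groups` (one chosen row per group, ordered by test
#'   GMEAN) and `best` (the overall winner row).
#' @export
select_best <- function(sweep_table) {
  if (nrow(sweep_table) == 0L) stop("empty sweep table", call. = FALSE)
  key <- interaction(sweep_table$model, sweep_table$learning, drop = TRUE)
  groups <- lapply(split(sweep_table, key), function(g) {
    g <- g[order(-g$train_gmean_mean, g$p), , drop = FALSE]
    g[1L, , drop = FALSE]
  })
  groups <- do.call(rbind, groups)
  groups <- groups[order(-groups$test_gmean_mean), , drop = FALSE]
  rownames(groups) <- NULL
  list(groups = groups, best = groups[1L, , drop = FALSE])
}

#' @rdname report_io
#' @export
write_best_model_report <- function(report, path) {
  jsonlite::write_json(list(best = report$best, groups = report$groups),
                       path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Selection-report JSON export
#'
#' @param report a [select_best()] result.
#' @param path file path.
#' @name report_io
#' @export
read_best_model_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
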