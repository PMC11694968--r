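# 2-D linearly separable toy with named columns.
separable_toy <- function(n = 40, gap = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(cbind(stats::rnorm(n / 2), stats::rnorm(n / 2)),
             cbind(stats::rnorm(n / 2) + gap, stats::rnorm(n / 2) + gap))
  colnames(X) <- c("u", "v")
  list(X = X, y = rep(c(0, 1), each = n / 2))
}

test_that("class weights are inversely proportional to frequencies", {
  expect_equal(compute_class_weights(rep(c(0, 1), each = 50)),
               c("0" = 1, "1" = 1))
  w <- compute_class_weights(rep(c(0, 1), c(90, 10)))
  expect_equal(unname(w["0"]), 0.5556, tolerance = 1e-4)
  expect_equal(unname(w["1"]), 5.0)
  expect_equal(compute_class_weights(rep(c(0, 1), c(90, 10)), cost_sensitive = FALSE),
               c("0" = 1, "1" = 1))
  expect_error(compute_class_weights(rep(1, 5)), "both classes")
})

test_that("undersampling hits the ratio-driven centroid count", {
  set.seed(3)
  n_inj <- 11
  tab <- data.frame(player_id = sprintf("P%02d", 1:150),
                    date = as.Date("2020-09-07") + 1:150,
                    a = stats::rnorm(150), b = stats::rnorm(150),
                    injury = rep(c(1L, 0L), c(n_inj, 139)))
  out <- kmeans_undersample(tab, undersample_config(ratio = 0.40, seed = 5))
  expect_equal(nrow(out), n_inj + round(n_inj / 0.40))   # 11 + 28 = 39
  expect_equal(sum(out$injury), n_inj)
  # injured rows preserved bit-exactly
  expect_equal(out[out$injury == 1, c("a", "b")],
               tab[tab$injury == 1, c("a", "b")], ignore_attr = TRUE)
  # determinism
  out2 <- kmeans_undersample(tab, undersample_config(ratio = 0.40, seed = 5))
  expect_identical(out, out2)
})

test_that("a ratio implying no reduction passes the data through", {
  tab <- data.frame(player_id = sprintf("P%02d", 1:20),
                    date = as.Date("2020-09-07") + 1:20,
                    a = stats::rnorm(20), injury = rep(c(1L, 0L), each = 10))
  expect_warning(out <- kmeans_undersample(tab, undersample_config(ratio = 1)),
                 "passing through")
  expect_identical(out, tab)
})

test_that("centroids recover well-separated cluster means", {
  set.seed(8)
  inj <- data.frame(player_id = "I", date = as.Date("2020-09-07"),
                    x = 0, y = 0, injury = 1L)
  non <- data.frame(player_id = sprintf("N%02d", 1:40),
                    date = as.Date("2020-09-08") + 1:40,
                    x = c(stats::rnorm(20, -10, 0.1), stats::rnorm(20, 10, 0.1)),
                    y = c(stats::rnorm(20, -10, 0.1), stats::rnorm(20, 10, 0.1)),
                    injury = 0L)
  tab <- rbind(inj, non)
  out <- kmeans_undersample(tab, undersample_config(use_k = TRUE, k = 2, seed = 2))
  cent <- out[out$injury == 0, c("x", "y")]
  expect_equal(sort(cent$x), c(-10, 10), tolerance = 0.1)
  expect_equal(sort(cent$y), c(-10, 10), tolerance = 0.1)
})

test_that("every classifier solves a separable toy at the elbow threshold", {
  toy <- separable_toy()
  for (kind in c("svm", "fnn", "adaboost")) {
    m <- train_classifier(model_spec(kind, seed = 3), toy$X, toy$y)
    p <- predict_proba(m, toy$X)
    thr <- elbow_threshold(toy$y, p)
    em <- eval_metrics(toy$y, p, thr)
    expect_equal(em$accuracy, 1.0, info = kind)
  }
})

test_that("boosting stops at one stump when one suffices and never exceeds 50", {
  X <- cbind(split_me = c(1:10, 21:30), junk = rep(1:5, 4))
  y <- rep(c(0, 1), each = 10)
  m <- train_classifier(model_spec("adaboost"), X, y)
  expect_length(m$fit$stumps, 1)

  toy <- separable_toy(n = 60, gap = 0.5, seed = 9)   # hard, overlapping
  m2 <- train_classifier(model_spec("adaboost"), toy$X, toy$y)
  expect_lte(length(m2$fit$stumps), 50)
})

test_that("network training is reproducible: identical loss trajectories", {
  toy <- separable_toy(seed = 5)
  m1 <- train_classifier(model_spec("fnn", seed = 11), toy$X, toy$y)
  m2 <- train_classifier(model_spec("fnn", seed = 11), toy$X, toy$y)
  expect_identical(m1$fit$loss_history, m2$fit$loss_history)
  expect_length(m1$fit$loss_history, 20)
  m3 <- train_classifier(model_spec("fnn", seed = 12), toy$X, toy$y)
  expect_false(identical(m1$fit$loss_history, m3$fit$loss_history))
})

test_that("probabilities are strict, pure and schema-checked", {
  toy <- separable_toy(seed = 6)
  Xdup <- rbind(toy$X, toy$X[1, , drop = FALSE])
  for (kind in c("svm", "fnn", "adaboost")) {
    m <- train_classifier(model_spec(kind, seed = 2), toy$X, toy$y)
    p <- predict_proba(m, Xdup)
    expect_length(p, nrow(Xdup))
    expect_true(all(p > 0 & p < 1), info = kind)
    expect_equal(p[1], p[length(p)], info = kind)   # duplicate row, same output
    bad <- toy$X
    colnames(bad) <- c("wrong", "names")
    expect_error(predict_proba(m, bad), "schema")
  }
})

test_that("SVM probabilities are order-consistent with the margin", {
  toy <- separable_toy(seed = 7)
  m <- train_classifier(model_spec("svm", seed = 4), toy$X, toy$y)
  pr <- stats::predict(m$fit$svm, toy$X, decision.values = TRUE)
  dv <- drop(attr(pr, "decision.values"))
  orient <- if (startsWith(colnames(attr(pr, "decision.values"))[1], "1")) 1 else -1
  p <- predict_proba(m, toy$X)
  expect_equal(stats::cor(p, orient * dv, method = "spearman"), 1)
})

test_that("degenerate training inputs are rejected", {
  toy <- separable_toy()
  expect_error(train_classifier(model_spec("svm"), toy$X, rep(1, nrow(toy$X))),
               "single-class")
  Xbad <- toy$X
  Xbad[1, 1] <- NA
  expect_error(train_classifier(model_spec("fnn"), Xbad, toy$y), "non-finite")
  expect_error(model_spec("svm", nonsense = 1), "unknown hyperparameter")
  expect_message(model_spec("fnn", epochs = 5L), "overriding")
})
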