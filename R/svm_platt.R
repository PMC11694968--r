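# RBF SVM with in-package Platt scaling. The margin comes from e1071/libsvm
# (class weights scale the per-class penalty C, adjusting the margin
# proportionally); the probability map is fitted here rather than taken from
# libsvm's internal estimate, whose sigmoid is unstable on small training
# sets. Platt's recipe: collect cross-validated decision values on the
# training data (stratified 5-fold, seeded), then fit a logistic sigmoid
# p = 1 / (1 + exp(-(a + b * f))) by maximum likelihood. Decision values are
# oriented toward the positive class first, so the map cannot invert.

.svm_decision <- function(fit, X) {
  pr <- stats::predict(fit, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  orient <- if (startsWith(colnames(dv)[1], "1")) 1 else -1
  orient * drop(dv)
}

svm_platt_fit <- function(X, y, weights, cost = 1.0, seed = 1L,
                          calib_folds = 5L) {
  set.seed(seed)
  yf <- factor(y, levels = c(0, 1))
  fit <- e1071::svm(x = X, y = yf, kernel = "radial", cost = cost,
                    class.weights = weights, scale = FALSE)

  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  k <- min(calib_folds, n1, n0)
  dv <- rep(NA_real_, length(y))
  if (k >= 2L) {
    # stratified fold assignment so every calibration fit sees both classes
    fold <- integer(length(y))
    fold[y == 1] <- sample(rep_len(seq_len(k), n1))
    fold[y == 0] <- sample(rep_len(seq_len(k), n0))
    for (f in seq_len(k)) {
      hold <- fold == f
      sub <- e1071::svm(x = X[!hold, , drop = FALSE], y = yf[!hold],
                        kernel = "radial", cost = cost,
                        class.weights = weights, scale = FALSE)
      dv[hold] <- .svm_decision(sub, X[hold, , drop = FALSE])
    }
  } else {
    dv <- .svm_decision(fit, X)
  }
  # Platt's smoothed targets keep the sigmoid finite on separable data
  t_pos <- (n1 + 1) / (n1 + 2)
  t_neg <- 1 / (n0 + 2)
  tgt <- ifelse(y == 1, t_pos, t_neg)
  sigmoid_coef <- suppressWarnings(
    stats::coef(stats::glm(tgt ~ dv, family = stats::binomial())))
  if (anyNA(sigmoid_coef)) sigmoid_coef <- c(0, 1)  # degenerate calibration set
  list(svm = fit, a = unname(sigmoid_coef[1]), b = unname(sigmoid_coef[2]))
}

svm_platt_predict <- function(fit, X) {
  f <- .svm_decision(fit$svm, X)
  sigmoid(fit$a + fit$b * f)
}
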