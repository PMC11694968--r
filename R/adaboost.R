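# Discrete AdaBoost over one-level decision stumps. The weak learner is an
# exhaustive weighted search over every feature and every split between
# consecutive distinct sorted values, in both polarities, so the chosen
# stump is the global weighted-error minimizer and the fit is fully
# deterministic (ties break on feature order, then split position).
# Cost sensitivity enters through the initial sample weights, which start
# proportional to the class weights instead of uniform; the boosting loop
# stops early once a stump reaches zero weighted error, and never exceeds
# the configured stump budget.

best_stump <- function(X, y, w) {
  n <- nrow(X)
  total_w <- sum(w)
  best <- list(err = Inf)
  for (j in seq_len(ncol(X))) {
    xv <- X[, j]
    ord <- order(xv)
    xs <- xv[ord]
    if (xs[1] == xs[n]) next
    ys <- y[ord]
    ws <- w[ord]
    cpos <- cumsum(ws * (ys == 1))
    cneg <- cumsum(ws * (ys == -1))
    tneg <- cneg[n]
    # split after position k: x > thr predicted +1 (polarity +1)
    ks <- c(0L, which(xs[-n] < xs[-1]), n)
    err_plus <- ifelse(ks == 0L, tneg,
                       cpos[pmax(ks, 1L)] + (tneg - cneg[pmax(ks, 1L)]))
    err_minus <- total_w - err_plus
    for (pol in c(1, -1)) {
      e <- if (pol == 1) err_plus else err_minus
      i <- which.min(e)
      if (e[i] < best$err - 1e-15) {
        k <- ks[i]
        thr <- if (k == 0L) xs[1] - 1 else if (k == n) xs[n] + 1
               else (xs[k] + xs[k + 1L]) / 2
        best <- list(err = e[i], feature = j, threshold = thr, polarity = pol)
      }
    }
  }
  best
}

stump_predict <- function(st, X) {
  st$polarity * ifelse(X[, st$feature] > st$threshold, 1, -1)
}

adaboost_fit <- function(X, y01, class_weights, max_stumps = 50L) {
  y <- 2 * y01 - 1
  w <- unname(class_weights[as.character(y01)])
  w <- w / sum(w)
  stumps <- list()
  for (t in seq_len(max_stumps)) {
    st <- best_stump(X, y, w)
    if (!is.finite(st$err)) break           # all features constant
    pred <- stump_predict(st, X)
    err <- sum(w[pred != y])
    if (err >= 0.5 - 1e-12 && length(stumps) > 0) break
    eclip <- min(max(err, 1e-10), 1 - 1e-10)
    st$alpha <- 0.5 * log((1 - eclip) / eclip)
    stumps[[length(stumps) + 1L]] <- st
    if (err < 1e-12) break                  # a single perfect stump suffices
    w <- w * exp(-st$alpha * y * pred)
    w <- w / sum(w)
  }
  if (length(stumps) == 0L) {
    stop("no informative stump could be fitted", call. = FALSE)
  }
  list(stumps = stumps, features = colnames(X))
}

# Probability via the logistic transform of the doubled weighted vote,
# the staged-decision analogue of Platt's sigmoid; strictly inside (0, 1).
adaboost_predict <- function(fit, X) {
  f <- numeric(nrow(X))
  for (st in fit$stumps) f <- f + st$alpha * stump_predict(st, X)
  sigmoid(2 * f)
}
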