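injured_fixture <- function(values, metric = "load") {
  out <- data.frame(player_id = rep("A", length(values)),
                    date = as.Date("2020-09-07") + seq_along(values),
                    injury = rep(1L, length(values)), stringsAsFactors = FALSE)
  out[[metric]] <- values
  out
}

test_that("bounds from {0, 10} match the hand evaluation", {
  b <- fit_winsor_bounds(injured_fixture(c(0, 10)))
  s <- sd(c(0, 10))                       # 7.0711
  expect_equal(b$median, 5)
  expect_equal(b$sd, s)
  expect_equal(b$lower, 5 - 1 * s)        # floor(0/s) + 1 = 1
  expect_equal(b$upper, 5 + 2 * s)        # floor(10/s) + 1 = 2
  expect_equal(b$lower, -2.0710678, tolerance = 1e-6)
  expect_equal(b$upper, 19.1421356, tolerance = 1e-6)
})

test_that("constant injured columns are marked no-clip", {
  b <- fit_winsor_bounds(injured_fixture(c(4, 4, 4)))
  expect_false(b$clip)
  x <- data.frame(player_id = "A", date = as.Date("2020-09-07"),
                  load = 99, injury = 0L)
  expect_equal(winsorize(x, b)$load, 99)
})

test_that("fitted bounds always keep one standard deviation of headroom", {
  set.seed(11)
  for (k in 1:50) {
    vals <- stats::rlnorm(sample(2:12, 1), meanlog = stats::runif(1, 0, 4))
    b <- fit_winsor_bounds(injured_fixture(vals))
    if (!b$clip) next
    expect_gte(b$upper - b$median, b$sd - 1e-12)
    expect_gte(b$median - b$lower, b$sd - 1e-12)
    expect_lte(b$lower, b$median)
  }
})

test_that("zero injured rows make bounds undefined", {
  expect_error(fit_winsor_bounds(injured_fixture(numeric(0))), "no injured")
})

test_that("clipping follows the three-branch rule and is idempotent", {
  b <- fit_winsor_bounds(injured_fixture(c(0, 10)))
  tab <- data.frame(player_id = "A", date = as.Date("2020-09-07") + 1:4,
                    load = c(-50, 5, 100, 19.14), injury = 0L)
  w <- winsorize(tab, b)
  expect_equal(w$load[1], b$lower)      # below L -> L
  expect_equal(w$load[2], 5)            # inside untouched
  expect_equal(w$load[3], b$upper)      # above U -> U
  expect_equal(winsorize(w, b), w)      # idempotent
  expect_error(winsorize(tab[, c("player_id", "date", "injury")], b), "unknown column")
})

test_that("winsorized output equals the independent clip oracle", {
  set.seed(4)
  for (k in 1:60) {
    n_inj <- sample(2:8, 1)
    inj <- round(stats::rlnorm(n_inj, 2, 1), 3)
    x <- round(stats::rlnorm(25, 2, 1.5), 3)
    tab <- data.frame(player_id = "A", date = as.Date("2020-09-07") + 1:25,
                      m = x, injury = 0L)
    b <- fit_winsor_bounds(injured_fixture(inj, metric = "m"))
    expect_equal(winsorize(tab, b)$m, oracle_winsorize(x, inj))
  }
})

test_that("bounds depend on injured rows only", {
  season <- season_with_injuries(micro_config(seed = 17))
  prep <- prepare_player_days(season$sessions, season$injuries)
  b1 <- fit_winsor_bounds(prep[prep$injury == 1, ])
  perturbed <- prep
  non <- which(perturbed$injury == 0)
  perturbed[non, feature_cols(perturbed)] <-
    perturbed[non, feature_cols(perturbed)] * 3 + 1
  b2 <- fit_winsor_bounds(perturbed[perturbed$injury == 1, ])
  expect_equal(b1, b2)
})

test_that("standardization hits mean zero and unit sample deviation", {
  tab <- data.frame(player_id = "A", date = as.Date("2020-09-07") + 1:3,
                    x = c(1, 2, 3), injury = 0L)
  s <- fit_standardizer(tab)
  out <- standardize(tab, s)
  expect_equal(out$x, c(-1, 0, 1))
  # fixed point: re-applying a freshly fitted standardizer changes nothing
  s2 <- fit_standardizer(out)
  expect_equal(standardize(out, s2)$x, out$x, tolerance = 1e-9)

  set.seed(5)
  tab2 <- data.frame(player_id = "A", date = as.Date("2020-09-07") + 1:40,
                     a = stats::rlnorm(40), b = stats::rnorm(40, 10, 4), injury = 0L)
  z <- standardize(tab2, fit_standardizer(tab2))
  expect_equal(mean(z$a), 0, tolerance = 1e-9)
  expect_equal(stats::sd(z$b), 1, tolerance = 1e-9)
})

test_that("constant columns pass through standardization flagged", {
  tab <- data.frame(player_id = "A", date = as.Date("2020-09-07") + 1:3,
                    c0 = c(7, 7, 7), x = c(1, 2, 4), injury = 0L)
  out <- standardize(tab, fit_standardizer(tab))
  expect_equal(out$c0, c(7, 7, 7))
  expect_equal(attr(out, "constant"), "c0")
  expect_error(fit_standardizer(tab[0, ]), "empty")
})

test_that("shifting a raw column moves only its mean", {
  set.seed(6)
  tab <- data.frame(player_id = "A", date = as.Date("2020-09-07") + 1:30,
                    x = stats::rnorm(30), injury = 0L)
  shifted <- tab
  shifted$x <- shifted$x + 100
  z1 <- standardize(tab, fit_standardizer(tab))
  z2 <- standardize(shifted, fit_standardizer(shifted))
  expect_equal(z1$x, z2$x, tolerance = 1e-9)
})

test_that("preprocessing parameters survive a JSON round trip", {
  season <- season_with_injuries(micro_config(seed = 8))
  prep <- prepare_player_days(season$sessions, season$injuries)
  pp <- preprocess_features(prep)
  bp <- tempfile(fileext = ".json")
  sp <- tempfile(fileext = ".json")
  write_winsor_bounds_json(pp$bounds, bp)
  write_standardizer_json(pp$standardizer, sp)
  expect_equal(read_winsor_bounds_json(bp), pp$bounds,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(read_standardizer_json(sp), pp$standardizer,
               tolerance = 1e-12, ignore_attr = TRUE)
})
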