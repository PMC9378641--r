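test_that("spline smoothing reproduces constants and lines", {
  yrs <- 1961:2020
  expect_equal(smooth_spline_series(rep(2.5, 60), yrs, smoothing = 1),
               rep(2.5, 60))
  lin <- 0.02 * (yrs - 1990) + 1
  for (lam in c(1e-6, 1, 1e4)) {
    expect_equal(smooth_spline_series(lin, yrs, smoothing = lam), lin,
                 tolerance = 1e-4)
  }
})

test_that("heavy spline smoothing shrinks variance toward the trend line", {
  set.seed(31)
  yrs <- 1961:2020
  y <- sin((yrs - 1960) / 4) + rnorm(60, 0, 0.3)
  sm <- smooth_spline_series(y, yrs, smoothing = 10)
  expect_lt(var(sm), var(y))
  # large penalty tends to the least-squares line
  heavy <- smooth_spline_series(y, yrs, smoothing = 1e6)
  line <- fitted(lm(y ~ yrs))
  expect_lt(max(abs(heavy - unname(line))), 0.05)
  # near-zero penalty interpolates
  loose <- smooth_spline_series(y, yrs, smoothing = 1e-12)
  expect_equal(loose, y, tolerance = 1e-3)
  expect_error(smooth_spline_series(c(1, 2, 3)), "few")
})

test_that("quartic-degree spline option smooths too", {
  skip_if_not_installed("mgcv")
  set.seed(32)
  yrs <- 1961:2020
  y <- cos((yrs - 1960) / 5) + rnorm(60, 0, 0.2)
  sm <- smooth_spline_series(y, yrs, smoothing = 5, degree = "quartic")
  expect_length(sm, 60)
  expect_lt(var(sm), var(y))
})

test_that("local regression reproduces constants and straight lines", {
  yrs <- 1:20
  expect_equal(local_regression(rep(3, 20), yrs, span = 0.4), rep(3, 20))
  lin <- 2 * yrs - 5
  expect_equal(local_regression(lin, yrs, span = 1), lin)
  expect_equal(local_regression(lin, yrs, span = 0.3), lin,
               tolerance = 1e-10)
  expect_error(local_regression(1:3), "4 points")
  expect_error(local_regression(1:10, span = 0), "span")
})

test_that("local regression matches a direct weighted-least-squares oracle", {
  set.seed(33)
  y <- sin(1:7) + rnorm(7, 0, 0.1)
  x <- 1:7
  span <- 0.5
  mine <- local_regression(y, x, span = span)
  q <- floor(span * 7)
  oracle <- vapply(seq_along(x), function(i) {
    d <- abs(x - x[i])
    dq <- sort(d)[q]
    w <- ifelse(d < dq, (1 - (d / dq)^3)^3, 0)
    w[d == 0] <- 1
    fit <- lm(y ~ x, weights = w)
    unname(predict(fit, data.frame(x = x[i])))
  }, numeric(1))
  expect_equal(mine, oracle, tolerance = 1e-10)
  # and the classical implementation agrees
  lo <- suppressWarnings(
    predict(loess(y ~ x, span = span, degree = 1, surface = "direct")))
  expect_equal(mine, unname(lo), tolerance = 1e-10)
})

test_that("smoothers are linear operators in the input series", {
  set.seed(34)
  yrs <- 1:30
  a <- rnorm(30)
  b <- rnorm(30)
  expect_equal(local_regression(a + b, yrs, 0.5),
               local_regression(a, yrs, 0.5) +
                 local_regression(b, yrs, 0.5),
               tolerance = 1e-10)
  expect_equal(smooth_spline_series(a + b, yrs, smoothing = 2),
               smooth_spline_series(a, yrs, smoothing = 2) +
                 smooth_spline_series(b, yrs, smoothing = 2),
               tolerance = 1e-6)
})

test_that("period statistics recover means, trends and acceleration", {
  yrs <- 1:10
  r <- period_mean_and_trend(yrs, yrs, periods = list(c(1, 10)))
  expect_equal(r$stats$trend, 1)

  yrs2 <- 1961:2020
  v <- ifelse(yrs2 <= 2000, 0.6, 1.6)
  r2 <- period_mean_and_trend(v, yrs2)
  expect_equal(r2$stats$mean, c(0.6, 1.6))
  expect_equal(r2$stats$trend, c(0, 0))

  # piecewise linear with a known post-2000 slope of 0.019 PgC/yr^2
  kink <- ifelse(yrs2 <= 2000, 0.5, 0.5 + 0.019 * (yrs2 - 2000))
  r3 <- period_mean_and_trend(kink, yrs2, trend_units = "TgC")
  expect_equal(r3$acceleration, 19, tolerance = 1e-9)

  # invariance to year re-centering
  r4 <- period_mean_and_trend(kink, yrs2 - 1960,
                              periods = list(c(1, 40), c(41, 60)))
  expect_equal(r4$stats$mean, r3$stats$mean / 1)
  expect_equal(r4$stats$trend[2] * 1000, r3$stats$trend[2])

  expect_error(period_mean_and_trend(v, yrs2,
                                     periods = list(c(1800, 1805))),
               "empty")
})

test_that("driver-dominance composite normalises channels and alpha", {
  rgb1 <- rgb_driver_composite(clim = 0, co2 = 3, lulcc = 0, net = 3,
                               alpha_scale = 3)
  expect_equal(c(rgb1$r, rgb1$g, rgb1$b, rgb1$alpha), c(0, 1, 0, 1))

  rgb2 <- rgb_driver_composite(2, -2, 2, net = 0)
  expect_equal(c(rgb2$r, rgb2$g, rgb2$b), rep(1 / 3, 3))
  expect_equal(rgb2$alpha, 0)

  z <- rgb_driver_composite(0, 0, 0, 0)
  expect_equal(c(z$r, z$g, z$b, z$alpha), c(0, 0, 0, 0))

  # scale invariance of the channels
  set.seed(35)
  cl <- matrix(rnorm(12), 3)
  co <- matrix(rnorm(12), 3)
  lu <- matrix(rnorm(12), 3)
  a <- rgb_driver_composite(cl, co, lu, cl + co + lu)
  b <- rgb_driver_composite(7 * cl, 7 * co, 7 * lu, cl + co + lu)
  expect_equal(a$r, b$r)
  expect_equal(a$b, b$b)
  sums <- a$r + a$g + a$b
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("summary tables equal hand-computed ensemble means and spreads", {
  res <- data.frame(
    model = rep(c("m1", "m2"), each = 2),
    pool = "vegetation",
    driver = rep(c("CO2", "ALL"), 2),
    input_adj = c(10, 12, 20, 18),
    output_adj = c(-2, -1, -4, -3),
    interaction_adj = c(0.5, 0.1, 1, 0.4),
    delta_actual = c(8.5, 11.1, 17, 15.4))
  tab <- summary_tables(res)
  co2_in <- tab[tab$driver == "CO2" & tab$term == "input_adj", ]
  expect_equal(co2_in$mean_PgC, 15)
  expect_equal(co2_in$sd_PgC, sd(c(10, 20)))
  expect_equal(co2_in$n_models, 2)
  expect_error(summary_tables(res[0, ]), "empty")
})

test_that("regional summary rows add: north plus south equals global", {
  res <- expand.grid(model = c("m1", "m2"), region = c("north", "south"),
                     stringsAsFactors = FALSE)
  res$pool <- "soil"
  res$driver <- "ALL"
  res$input_adj <- c(1, 2, 3, 4)
  res$output_adj <- 0
  res$interaction_adj <- 0
  res$delta_actual <- res$input_adj
  glob <- aggregate(input_adj ~ model, data = res, FUN = sum)
  tabs <- lapply(split(res, res$region), summary_tables,
                 terms = "input_adj")
  expect_equal(tabs$north$mean_PgC + tabs$south$mean_PgC,
               mean(glob$input_adj))
})
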