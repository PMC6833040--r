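test_that("ARIMA handles constant and random-walk windows by closed form", {
  w <- make_window_raw(rep(123, 72))
  expect_message(m <- fit_arima(w), "mean predictor")
  for (h in c(1, 3, 12)) expect_equal(predict(m, w, h), 123)

  # (0,1,0): forecast at any horizon equals the last value
  set.seed(4)
  w <- make_window_raw(120 + cumsum(rnorm(72)))
  m <- fit_arima(w, order = c(0, 1, 0))
  for (h in c(1, 4, 10))
    expect_equal(predict(m, w, h), w$values[72], tolerance = 1e-8)
})

test_that("a fitted AR(1) forecasts by its closed form mu + phi^h (x - mu)", {
  set.seed(11)
  x <- as.numeric(arima.sim(list(ar = 0.8), 500)) + 120
  w <- make_window_raw(x)
  m <- fit_arima(w, order = c(1, 0, 0))
  phi <- coef(m$fit)[["ar1"]]
  mu <- coef(m$fit)[["intercept"]]
  expect_lt(abs(phi - 0.8), 0.1)
  for (h in 1:4)
    expect_equal(forecast_arima(m, h), mu + phi^h * (x[500] - mu),
                 tolerance = 1e-6)
})

test_that("multi-step ARIMA forecasts agree with brute-force recursion", {
  set.seed(21)
  x <- as.numeric(arima.sim(list(ar = c(0.5, 0.3)), 300)) + 150
  w <- make_window_raw(x)
  m <- fit_arima(w, order = c(2, 0, 0))
  phi <- coef(m$fit)[c("ar1", "ar2")]
  mu <- coef(m$fit)[["intercept"]]
  # recurse the AR(2) conditional mean by hand
  hist <- c(x[299], x[300])
  for (h in 1:5) {
    nxt <- mu + phi[[1]] * (hist[2] - mu) + phi[[2]] * (hist[1] - mu)
    expect_equal(forecast_arima(m, h), nxt, tolerance = 1e-6)
    hist <- c(hist[2], nxt)
  }
})

test_that("order selection prefers differencing on random walks but not on stationary series", {
  set.seed(31)
  d_rw <- replicate(50, {
    w <- make_window_raw(120 + cumsum(rnorm(200)))
    fit_arima(w)$order[2]
  })
  expect_gte(mean(d_rw == 1), 0.9)

  d_ar <- replicate(20, {
    w <- make_window_raw(as.numeric(arima.sim(list(ar = 0.5), 200)) + 120)
    fit_arima(w)$order[2]
  })
  expect_lte(mean(d_ar == 1), 0.2)
})

test_that("ML forecasters learn noiseless structure and degrade gracefully", {
  # constant targets: both methods predict the constant
  w <- make_window_raw(c(rep(c(100, 150), 20), rep(100, 2)))
  p <- embed_window(w, 6, 2)
  p$y <- rep(130, length(p$y))
  expect_message(mrf <- fit_ml(p, "rf"), "mean predictor")
  expect_equal(predict(mrf, w, 2), 130)

  # periodic series with period h: the target equals the last lag exactly
  w <- make_window_raw(rep(c(100, 140, 180), 24))  # n = 72, period 3
  p <- embed_window(w, 6, 3)
  mrf <- fit_ml(p, "rf", rf_params(seed = 5))
  preds <- apply(p$X, 1, function(r) {
    ww <- w
    ww$values[67:72] <- r   # prediction uses the m most recent values
    predict(mrf, ww, 3)
  })
  expect_lt(sqrt(mean((preds - p$y)^2)), 5)

  # rf predictions never leave the training-target range
  expect_true(all(preds >= min(p$y) & preds <= max(p$y)))

  # same seed, same forest
  m1 <- fit_ml(p, "rf", rf_params(seed = 9))
  m2 <- fit_ml(p, "rf", rf_params(seed = 9))
  expect_equal(predict(m1, w, 3), predict(m2, w, 3))
})

test_that("SVR interpolates noiseless pairs and is deterministic", {
  set.seed(3)
  w <- make_window_raw(120 + 30 * sin(seq(0, 4 * pi, length.out = 12)))
  p <- embed_window(w, 6, 1)   # 6 noiseless pairs
  m <- fit_ml(p, "svr", svr_params(cost = 1000, epsilon = 0))
  for (i in seq_along(p$y)) {
    ww <- w
    ww$values[7:12] <- p$X[i, ]
    expect_lt(abs(predict(m, ww, 1) - p$y[i]), 1)
  }
  m2 <- fit_ml(p, "svr", svr_params(cost = 1000, epsilon = 0))
  ww <- w
  expect_equal(predict(m, ww, 1), predict(m2, ww, 1))
})

test_that("the naive baseline is persistence and its random-walk RMSE follows sigma * sqrt(h)", {
  w <- make_window_raw(c(rnorm(71, 120), 143))
  m <- fit_naive(w)
  for (h in c(1, 5, 12)) expect_equal(predict(m, w, h), 143)

  set.seed(12)
  s <- make_series(200 + cumsum(rnorm(3000, 0, 1)), sf_min = 5)
  cfg <- eval_config(psw_hours = 1, sf_min = 5, ph_min = 20,
                     methods = "naive")
  rec <- rolling_evaluate(s, "naive", psw_hours = 1, ph_min = 20, cfg)
  expect_equal(rmse(rec), sqrt(4), tolerance = 0.1)  # sigma * sqrt(h), h = 4
})

test_that("forecaster metadata and horizons are enforced", {
  w <- make_window_raw(rnorm(72, 120), sf_min = 5)
  p <- embed_window(w, 6, 3)
  m <- fit_ml(p, "rf", rf_params(n_trees = 50))
  w_bad <- make_window_raw(rnorm(36, 120), sf_min = 5)
  expect_error(predict(m, w_bad, 3), "metadata mismatch")
  expect_error(predict(m, w, 5), "trained for h = 3")
  expect_error(forecast_arima(m, 2), "arima")
  expect_error(fit_arima(make_window_raw(rnorm(5))), ">= 10")
})

test_that("all methods give finite in-range forecasts across window/horizon combinations", {
  s5 <- small_series5()
  s15 <- resample(small_cohort()$sensor[[1]], 15)
  for (series in list(s5, s15)) {
    for (method in c("naive", "arima", "rf", "svr")) {
      for (psw in c(3, 6)) {
        cfg <- eval_config(psw_hours = psw, sf_min = series$sf_min,
                           ph_min = 60, methods = method, refit_every = 48)
        rec <- rolling_evaluate(series, method, psw, 60, cfg)
        expect_true(all(is.finite(rec$y_pred)))
        expect_true(all(rec$y_pred >= 20 & rec$y_pred <= 600))
      }
    }
  }
})
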