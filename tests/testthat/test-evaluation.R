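test_that("rolling evaluation emits one record per origin after burn-in", {
  s <- small_series5()                       # 2 days at SF 5 = 576 samples
  cfg <- eval_config(psw_hours = 6, sf_min = 5, ph_min = 15,
                     methods = "naive")
  rec <- rolling_evaluate(s, "naive", 6, 15, cfg)
  expect_equal(nrow(rec), 576 - 72 - 3 + 1)  # 502
  expect_equal(rec$ph_eff_min[1], 15)
  expect_equal(as.numeric(difftime(rec$target_time, rec$origin_time,
                                   units = "mins")),
               rep(15, nrow(rec)))
  # chronological order
  expect_true(all(diff(as.numeric(rec$origin_time)) > 0))

  # a wider shared burn-in shrinks the origin set accordingly
  cfg36 <- eval_config(psw_hours = c(6, 36), sf_min = 5, ph_min = 15,
                       methods = "naive")
  rec36 <- rolling_evaluate(s, "naive", 6, 15, cfg36)
  expect_equal(nrow(rec36), 576 - 432 - 3 + 1)

  expect_error(rolling_evaluate(make_series(rnorm(50, 120), 5), "naive", 6,
                                15, cfg), "too short")
})

test_that("every method reproduces a constant series exactly", {
  s <- make_series(rep(130, 120), sf_min = 5)
  cfg <- eval_config(psw_hours = 3, sf_min = 5, ph_min = 15,
                     methods = c("naive", "arima", "rf", "svr"),
                     refit_every = 24)
  for (method in c("naive", "arima", "rf", "svr")) {
    rec <- suppressMessages(rolling_evaluate(s, method, 3, 15, cfg))
    expect_equal(rec$y_pred, rep(130, nrow(rec)))
    expect_equal(rmse(rec), 0)
  }
})

test_that("the naive path agrees with an independently coded persistence loop", {
  s <- small_series5()
  cfg <- eval_config(psw_hours = 6, sf_min = 5, ph_min = 30,
                     methods = "naive")
  rec <- rolling_evaluate(s, "naive", 6, 30, cfg)
  # brute-force oracle: persistence forecast h = 6 steps ahead
  v <- s$values
  ora_pred <- v[72:(length(v) - 6)]
  ora_true <- v[(72 + 6):length(v)]
  expect_equal(rec$y_pred, ora_pred)
  expect_equal(rec$y_true, ora_true)
})

test_that("rmse matches hand-computed and two-pass oracle values", {
  rec <- data.frame(y_true = c(100, 100), y_pred = c(100, 110))
  expect_equal(rmse(rec), sqrt(50))          # errors 0 and 10

  rec <- data.frame(y_true = rnorm(20, 150), y_pred = 0)
  rec$y_pred <- rec$y_true + 7.5             # constant offset
  expect_equal(rmse(rec), 7.5)

  expect_error(rmse(data.frame(y_true = numeric(0), y_pred = numeric(0))),
               "zero records")

  set.seed(99)
  rec <- data.frame(y_true = runif(1000, 40, 400),
                    y_pred = runif(1000, 40, 400))
  # independent two-pass computation: accumulate squared errors, then root
  acc <- 0
  for (i in 1:1000) acc <- acc + (rec$y_pred[i] - rec$y_true[i])^2
  expect_equal(rmse(rec), sqrt(acc / 1000), tolerance = 1e-9)
})

test_that("grid presets enumerate the two experiments' cells exactly", {
  c1 <- grid_cells(experiment1_config())
  expect_equal(nrow(c1), 60)                 # 5 PSW x 4 PH x 3 methods
  expect_equal(sum(c1$method == "rf"), 20)
  expect_true(all(c1$sf_min == 5))

  c2 <- grid_cells(experiment2_config())
  expect_equal(nrow(c2), 36)                 # 3 SF x 4 PH x 3 methods
  expect_equal(sum(c2$method == "svr"), 12)
  expect_true(all(c2$psw_hours == 6))
})

test_that("invalid grid combinations are rejected before any computation", {
  expect_error(eval_config(psw_hours = 6, sf_min = 7), "non-integer window")
  expect_error(eval_config(ph_min = 15, sf_min = 10, ph_exact = TRUE),
               "not a multiple")
  expect_error(eval_config(methods = "lstm"), "unknown method")
  expect_error(eval_config(refit_every = 0), "refit_every")
  # horizons that are not multiples of the sampling interval are evaluated
  # at the next on-grid step
  s <- make_series(rnorm(200, 120, 5), sf_min = 10)
  cfg <- eval_config(psw_hours = 3, sf_min = 10, ph_min = 15,
                     methods = "naive")
  rec <- rolling_evaluate(s, "naive", 3, 15, cfg)
  expect_equal(rec$ph_eff_min[1], 20)
  expect_equal(rec$ph_min[1], 15)
})

test_that("refit cadence never changes the evaluation origins", {
  s <- small_series5()
  cfg1 <- eval_config(psw_hours = 6, sf_min = 5, ph_min = 15, methods = "rf",
                      refit_every = 1, rf = rf_params(n_trees = 25))
  cfg5 <- eval_config(psw_hours = 6, sf_min = 5, ph_min = 15, methods = "rf",
                      refit_every = 50, rf = rf_params(n_trees = 25))
  r1 <- rolling_evaluate(s, "rf", 6, 15, cfg1)
  r5 <- rolling_evaluate(s, "rf", 6, 15, cfg5)
  expect_equal(r1$origin_time, r5$origin_time)
  expect_equal(r1$y_true, r5$y_true)
  expect_lt(length(attr(r5, "log")$refit_origins),
            length(attr(r1, "log")$refit_origins))

  # naive is refit-free, so records must be bit-identical
  n1 <- rolling_evaluate(s, "naive", 6, 15, cfg1)
  n5 <- rolling_evaluate(s, "naive", 6, 15, cfg5)
  expect_identical(n1$y_pred, n5$y_pred)
})

test_that("run_grid composes rolling evaluation and keeps every patient", {
  coh <- small_cohort()
  cfg <- eval_config(psw_hours = 6, sf_min = 5, ph_min = 30,
                     methods = "naive")
  g <- run_grid(coh, cfg, quiet = TRUE)
  expect_s3_class(g, "cgm_grid")
  expect_equal(nrow(g$rmse), 2)              # 1 cell x 2 patients
  # composition: cell RMSE equals rmse(rolling_evaluate(...)) directly
  s <- resample(coh$sensor[[1]], 5)
  expect_equal(g$rmse$rmse_mgdl[g$rmse$patient_id == s$patient_id],
               rmse(rolling_evaluate(s, "naive", 6, 30, cfg)))
  # no silent patient drops
  agg <- suppressMessages(aggregate(g))
  expect_equal(agg$n_patients, 2)
})

test_that("aggregation computes unweighted cross-patient mean and sample sd", {
  g <- structure(list(rmse = data.frame(
    method = "naive", psw_hours = 6, sf_min = 5, ph_min = 30,
    patient_id = c("P01", "P02"), rmse_mgdl = c(10, 20), n_records = 100),
    config = NULL), class = "cgm_grid")
  agg <- aggregate(g)
  expect_equal(agg$mean_rmse, 15)
  expect_equal(agg$sd_rmse, sd(c(10, 20)))
  expect_equal(agg$sd_rmse, 7.071, tolerance = 1e-4)

  # permutation invariance
  g2 <- g; g2$rmse <- g$rmse[2:1, ]
  expect_equal(aggregate(g2), agg)

  # single patient: sd reported as 0, with a caveat
  g1 <- g; g1$rmse <- g$rmse[1, ]
  expect_message(agg1 <- aggregate(g1), "single-patient")
  expect_equal(agg1$sd_rmse, 0)
})

test_that("find_optimal_psw returns the argmin with ties toward smaller windows", {
  summ <- data.frame(method = "rf", psw_hours = c(3, 6, 12, 24, 36),
                     sf_min = 5, ph_min = 30, n_patients = 5,
                     mean_rmse = c(12, 10, 13, 14, 15), sd_rmse = 1)
  expect_equal(find_optimal_psw(summ, "rf", 5, 30), 6)

  summ$mean_rmse <- rep(10, 5)
  expect_equal(find_optimal_psw(summ, "rf", 5, 30), 3)

  expect_error(find_optimal_psw(summ, "rf", 5, 30,
                                psw_hours = c(3, 6, 12, 24, 36, 48)),
               "missing PSW")
  expect_error(find_optimal_psw(summ, "arima", 5, 30), "no cells")
})
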