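#' Candidate ARIMA orders for automatic selection
#'
#' @param max_p,max_q Largest autoregressive / moving-average orders
#'   considered (at most 3).
#' @param d Differencing orders considered (subset of `{0, 1}`).
#' @return A data.frame with columns `p`, `d`, `q`.
#' @export
default_order_grid <- function(max_p = 3, max_q = 3, d = 0:1) {
  if (max_p < 0 || max_p > 3 || max_q < 0 || max_q > 3)
    stopf("'max_p' and 'max_q' must lie in 0..3")
  if (!all(d %in% 0:1)) stopf("'d' must be a subset of {0, 1}")
  expand.grid(p = 0:max_p, d = sort(unique(d)), q = 0:max_q,
              KEEP.OUT.ATTRS = FALSE)
}

#' Random forest hyperparameters
#'
#' Fixed defaults in the spirit of standard regression-forest practice:
#' 500 trees, `mtry = ceiling(m/3)` features per split, minimum node size 5.
#'
#' @param n_trees Number of trees.
#' @param mtry Features tried per split; `NULL` means `ceiling(m/3)`.
#' @param min_node Minimum size of terminal nodes.
#' @param seed RNG seed making the fitted forest reproducible.
#' @return An object of class `rf_params`.
#' @export
rf_params <- function(n_trees = 500, mtry = NULL, min_node = 5, seed = 1) {
  if (n_trees < 1) stopf("'n_trees' must be >= 1")
  structure(list(n_trees = n_trees, mtry = mtry, min_node = min_node,
                 seed = seed), class = "rf_params")
}

#' Support vector regression hyperparameters
#'
#' Radial-basis-kernel epsilon-regression with fixed defaults; features and
#' target are z-scored with the training window's own mean and standard
#' deviation before fitting, and predictions are mapped back.
#'
#' @param cost Regularization constant C (> 0).
#' @param epsilon Epsilon of the insensitive loss band (>= 0).
#' @param gamma RBF kernel width; `NULL` means `1/m` on standardized
#'   features.
#' @return An object of class `svr_params`.
#' @export
svr_params <- function(cost = 1, epsilon = 0.1, gamma = NULL) {
  if (cost <= 0) stopf("'cost' must be > 0")
  if (epsilon < 0) stopf("'epsilon' must be >= 0")
  if (!is.null(gamma) && gamma <= 0) stopf("'gamma' must be > 0")
  structure(list(cost = cost, epsilon = epsilon, gamma = gamma),
            class = "svr_params")
}

# Dot-prefixed formals so that fields passed through ... (m, h, mu, ...)
# can never partially match them.
new_forecaster <- function(.method, .fit, .window, ...) {
  structure(c(list(method = .method, fit = .fit, n = .window$n,
                   sf_min = .window$sf_min), list(...)),
            class = "cgm_forecaster")
}

# AICc of a CSS-fitted ARIMA; Inf when the fit failed.
arima_aicc <- function(fit) {
  if (is.null(fit) || !is.finite(fit$loglik)) return(Inf)
  k <- length(fit$coef) + 1  # + innovation variance
  n <- fit$nobs
  if (n - k - 1 <= 0) return(Inf)
  -2 * fit$loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

try_arima <- function(x, order, fixed = NULL) {
  tryCatch(
    suppressWarnings(stats::arima(x, order = order, fixed = fixed,
                                  method = "CSS", transform.pars = FALSE)),
    error = function(e) NULL)
}

# Differencing order via the Phillips-Perron unit-root test: keep d = 1
# unless the unit-root null is rejected at the 5% level. Information
# criteria are not comparable across d (differencing changes the sample),
# so d is decided first, as in standard automatic order selection.
choose_d <- function(x, alpha = 0.05) {
  pv <- tryCatch(suppressWarnings(stats::PP.test(stats::ts(x))$p.value),
                 error = function(e) 1)
  if (!is.finite(pv) || pv > alpha) 1L else 0L
}

#' Fit an ARIMA forecaster to one window with automatic order selection
#'
#' The differencing order `d` is chosen by a Phillips--Perron unit-root
#' test, then `(p, q)` by minimizing AICc over the candidate grid at that
#' `d`, with conditional-sum-of-squares fitting. If every candidate fails to
#' converge the model falls back to ARIMA(1,1,0); a constant window falls
#' back to a mean predictor.
#'
#' @param window A `cgm_window` with at least 10 values.
#' @param order_grid Candidate orders from [default_order_grid()].
#' @param order Optional fixed `c(p, d, q)`; skips selection (used by the
#'   rolling harness to re-estimate coefficients at a previously selected
#'   order).
#' @return A `cgm_forecaster` with method tag `"arima"`, recording the
#'   selected order and coefficients.
#' @export
fit_arima <- function(window, order_grid = default_order_grid(), order = NULL) {
  if (!inherits(window, "cgm_window")) stopf("'window' must be a cgm_window")
  x <- window$values
  if (length(x) < 10) stopf("window length must be >= 10 for ARIMA")
  if (stats::sd(x) == 0) {
    message("constant window: ARIMA degenerates to the mean predictor")
    return(new_forecaster("arima", NULL, window, degenerate = TRUE,
                          mu = x[1], order = c(0, 0, 0),
                          train_values = x))
  }
  if (is.null(order)) {
    d <- choose_d(x)
    g <- order_grid[order_grid$d == d, , drop = FALSE]
    if (nrow(g) == 0) g <- order_grid
    fits <- lapply(seq_len(nrow(g)),
                   function(i) try_arima(x, c(g$p[i], g$d[i], g$q[i])))
    aicc <- vapply(fits, arima_aicc, numeric(1))
    if (all(!is.finite(aicc))) {
      fit <- try_arima(x, c(1, 1, 0))
      order <- c(1, 1, 0)
    } else {
      best <- which.min(aicc)
      fit <- fits[[best]]
      order <- c(g$p[best], g$d[best], g$q[best])
    }
  } else {
    fit <- try_arima(x, order)
  }
  if (is.null(fit)) {
    message("ARIMA fit failed; falling back to the mean predictor")
    return(new_forecaster("arima", NULL, window, degenerate = TRUE,
                          mu = mean(x), order = c(0, 0, 0), train_values = x))
  }
  new_forecaster("arima", fit, window, degenerate = FALSE,
                 order = as.integer(order), train_values = x)
}

#' Iterated multi-step forecast from a fitted ARIMA model
#'
#' @param model A `cgm_forecaster` with method `"arima"`.
#' @param h Horizon in steps (>= 1).
#' @return Point forecast (mg/dL) of the conditional mean `h` steps ahead.
#' @export
forecast_arima <- function(model, h) {
  if (!inherits(model, "cgm_forecaster") || model$method != "arima")
    stopf("'model' must be an arima cgm_forecaster")
  if (!is.numeric(h) || h < 1) stopf("'h' must be >= 1")
  h <- as.integer(h)
  if (isTRUE(model$degenerate)) return(model$mu)
  # CSS fits are unconstrained, so predict may warn about non-invertible
  # MA parts; the conditional-mean forecast is still well defined
  as.numeric(suppressWarnings(stats::predict(model$fit, n.ahead = h)$pred[h]))
}

# Re-apply a fitted ARIMA's coefficients to a new window (Kalman filtering
# only, no re-optimization) so forecasts can be issued from origins between
# refits.
arima_refilter <- function(model, window) {
  if (isTRUE(model$degenerate)) return(model)
  fit <- try_arima(window$values, model$order, fixed = model$fit$coef)
  if (is.null(fit)) {  # e.g. new window constant
    return(new_forecaster("arima", NULL, window, degenerate = TRUE,
                          mu = mean(window$values), order = model$order,
                          train_values = window$values))
  }
  new_forecaster("arima", fit, window, degenerate = FALSE,
                 order = model$order, train_values = window$values)
}

mean_predictor <- function(method, pairs, mu) {
  new_forecaster(method, NULL,
                 list(n = pairs$n, sf_min = pairs$sf_min),
                 degenerate = TRUE, mu = mu, m = pairs$m, h = pairs$h)
}

#' Fit a machine-learning forecaster on embedded pairs
#'
#' Direct-strategy regression of the value `h` steps ahead on the `m` most
#' recent values. The random forest is reproducible given its seed; the SVR
#' is deterministic. Degenerate training sets (fewer than two pairs, or
#' zero target variance for the SVR's standardization) fall back to a mean
#' predictor with a message.
#'
#' @param pairs A `supervised_set` from [embed_window()].
#' @param method `"rf"` or `"svr"`.
#' @param params An [rf_params()] or [svr_params()] object.
#' @return A `cgm_forecaster` with the corresponding method tag.
#' @export
fit_ml <- function(pairs, method = c("rf", "svr"), params = NULL) {
  method <- match.arg(method)
  if (!inherits(pairs, "supervised_set"))
    stopf("'pairs' must be a supervised_set")
  m <- pairs$m
  if (method == "rf") {
    params <- params %||% rf_params()
    if (nrow(pairs$X) < 2 || stats::var(pairs$y) == 0) {
      message("degenerate training set: random forest falls back to the mean predictor")
      return(mean_predictor("rf", pairs, mean(pairs$y)))
    }
    mtry <- params$mtry %||% max(1L, ceiling(m / 3))
    # suppress the "five or fewer unique values" note: tiny windows with
    # few embedded pairs are a legitimate study condition here
    fit <- with_seed(params$seed,
                     suppressWarnings(
                       randomForest::randomForest(x = pairs$X, y = pairs$y,
                                                  ntree = params$n_trees,
                                                  mtry = min(mtry, m),
                                                  nodesize = params$min_node)))
    new_forecaster("rf", fit, list(n = pairs$n, sf_min = pairs$sf_min),
                   degenerate = FALSE, m = m, h = pairs$h, params = params)
  } else {
    params <- params %||% svr_params()
    mu <- pairs$win_mean; s <- pairs$win_sd
    if (nrow(pairs$X) < 2 || s == 0 || stats::var(pairs$y) == 0) {
      message("degenerate training set: SVR falls back to the mean predictor")
      return(mean_predictor("svr", pairs, mean(pairs$y)))
    }
    gamma <- params$gamma %||% (1 / m)
    fit <- e1071::svm(x = (pairs$X - mu) / s, y = (pairs$y - mu) / s,
                      type = "eps-regression", kernel = "radial",
                      cost = params$cost, epsilon = params$epsilon,
                      gamma = gamma, scale = FALSE)
    new_forecaster("svr", fit, list(n = pairs$n, sf_min = pairs$sf_min),
                   degenerate = FALSE, m = m, h = pairs$h,
                   center = mu, scale = s, params = params)
  }
}

#' Fit the persistence (naive) baseline
#'
#' Predicts the last observed value for any horizon -- the standard baseline
#' for short-horizon physiological series.
#'
#' @param window A `cgm_window`.
#' @return A `cgm_forecaster` with method tag `"naive"`.
#' @export
fit_naive <- function(window) {
  if (!inherits(window, "cgm_window")) stopf("'window' must be a cgm_window")
  new_forecaster("naive", NULL, window, degenerate = FALSE)
}

#' Point forecast from a fitted forecaster applied to a window
#'
#' Dispatches on the method tag: ARIMA forecasts by iterated recursion
#' (re-filtering its coefficients on `window` if it differs from the
#' training window); RF/SVR apply the fitted regression to the `m` most
#' recent values (the SVR de-standardizes its output); the naive model
#' returns the last window value. Forecasts are clipped to the
#' physiological range 20--600 mg/dL as a sanity bound.
#'
#' @param object A `cgm_forecaster`.
#' @param window A `cgm_window` whose `(n, sf_min)` match the training
#'   metadata.
#' @param h Horizon in steps; for RF/SVR it must equal the horizon the
#'   model was trained for (direct strategy).
#' @param ... Unused.
#' @return Point forecast in mg/dL, finite.
#' @export
predict.cgm_forecaster <- function(object, window, h = object$h, ...) {
  if (!inherits(window, "cgm_window")) stopf("'window' must be a cgm_window")
  if (window$n != object$n || window$sf_min != object$sf_min)
    stopf("window metadata mismatch: model trained with (n = %d, sf = %g), window has (n = %d, sf = %g)",
          object$n, object$sf_min, window$n, window$sf_min)
  yhat <- switch(object$method,
    naive = window$values[window$n],
    arima = {
      mdl <- if (identical(object$train_values, window$values)) object
             else arima_refilter(object, window)
      forecast_arima(mdl, h)
    },
    rf = ,
    svr = {
      if (is.null(h) || h != object$h)
        stopf("direct-strategy %s model was trained for h = %d steps",
              object$method, object$h)
      if (isTRUE(object$degenerate)) object$mu
      else {
        x <- matrix(window$values[(window$n - object$m + 1):window$n],
                    nrow = 1)
        colnames(x) <- paste0("lag", (object$m - 1):0)
        if (object$method == "svr") {
          as.numeric(stats::predict(object$fit,
                                    (x - object$center) / object$scale)) *
            object$scale + object$center
        } else {
          as.numeric(stats::predict(object$fit, x))
        }
      }
    },
    stopf("unknown method '%s'", object$method))
  if (!is.finite(yhat)) stopf("non-finite forecast from method '%s'",
                              object$method)
  min(max(yhat, 20), 600)
}

#' @export
print.cgm_forecaster <- function(x, ...) {
  extra <- if (x$method == "arima" && !isTRUE(x$degenerate))
    sprintf(" order (%s)", paste(x$order, collapse = ","))
  else if (isTRUE(x$degenerate)) " [degenerate: mean predictor]"
  else ""
  cat(sprintf("<cgm_forecaster> %s%s, trained on n = %d at SF %g min\n",
              x$method, extra, x$n, x$sf_min))
  invisible(x)
}
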