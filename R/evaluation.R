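#' Evaluation configuration for the forecasting grid
#'
#' Defines the experiment grid: past sliding window lengths (PSW, data
#' volume), sampling frequencies (SF, data velocity), prediction horizons
#' (PH) and forecasting methods, plus the rolling-evaluation controls.
#' Validation happens here, before any computation: every `(psw, sf)` pair
#' must give an integer window size. A horizon that is not a multiple of the
#' sampling interval is evaluated at the next on-grid step
#' (`h = ceiling(ph/sf)`), with the effective horizon recorded per
#' prediction; `ph_exact = TRUE` makes such pairs an error instead.
#'
#' @param psw_hours PSW lengths in hours (study design: 3, 6, 12, 24, 36).
#' @param sf_min Sampling intervals in minutes (study design: 5, 10, 15).
#' @param ph_min Prediction horizons in minutes (study design: 15, 30, 45,
#'   60).
#' @param methods Subset of `"arima"`, `"rf"`, `"svr"`, `"naive"`.
#' @param refit_every Refit cadence in evaluation origins: models are refit
#'   every `refit_every`-th origin and reused (ARIMA re-filters its
#'   coefficients on the current window) in between. Every origin is always
#'   evaluated.
#' @param burn_in_hours History (hours) reserved before the first evaluation
#'   origin; defaults to `max(psw_hours)` so that every grid cell is scored
#'   on the identical origin set.
#' @param m Embedding dimension for the RF/SVR lag vectors.
#' @param seed Seed recorded for the run.
#' @param rf,svr Hyperparameters, see [rf_params()] and [svr_params()].
#' @param order_grid ARIMA candidate orders, see [default_order_grid()].
#' @param ph_exact Error on horizons that are not multiples of the sampling
#'   interval instead of rounding the step count up.
#' @return An object of class `eval_config`.
#' @export
eval_config <- function(psw_hours = c(3, 6, 12, 24, 36),
                        sf_min = c(5, 10, 15),
                        ph_min = c(15, 30, 45, 60),
                        methods = c("arima", "rf", "svr"),
                        refit_every = 1,
                        burn_in_hours = NULL,
                        m = 6, seed = 1,
                        rf = rf_params(), svr = svr_params(),
                        order_grid = default_order_grid(),
                        ph_exact = FALSE) {
  if (!length(psw_hours) || !length(sf_min) || !length(ph_min) ||
      !length(methods))
    stopf("'psw_hours', 'sf_min', 'ph_min' and 'methods' must be non-empty")
  bad <- !methods %in% c("arima", "rf", "svr", "naive")
  if (any(bad)) stopf("unknown method(s): %s",
                      paste(methods[bad], collapse = ", "))
  for (psw in psw_hours) for (sf in sf_min) window_size(psw, sf)
  if (ph_exact) {
    for (ph in ph_min) for (sf in sf_min)
      if (ph %% sf != 0)
        stopf("PH %g min is not a multiple of SF %g min", ph, sf)
  }
  if (refit_every < 1 || refit_every != round(refit_every))
    stopf("'refit_every' must be a positive integer")
  burn <- burn_in_hours %||% max(psw_hours)
  if (burn < max(psw_hours))
    stopf("'burn_in_hours' must cover the largest PSW (%g h)", max(psw_hours))
  structure(list(psw_hours = psw_hours, sf_min = sf_min, ph_min = ph_min,
                 methods = methods, refit_every = as.integer(refit_every),
                 burn_in_hours = burn, m = as.integer(m), seed = seed,
                 rf = rf, svr = svr, order_grid = order_grid,
                 ph_exact = ph_exact),
            class = "eval_config")
}

#' Preset grids for the two experiments
#'
#' `experiment1_config()` varies data volume: PSW 3--36 h crossed with PH
#' 15--60 min at a fixed SF of 5 min (20 cells per method).
#' `experiment2_config()` varies data velocity: SF 5, 10, 15 min crossed
#' with PH 15--60 min at the fixed 6-h PSW (12 cells per method).
#'
#' @param ... Overrides passed to [eval_config()].
#' @return An `eval_config`.
#' @export
experiment1_config <- function(...) {
  eval_config(psw_hours = c(3, 6, 12, 24, 36), sf_min = 5,
              ph_min = c(15, 30, 45, 60), ...)
}

#' @rdname experiment1_config
#' @export
experiment2_config <- function(...) {
  eval_config(psw_hours = 6, sf_min = c(5, 10, 15),
              ph_min = c(15, 30, 45, 60), ...)
}

#' Enumerate the cells of an evaluation grid
#'
#' @param config An [eval_config()].
#' @return A data.frame with one row per (method, psw_hours, sf_min, ph_min)
#'   cell.
#' @export
grid_cells <- function(config) {
  expand.grid(method = config$methods, psw_hours = config$psw_hours,
              sf_min = config$sf_min, ph_min = config$ph_min,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

horizon_steps <- function(ph_min, sf_min, ph_exact = FALSE) {
  h <- ph_min / sf_min
  if (abs(h - round(h)) > 1e-9) {
    if (ph_exact)
      stopf("PH %g min is not a multiple of SF %g min", ph_min, sf_min)
    h <- ceiling(h)
  }
  as.integer(round(h))
}

#' Rolling-origin evaluation of one grid cell on one patient series
#'
#' Walks the forecast origin through the series: at every origin after the
#' burn-in, the trailing window of `psw_hours` is formed, a patient-centric
#' model is fit (every `refit_every`-th origin; reused in between, with
#' ARIMA re-filtering its coefficients on the current window), a point
#' forecast `ph_min` ahead is issued, and it is paired with the reading the
#' sensor actually produced at the target time.
#'
#' @param series A `sampled_series` from [resample()].
#' @param method One of `"arima"`, `"rf"`, `"svr"`, `"naive"`.
#' @param psw_hours Past-window length (hours).
#' @param ph_min Prediction horizon (minutes).
#' @param config An [eval_config()]; its `burn_in_hours`, `refit_every`,
#'   `m`, hyperparameters and order grid are honored.
#' @return A data.frame of prediction records (`patient_id`, `origin_time`,
#'   `target_time`, `y_true`, `y_pred`, `method`, `psw_hours`, `sf_min`,
#'   `ph_min`, `ph_eff_min`), in chronological order, with a `log` attribute
#'   recording the refit origins and (for ARIMA) the selected order.
#' @examples
#' coh <- generate_cohort(n_patients = 1, duration_days = 2, seed = 1)
#' s <- resample(coh$sensor[[1]], 5)
#' cfg <- eval_config(psw_hours = 6, sf_min = 5, ph_min = 15,
#'                    methods = "naive")
#' rec <- rolling_evaluate(s, "naive", psw_hours = 6, ph_min = 15, cfg)
#' nrow(rec)  # 502 origins
#' @export
rolling_evaluate <- function(series, method, psw_hours, ph_min,
                             config = eval_config(psw_hours = psw_hours,
                                                  sf_min = series$sf_min,
                                                  ph_min = ph_min,
                                                  methods = method)) {
  if (!inherits(series, "sampled_series"))
    stopf("'series' must be a sampled_series from resample()")
  if (!method %in% c("arima", "rf", "svr", "naive"))
    stopf("unknown method '%s'", method)
  sf <- series$sf_min
  n <- window_size(psw_hours, sf)
  h <- horizon_steps(ph_min, sf, config$ph_exact)
  burn_h <- max(config$burn_in_hours %||% psw_hours, psw_hours)
  burn <- window_size(burn_h, sf)
  N <- length(series$values)
  first <- max(burn, n)
  if (N < first + h)
    stopf("series too short: need at least %d samples (burn-in %g h + horizon), got %d",
          first + h, burn_h, N)
  origins <- first:(N - h)

  model <- NULL
  selected_order <- NULL
  refit_at <- integer(0)
  y_pred <- numeric(length(origins))
  for (k in seq_along(origins)) {
    i <- origins[k]
    window <- make_window(series, i, psw_hours)
    refit <- is.null(model) || ((k - 1L) %% config$refit_every == 0L)
    if (refit) {
      model <- switch(method,
        naive = fit_naive(window),
        arima = {
          mdl <- fit_arima(window, order_grid = config$order_grid,
                           order = selected_order)
          # order selection is run once per evaluation; later refits
          # re-estimate coefficients at the selected order
          if (is.null(selected_order) && !isTRUE(mdl$degenerate))
            selected_order <- mdl$order
          mdl
        },
        rf = fit_ml(embed_window(window, config$m, h), "rf", config$rf),
        svr = fit_ml(embed_window(window, config$m, h), "svr", config$svr))
      refit_at <- c(refit_at, i)
    }
    y_pred[k] <- predict(model, window, h)
  }
  records <- data.frame(patient_id = series$patient_id,
                        origin_time = series$timestamps[origins],
                        target_time = series$timestamps[origins + h],
                        y_true = series$values[origins + h],
                        y_pred = y_pred,
                        method = method, psw_hours = psw_hours, sf_min = sf,
                        ph_min = ph_min, ph_eff_min = h * sf,
                        stringsAsFactors = FALSE)
  attr(records, "log") <- list(refit_origins = refit_at,
                               arima_order = selected_order,
                               n = n, h = h, burn_in_hours = burn_h)
  records
}

#' Root mean square forecast error
#'
#' `sqrt(mean((y_pred - y_true)^2))` over a set of prediction records.
#'
#' @param records A data.frame with columns `y_true` and `y_pred` (as
#'   produced by [rolling_evaluate()]).
#' @return RMSE in mg/dL.
#' @export
rmse <- function(records) {
  if (is.null(records) || nrow(records) == 0)
    stopf("cannot compute RMSE of zero records")
  if (!all(c("y_true", "y_pred") %in% names(records)))
    stopf("'records' must have columns y_true and y_pred")
  sqrt(mean((records$y_pred - records$y_true)^2))
}

#' Run a full evaluation grid over a cohort
#'
#' Evaluates every (method, PSW, SF, PH) cell of the configuration for every
#' patient, producing one RMSE per patient per cell. The configuration is
#' validated before any computation starts; the shared burn-in (the largest
#' PSW in the run) guarantees all cells are scored on the identical origin
#' set.
#'
#' @param cohort A `cgm_cohort`, or a list of `sensor_trace` objects (e.g.
#'   from [read_cgm_csv()]).
#' @param config An [eval_config()] such as [experiment1_config()] or
#'   [experiment2_config()].
#' @param quiet Suppress per-patient progress messages.
#' @return A `cgm_grid`: list with `rmse` (data.frame `method, psw_hours,
#'   sf_min, ph_min, patient_id, rmse_mgdl, n_records`) and `config`.
#' @export
run_grid <- function(cohort, config, quiet = FALSE) {
  traces <- if (inherits(cohort, "cgm_cohort")) cohort$sensor else cohort
  if (!length(traces)) stopf("empty cohort")
  if (!inherits(config, "eval_config"))
    stopf("'config' must be an eval_config")
  cells <- grid_cells(config)
  out <- vector("list", length(traces) * nrow(cells))
  r <- 0L
  for (tr in traces) {
    sampled <- lapply(stats::setNames(config$sf_min, config$sf_min),
                      function(sf) resample(tr, sf))
    if (!quiet)
      message(sprintf("evaluating patient %s (%d cells)", tr$patient_id,
                      nrow(cells)))
    for (ci in seq_len(nrow(cells))) {
      cell <- cells[ci, ]
      rec <- rolling_evaluate(sampled[[as.character(cell$sf_min)]],
                              cell$method, cell$psw_hours, cell$ph_min,
                              config)
      r <- r + 1L
      out[[r]] <- data.frame(method = cell$method,
                             psw_hours = cell$psw_hours,
                             sf_min = cell$sf_min, ph_min = cell$ph_min,
                             patient_id = tr$patient_id,
                             rmse_mgdl = rmse(rec),
                             n_records = nrow(rec),
                             stringsAsFactors = FALSE)
    }
  }
  structure(list(rmse = do.call(rbind, out[seq_len(r)]), config = config),
            class = "cgm_grid")
}

#' @export
print.cgm_grid <- function(x, ...) {
  cat(sprintf("<cgm_grid> %d cell evaluations over %d patients\n",
              nrow(x$rmse), length(unique(x$rmse$patient_id))))
  invisible(x)
}

#' Cross-patient aggregation of a grid result
#'
#' Unweighted cross-patient mean and sample (n-1) standard deviation of the
#' per-patient RMSEs in every cell. Per-patient errors are never pooled
#' across patients before averaging. With a single patient the standard
#' deviation is reported as 0 (with a message).
#'
#' @param x A `cgm_grid` from [run_grid()].
#' @param ... Unused.
#' @return A data.frame `method, psw_hours, sf_min, ph_min, n_patients,
#'   mean_rmse, sd_rmse`.
#' @export
aggregate.cgm_grid <- function(x, ...) {
  df <- x$rmse
  key <- interaction(df$method, df$psw_hours, df$sf_min, df$ph_min,
                     drop = TRUE)
  rows <- lapply(split(df, key), function(cell) {
    data.frame(method = cell$method[1], psw_hours = cell$psw_hours[1],
               sf_min = cell$sf_min[1], ph_min = cell$ph_min[1],
               n_patients = nrow(cell),
               mean_rmse = mean(cell$rmse_mgdl),
               sd_rmse = if (nrow(cell) > 1) stats::sd(cell$rmse_mgdl) else 0,
               stringsAsFactors = FALSE)
  })
  if (any(vapply(rows, function(r) r$n_patients, numeric(1)) == 1))
    message("single-patient cell(s): cross-patient sd reported as 0")
  out <- do.call(rbind, rows)
  out <- out[order(out$method, out$sf_min, out$ph_min, out$psw_hours), ]
  rownames(out) <- NULL
  out
}

#' Past-window length minimizing mean RMSE for one method/SF/PH slice
#'
#' @param summary An aggregate table from [aggregate.cgm_grid()].
#' @param method,sf_min,ph_min The slice to query.
#' @param psw_hours Optional expected set of PSW values; an error is raised
#'   if any is missing from the slice.
#' @return The PSW (hours) with the smallest mean RMSE; ties break toward
#'   the smallest PSW.
#' @export
find_optimal_psw <- function(summary, method, sf_min, ph_min,
                             psw_hours = NULL) {
  sl <- summary[summary$method == method & summary$sf_min == sf_min &
                summary$ph_min == ph_min, ]
  if (nrow(sl) == 0)
    stopf("no cells for method '%s' at SF %g, PH %g", method, sf_min, ph_min)
  if (!is.null(psw_hours)) {
    miss <- setdiff(psw_hours, sl$psw_hours)
    if (length(miss))
      stopf("missing PSW cell(s): %s h", paste(miss, collapse = ", "))
  }
  sl <- sl[order(sl$psw_hours), ]
  sl$psw_hours[which.min(sl$mean_rmse)]
}

#' Persist grid results as CSV
#'
#' Writes `results.csv` (per-patient RMSEs) and `aggregate.csv`
#' (cross-patient mean and sd per cell).
#'
#' @param grid A `cgm_grid`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_grid_csv <- function(grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "results.csv")
  p2 <- file.path(dir, "aggregate.csv")
  write.csv(grid$rmse, p1, row.names = FALSE, quote = FALSE)
  write.csv(aggregate(grid), p2, row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}

#' Bar chart of mean RMSE by PSW or SF, faceted by method
#'
#' Mirrors the layout of the two experiment summaries: grouped bars of
#' cross-patient mean RMSE (error bars = +/- 1 sd) against the prediction
#' horizon, one bar group per PSW (experiment 1) or SF (experiment 2).
#'
#' @param summary An aggregate table from [aggregate.cgm_grid()].
#' @param by `"psw_hours"` or `"sf_min"` for the bar grouping.
#' @return A ggplot object.
#' @export
plot_grid_rmse <- function(summary, by = c("psw_hours", "sf_min")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stopf("plot_grid_rmse requires the ggplot2 package")
  by <- match.arg(by)
  summary$group <- factor(summary[[by]])
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = factor(.data$ph_min), y = .data$mean_rmse,
                               fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.85),
                      width = 0.8) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_rmse - .data$sd_rmse,
                                        ymax = .data$mean_rmse + .data$sd_rmse),
                           position = ggplot2::position_dodge(width = 0.85),
                           width = 0.3) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = "prediction horizon (min)", y = "mean RMSE (mg/dL)",
                  fill = if (by == "psw_hours") "PSW (h)" else "SF (min)") +
    ggplot2::theme_minimal()
}
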