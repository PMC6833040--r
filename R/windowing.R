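#' Resample a trace to the experiment's sampling frequency
#'
#' Instantaneous point-sampling (no averaging) on a grid anchored at the
#' trace start: indices 1, 1+k, 1+2k, ... for `k = sf_min / native step`.
#' FGM readings are instantaneous estimates, so subsampling -- not block
#' averaging -- is the faithful way to lower the data velocity.
#'
#' @param trace A `sensor_trace` or `glucose_trace` at a uniform native
#'   step; a `sampled_series` is also accepted (so resampling at a series'
#'   own frequency is the identity).
#' @param sf_min Sampling interval in minutes; must be a positive multiple of
#'   the native step. The study design uses 5, 10 and 15 min.
#' @return A `sampled_series`: list with `patient_id`, `sf_min`, `values`,
#'   `timestamps`.
#' @export
resample <- function(trace, sf_min) {
  if (inherits(trace, "glucose_trace")) {
    step <- trace$step_min
    ts <- trace_timestamps(trace)
  } else if (inherits(trace, "sampled_series")) {
    step <- trace$sf_min
    ts <- trace$timestamps
  } else if (inherits(trace, "sensor_trace")) {
    d <- diff(as.numeric(trace$timestamps)) / 60
    if (length(d) && max(abs(d - d[1])) > 1e-9)
      stopf("trace is not uniformly sampled")
    step <- if (length(d)) d[1] else 1
    ts <- trace$timestamps
  } else stopf("'trace' must be a sensor_trace or glucose_trace")
  if (!is.numeric(sf_min) || sf_min <= 0)
    stopf("'sf_min' must be positive")
  k <- sf_min / step
  if (abs(k - round(k)) > 1e-9)
    stopf("'sf_min' = %g is not a multiple of the native step (%g min)",
          sf_min, step)
  idx <- seq(1L, length(trace$values), by = as.integer(round(k)))
  structure(list(patient_id = trace$patient_id, sf_min = sf_min,
                 values = trace$values[idx], timestamps = ts[idx]),
            class = "sampled_series")
}

window_size <- function(psw_hours, sf_min) {
  n <- psw_hours * 60 / sf_min
  if (abs(n - round(n)) > 1e-9)
    stopf("PSW %g h at SF %g min gives a non-integer window size", psw_hours,
          sf_min)
  as.integer(round(n))
}

#' Extract the past sliding window ending at a given index
#'
#' Returns the training set of `n = psw_hours * 60 / sf_min` most recent
#' values up to and including `end_index` (oldest first) -- the past sliding
#' window (PSW) whose length controls data volume.
#'
#' @param series A `sampled_series`.
#' @param end_index 1-based index of the newest sample in the window.
#' @param psw_hours Past-window length in hours (study design: 3--36 h).
#' @return A `cgm_window`: list with `values`, `n`, `psw_hours`, `sf_min`.
#' @examples
#' s <- structure(list(patient_id = "P01", sf_min = 5, values = rnorm(100),
#'                     timestamps = Sys.time() + (0:99) * 300),
#'                class = "sampled_series")
#' w <- make_window(s, end_index = 80, psw_hours = 6)
#' w$n  # 72
#' @export
make_window <- function(series, end_index, psw_hours) {
  n <- window_size(psw_hours, series$sf_min)
  if (end_index < n)
    stopf(paste0("insufficient history: window of n = %d samples needs ",
                 "end_index >= %d (burn-in %g h), got %d"),
          n, n, psw_hours, end_index)
  if (end_index > length(series$values))
    stopf("'end_index' beyond the series end")
  structure(list(values = series$values[(end_index - n + 1L):end_index],
                 n = n, psw_hours = psw_hours, sf_min = series$sf_min),
            class = "cgm_window")
}

#' FIFO update of a sliding window
#'
#' Drops the oldest observation, shifts the rest one position up, and
#' appends `new_value` as the newest one; the window length is preserved and
#' the input window is not modified.
#'
#' @param window A `cgm_window`.
#' @param new_value New glucose reading (mg/dL), finite.
#' @return The updated `cgm_window`.
#' @export
slide_update <- function(window, new_value) {
  if (!inherits(window, "cgm_window")) stopf("'window' must be a cgm_window")
  if (!is.numeric(new_value) || length(new_value) != 1 || !is.finite(new_value))
    stopf("'new_value' must be a single finite number")
  window$values <- c(window$values[-1L], new_value)
  window
}

#' Time-delay embedding of a window into supervised pairs
#'
#' Builds the direct-strategy training set for the machine-learning
#' forecasters: every chronologically contiguous lag vector
#' `(x[t-m+1], ..., x[t])` within the window paired with the target
#' `x[t+h]`, i.e. the value `h` steps (`h * sf_min` minutes) ahead.
#'
#' @param window A `cgm_window` of length `n`.
#' @param m Embedding dimension (number of lags per feature vector).
#' @param h Horizon in steps (>= 1).
#' @return A `supervised_set`: list with feature matrix `X`
#'   (`n - m - h + 1` rows, `m` columns, oldest lag first), targets `y`, and
#'   metadata `m`, `h`, `n`, `sf_min`, plus the window mean/sd used for
#'   standardization by the SVR.
#' @export
embed_window <- function(window, m = 6, h) {
  if (!inherits(window, "cgm_window")) stopf("'window' must be a cgm_window")
  if (m < 1 || h < 1) stopf("'m' and 'h' must be >= 1")
  n <- window$n
  if (m + h > n)
    stopf("window too small for embedding: m + h = %d > n = %d", m + h, n)
  v <- window$values
  X <- stats::embed(v, m)[, m:1, drop = FALSE]   # rows end at t = m..n
  n_pairs <- n - m - h + 1L
  X <- X[seq_len(n_pairs), , drop = FALSE]
  y <- v[(m + h):n]
  colnames(X) <- paste0("lag", (m - 1):0)
  structure(list(X = X, y = y, m = as.integer(m), h = as.integer(h),
                 n = n, sf_min = window$sf_min,
                 win_mean = mean(v), win_sd = stats::sd(v)),
            class = "supervised_set")
}
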