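# Shared fixtures, generated once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixtures)) assign(name, make(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# 2 patients x 2 days, used by cheap pipeline tests
small_cohort <- function() {
  fixture("small_cohort",
          function() generate_cohort(n_patients = 2, duration_days = 2,
                                     seed = 11))
}

small_series5 <- function() {
  fixture("small_series5", function() resample(small_cohort()$sensor[[1]], 5))
}

# Build a sampled_series directly from a numeric vector
make_series <- function(values, sf_min = 5, patient_id = "S01") {
  structure(list(patient_id = patient_id, sf_min = sf_min,
                 values = as.numeric(values),
                 timestamps = as.POSIXct("2018-03-01 00:00:00", tz = "UTC") +
                   (seq_along(values) - 1) * sf_min * 60),
            class = "sampled_series")
}

# Build a 1-min glucose_trace directly from a numeric vector
make_truth <- function(values, patient_id = "T01") {
  structure(list(patient_id = patient_id,
                 start_time = as.POSIXct("2018-03-01 00:00:00", tz = "UTC"),
                 step_min = 1, values = as.numeric(values)),
            class = "glucose_trace")
}

# Wrap a numeric vector as a cgm_window (for forecaster unit tests)
make_window_raw <- function(values, sf_min = 5) {
  n <- length(values)
  structure(list(values = as.numeric(values), n = n,
                 psw_hours = n * sf_min / 60, sf_min = sf_min),
            class = "cgm_window")
}
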