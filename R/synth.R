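#' Simulation parameters for synthetic glucose dynamics
#'
#' Parameters of the ground-truth glucose model used by
#' [simulate_ground_truth()]. The model is additive: a baseline level, a
#' circadian sinusoid, gamma-shaped meal excursions whose tails decay at the
#' fast-insulin rate, and Ornstein--Uhlenbeck (OU) physiological noise, all
#' clamped to a physiological range. It emulates a type 1 diabetes patient on
#' a basal-bolus regimen with a regular daily routine.
#'
#' @param baseline_mgdl Baseline glucose level (mg/dL).
#' @param circadian_amplitude Amplitude of the circadian sinusoid (mg/dL).
#' @param circadian_phase_h Phase of the circadian component (hours); the
#'   sinusoid peaks 6 h after this clock time. The default of 2 puts the peak
#'   at 08:00, a dawn-phenomenon-like morning rise.
#' @param meals_per_day Number of meals per day (non-negative integer).
#' @param meal_rise_range Length-2 numeric, the range (mg/dL) from which each
#'   meal's peak glucose excursion is drawn uniformly.
#' @param meal_time_to_peak Minutes from meal start to peak excursion.
#' @param insulin_decay_halflife Half-life (minutes) of the post-meal decay
#'   driven by fast-acting insulin.
#' @param ou_theta Mean-reversion rate of the OU noise (1/min).
#' @param ou_sigma Diffusion scale of the OU noise (mg/dL per sqrt(min)).
#' @param floor_mgdl,ceiling_mgdl Physiological clamp applied to the
#'   ground truth (mg/dL); must satisfy 20 <= floor < ceiling <= 600.
#' @return An object of class `sim_params`.
#' @seealso [simulate_ground_truth()], [generate_cohort()]
#' @export
sim_params <- function(baseline_mgdl = 120,
                       circadian_amplitude = 15,
                       circadian_phase_h = 2,
                       meals_per_day = 4,
                       meal_rise_range = c(40, 120),
                       meal_time_to_peak = 45,
                       insulin_decay_halflife = 60,
                       ou_theta = 0.01,
                       ou_sigma = 0.8,
                       floor_mgdl = 20,
                       ceiling_mgdl = 600) {
  p <- list(baseline_mgdl = baseline_mgdl,
            circadian_amplitude = circadian_amplitude,
            circadian_phase_h = circadian_phase_h,
            meals_per_day = meals_per_day,
            meal_rise_range = meal_rise_range,
            meal_time_to_peak = meal_time_to_peak,
            insulin_decay_halflife = insulin_decay_halflife,
            ou_theta = ou_theta,
            ou_sigma = ou_sigma,
            floor_mgdl = floor_mgdl,
            ceiling_mgdl = ceiling_mgdl)
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  chk_pos <- function(field) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stopf("invalid sim_params: '%s' must be a single positive number", field)
  }
  for (f in c("baseline_mgdl", "circadian_amplitude", "meal_time_to_peak",
              "insulin_decay_halflife", "ou_theta", "ou_sigma")) chk_pos(f)
  if (!is.numeric(p$circadian_phase_h) || length(p$circadian_phase_h) != 1 ||
      !is.finite(p$circadian_phase_h))
    stopf("invalid sim_params: 'circadian_phase_h' must be a finite number")
  if (!is.numeric(p$meals_per_day) || length(p$meals_per_day) != 1 ||
      p$meals_per_day < 0 || p$meals_per_day != round(p$meals_per_day))
    stopf("invalid sim_params: 'meals_per_day' must be a non-negative integer")
  r <- p$meal_rise_range
  if (!is.numeric(r) || length(r) != 2 || any(!is.finite(r)) ||
      any(r <= 0) || r[1] > r[2])
    stopf("invalid sim_params: 'meal_rise_range' must be an increasing positive pair")
  if (!is.numeric(p$floor_mgdl) || !is.numeric(p$ceiling_mgdl) ||
      p$floor_mgdl < 20 || p$ceiling_mgdl > 600 ||
      p$floor_mgdl >= p$ceiling_mgdl)
    stopf("invalid sim_params: require 20 <= 'floor_mgdl' < 'ceiling_mgdl' <= 600")
  invisible(p)
}

# Daily windows (hours) within which meal times are drawn; mirrors a
# regular breakfast / lunch / snack / dinner routine.
MEAL_WINDOWS <- list(c(7, 9), c(12, 14), c(16, 17), c(20, 22))

# Normalized meal kernel: gamma-shaped rise peaking (value 1) at
# `tp` minutes, tail decaying exponentially at the fast-insulin rate.
meal_kernel <- function(t_min, tp, halflife) {
  b <- halflife / log(2)
  a <- tp / b
  k <- t_min^a * exp(-t_min / b)
  k / (tp^a * exp(-tp / b))
}

#' Simulate ground-truth glucose dynamics for one patient
#'
#' Generates a uniformly sampled (1-min step) interstitial glucose series:
#' baseline + circadian sinusoid + randomized gamma-shaped meal excursions
#' with insulin-driven exponential decay + Ornstein--Uhlenbeck noise, clamped
#' to `[floor_mgdl, ceiling_mgdl]`. Deterministic for fixed
#' `(params, duration_days, seed)`.
#'
#' @param params A [sim_params()] object.
#' @param duration_days Number of days to simulate (>= 1).
#' @param seed Integer seed for this patient's randomness.
#' @param patient_id Identifier stored on the trace.
#' @param start_time `POSIXct` start of the series (UTC midnight by default,
#'   so clock-time components line up with meal windows).
#' @return A `glucose_trace`: list with `patient_id`, `start_time`,
#'   `step_min` (always 1) and `values` (length `duration_days * 1440`).
#' @examples
#' tr <- simulate_ground_truth(sim_params(), duration_days = 2, seed = 7)
#' length(tr$values)  # 2880
#' @export
simulate_ground_truth <- function(params = sim_params(), duration_days, seed,
                                  patient_id = "P01",
                                  start_time = as.POSIXct("2018-03-01 00:00:00",
                                                          tz = "UTC")) {
  validate_sim_params(params)
  if (!is.numeric(duration_days) || length(duration_days) != 1 ||
      duration_days < 1 || duration_days != round(duration_days))
    stopf("invalid 'duration_days': must be a positive integer")
  if (missing(seed) || is.null(seed)) stopf("a 'seed' must be provided")

  n <- duration_days * 1440L
  t_min <- seq_len(n) - 1L           # minutes since start
  tod_h <- (t_min / 60) %% 24        # clock time in hours

  g <- rep(params$baseline_mgdl, n)
  g <- g + params$circadian_amplitude *
    sin(2 * pi * (tod_h - params$circadian_phase_h) / 24)

  with_seed(seed, {
    # meal excursions: one draw per (day, meal slot), time uniform within
    # the slot's window, peak height uniform in meal_rise_range
    if (params$meals_per_day > 0) {
      support <- 0:720  # kernel support, minutes
      for (day in seq_len(duration_days) - 1L) {
        for (j in seq_len(params$meals_per_day)) {
          win <- MEAL_WINDOWS[[((j - 1L) %% 4L) + 1L]]
          t_meal <- round((day * 24 + runif(1, win[1], win[2])) * 60)
          amp <- runif(1, params$meal_rise_range[1], params$meal_rise_range[2])
          idx <- t_meal + support
          keep <- idx >= 0 & idx < n
          g[idx[keep] + 1L] <- g[idx[keep] + 1L] +
            amp * meal_kernel(support[keep], params$meal_time_to_peak,
                              params$insulin_decay_halflife)
        }
      }
    }
    # OU noise via exact discretization at dt = 1 min
    theta <- params$ou_theta; sigma <- params$ou_sigma
    a1 <- exp(-theta)
    sd_step <- sigma * sqrt((1 - exp(-2 * theta)) / (2 * theta))
    sd_stat <- sigma / sqrt(2 * theta)
    z <- rnorm(n)
    x <- c(sd_stat * z[1], sd_step * z[-1])
    g <- g + as.numeric(stats::filter(x, a1, method = "recursive"))
  })

  g <- pmin(pmax(g, params$floor_mgdl), params$ceiling_mgdl)
  structure(list(patient_id = patient_id, start_time = start_time,
                 step_min = 1, values = g),
            class = "glucose_trace")
}

#' @export
print.glucose_trace <- function(x, ...) {
  cat(sprintf("<glucose_trace> patient %s: %d values at %g-min step from %s\n",
              x$patient_id, length(x$values), x$step_min,
              format(x$start_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")))
  cat(sprintf("  mean %.1f mg/dL, range [%.1f, %.1f]\n",
              mean(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Flash glucose monitor error-model parameters
#'
#' Describes how a flash glucose monitor (FGM) distorts the true glucose
#' signal: a first-order interstitial lag, multiplicative Gaussian reading
#' noise, and clipping to the sensor's reporting range with low/high
#' saturation flags.
#'
#' The default `sigma_rel` is calibrated so that the sensor's mean absolute
#' relative difference (MARD) comes out at 11.4%: for multiplicative
#' Gaussian noise, `E|eps| = sigma_rel * sqrt(2/pi)`, so
#' `sigma_rel = 0.114 / sqrt(2/pi) = 0.1429`. The default lag time constant
#' of 7.5 min is the midpoint of the 5--10 min interstitial delay typical of
#' these sensors.
#'
#' @param lag_tau_min Time constant (minutes) of the first-order lag filter;
#'   0 disables the lag.
#' @param sigma_rel Standard deviation of the multiplicative relative noise.
#' @param clip_low,clip_high Sensor reporting range (mg/dL); readings outside
#'   are clipped and flagged `"low"` / `"high"`.
#' @return An object of class `sensor_params`.
#' @export
sensor_params <- function(lag_tau_min = 7.5, sigma_rel = 0.1429,
                          clip_low = 40, clip_high = 500) {
  if (!is.numeric(lag_tau_min) || lag_tau_min < 0)
    stopf("invalid sensor_params: 'lag_tau_min' must be >= 0")
  if (!is.numeric(sigma_rel) || sigma_rel < 0)
    stopf("invalid sensor_params: 'sigma_rel' must be >= 0")
  if (!is.numeric(clip_low) || !is.numeric(clip_high) || clip_low >= clip_high)
    stopf("invalid sensor_params: require 'clip_low' < 'clip_high'")
  structure(list(lag_tau_min = lag_tau_min, sigma_rel = sigma_rel,
                 clip_low = clip_low, clip_high = clip_high),
            class = "sensor_params")
}

trace_timestamps <- function(trace) {
  trace$start_time + (seq_along(trace$values) - 1) * trace$step_min * 60
}

#' Apply the sensor error model to a ground-truth trace
#'
#' Transforms true glucose into FGM readings:
#' `reading = clip(lagged(truth) * (1 + eps))` with `eps ~ N(0, sigma_rel^2)`
#' i.i.d.; the lag is a first-order exponential filter with time constant
#' `lag_tau_min`, initialized at the first truth value. Samples outside the
#' reporting range are clipped to it and flagged `"low"` or `"high"`; all
#' others are flagged `"ok"`.
#'
#' @param truth A `glucose_trace` at 1-min step.
#' @param sensor A [sensor_params()] object.
#' @param seed Integer seed for the reading noise.
#' @return A `sensor_trace`: list with `patient_id`, `timestamps` (POSIXct),
#'   `values` and `flags`, same length as the input.
#' @export
apply_sensor_model <- function(truth, sensor = sensor_params(), seed) {
  if (!inherits(truth, "glucose_trace")) stopf("'truth' must be a glucose_trace")
  if (length(truth$values) == 0) stopf("empty trace")
  if (missing(seed) || is.null(seed)) stopf("a 'seed' must be provided")

  x <- truth$values
  if (sensor$lag_tau_min > 0) {
    alpha <- exp(-truth$step_min / sensor$lag_tau_min)
    x <- as.numeric(stats::filter((1 - alpha) * x, alpha,
                                  method = "recursive", init = x[1]))
  }
  raw <- with_seed(seed, x * (1 + rnorm(length(x), 0, sensor$sigma_rel)))
  flags <- rep("ok", length(raw))
  flags[raw < sensor$clip_low] <- "low"
  flags[raw > sensor$clip_high] <- "high"
  values <- pmin(pmax(raw, sensor$clip_low), sensor$clip_high)
  structure(list(patient_id = truth$patient_id,
                 timestamps = trace_timestamps(truth),
                 values = values, flags = flags),
            class = "sensor_trace")
}

#' @export
print.sensor_trace <- function(x, ...) {
  cat(sprintf("<sensor_trace> patient %s: %d readings (%d low, %d high)\n",
              x$patient_id, length(x$values),
              sum(x$flags == "low"), sum(x$flags == "high")))
  invisible(x)
}

#' Mean absolute relative difference between sensor and truth
#'
#' MARD, the standard CGM accuracy metric: the mean of
#' `|sensor - truth| / truth` over samples not saturated at the sensor's
#' range limits (flag `"ok"`).
#'
#' @param sensor A `sensor_trace`.
#' @param truth The aligned `glucose_trace` it was derived from.
#' @return MARD as a fraction (e.g. 0.114 for 11.4%).
#' @export
compute_mard <- function(sensor, truth) {
  if (length(sensor$values) != length(truth$values))
    stopf("length mismatch: sensor has %d samples, truth has %d",
          length(sensor$values), length(truth$values))
  ts <- trace_timestamps(truth)
  if (!isTRUE(all.equal(as.numeric(sensor$timestamps), as.numeric(ts))))
    stopf("sensor and truth timestamps are not aligned")
  if (any(truth$values <= 0)) stopf("truth contains non-positive glucose values")
  ok <- sensor$flags == "ok"
  if (!any(ok)) stopf("no unsaturated samples to compute MARD over")
  mean(abs(sensor$values[ok] - truth$values[ok]) / truth$values[ok])
}

#' Generate a synthetic FGM cohort
#'
#' Simulates `n_patients` independent patients and passes each ground-truth
#' series through the sensor error model. Per-patient seeds are derived from
#' the master seed by a fixed counter scheme
#' (`seed_i = (seed + 7919 * i) mod (2^31 - 1)`, with `seed_i + 1` and
#' `seed_i + 2` for the truth and sensor substreams), so any patient can be
#' regenerated in isolation. Inter-patient variability is emulated by
#' jittering baseline, circadian amplitude and meal sizes by a uniform
#' +/-20% factor per patient.
#'
#' @param n_patients Number of patients (>= 1); the emulated study cohort
#'   size is 25.
#' @param duration_days Days of wear per patient, between 1 and the 14-day
#'   sensor life.
#' @param params Cohort-level [sim_params()] before per-patient jitter.
#' @param sensor A [sensor_params()] object.
#' @param seed Master integer seed.
#' @return A `cgm_cohort`: list with `sensor` (list of `sensor_trace`),
#'   `truth` (list of `glucose_trace`), the generating parameters and the
#'   per-patient seeds.
#' @examples
#' coh <- generate_cohort(n_patients = 2, duration_days = 1, seed = 1)
#' sapply(coh$sensor, function(s) length(s$values))  # 1440 1440
#' @export
generate_cohort <- function(n_patients = 25, duration_days = 14,
                            params = sim_params(), sensor = sensor_params(),
                            seed) {
  if (!is.numeric(n_patients) || n_patients < 1)
    stopf("'n_patients' must be >= 1")
  if (!is.numeric(duration_days) || duration_days < 1)
    stopf("'duration_days' must be >= 1")
  if (duration_days > 14)
    stopf("'duration_days' = %g exceeds the 14-day sensor life", duration_days)
  if (missing(seed) || is.null(seed)) stopf("a 'seed' must be provided")
  validate_sim_params(params)

  ids <- sprintf("P%02d", seq_len(n_patients))
  patient_seeds <- vapply(seq_len(n_patients), function(i) derive_seed(seed, i),
                          integer(1))
  truth <- vector("list", n_patients)
  sens <- vector("list", n_patients)
  pparams <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    base_seed <- patient_seeds[i]
    jit <- with_seed(base_seed, runif(3, 0.8, 1.2))
    p_i <- params
    p_i$baseline_mgdl <- params$baseline_mgdl * jit[1]
    p_i$circadian_amplitude <- params$circadian_amplitude * jit[2]
    p_i$meal_rise_range <- params$meal_rise_range * jit[3]
    pparams[[i]] <- p_i
    truth[[i]] <- simulate_ground_truth(p_i, duration_days,
                                        seed = derive_seed(base_seed, 1),
                                        patient_id = ids[i])
    sens[[i]] <- apply_sensor_model(truth[[i]], sensor,
                                    seed = derive_seed(base_seed, 2))
  }
  structure(list(sensor = sens, truth = truth, params = params,
                 sensor_params = sensor, seed = seed,
                 patient_seeds = patient_seeds, patient_params = pparams,
                 duration_days = duration_days),
            class = "cgm_cohort")
}

#' @export
print.cgm_cohort <- function(x, ...) {
  cat(sprintf("<cgm_cohort> %d patients x %d days (master seed %s)\n",
              length(x$sensor), x$duration_days, format(x$seed)))
  invisible(x)
}
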