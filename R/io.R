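TS_FMT <- "%Y-%m-%dT%H:%M:%SZ"

format_ts <- function(t) format(t, TS_FMT, tz = "UTC")

parse_ts <- function(s) as.POSIXct(s, format = TS_FMT, tz = "UTC")

#' Write a cohort as per-patient CGM CSV files plus a JSON manifest
#'
#' One CSV per patient with columns
#' `patient_id, timestamp, glucose_mgdl, flag` (timestamps ISO-8601 UTC),
#' plus `manifest.json` recording the generating parameters and per-patient
#' seeds so the cohort can be regenerated exactly.
#'
#' @param cohort A `cgm_cohort` from [generate_cohort()], or a list of
#'   `sensor_trace` objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of the files written.
#' @export
write_cgm_csv <- function(cohort, dir) {
  traces <- if (inherits(cohort, "cgm_cohort")) cohort$sensor else cohort
  if (!length(traces)) stopf("no traces to write")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (tr in traces) {
    df <- data.frame(patient_id = tr$patient_id,
                     timestamp = format_ts(tr$timestamps),
                     glucose_mgdl = tr$values,
                     flag = tr$flags)
    path <- file.path(dir, paste0(tr$patient_id, ".csv"))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    paths <- c(paths, path)
  }
  if (inherits(cohort, "cgm_cohort")) {
    manifest <- list(
      n_patients = length(cohort$sensor),
      duration_days = cohort$duration_days,
      seed = cohort$seed,
      patient_seeds = as.list(cohort$patient_seeds),
      sim_params = unclass(cohort$params),
      sensor_params = unclass(cohort$sensor_params),
      files = basename(paths))
    mpath <- file.path(dir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, mpath)
  }
  invisible(paths)
}

#' Read CGM CSV files into sensor traces
#'
#' Reads one or more CSV files in the dialect written by [write_cgm_csv()]
#' (`patient_id, timestamp, glucose_mgdl, flag`; the `flag` column may be
#' omitted, in which case all rows are `"ok"`). Rows are validated: glucose
#' must lie within the sensor reporting range 40--500 mg/dL, timestamps must
#' parse and be strictly increasing per patient, and malformed rows are
#' reported with their line number.
#'
#' @param paths Character vector of CSV file paths.
#' @param clip_low,clip_high Accepted glucose range (mg/dL).
#' @return A list of `sensor_trace` objects, one per patient.
#' @export
read_cgm_csv <- function(paths, clip_low = 40, clip_high = 500) {
  rows <- NULL
  for (path in paths) {
    if (!file.exists(path)) stopf("file not found: %s", path)
    df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    if (nrow(df) == 0) stopf("no records in %s", path)
    need <- c("patient_id", "timestamp", "glucose_mgdl")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stopf("%s: missing required column(s): %s", path,
            paste(miss, collapse = ", "))
    if (!"flag" %in% names(df)) df$flag <- "ok"
    df$.line <- seq_len(nrow(df)) + 1L  # header is line 1
    df$.file <- path
    rows <- rbind(rows, df[c("patient_id", "timestamp", "glucose_mgdl",
                             "flag", ".line", ".file")])
  }
  g <- suppressWarnings(as.numeric(rows$glucose_mgdl))
  bad <- which(!is.finite(g))
  if (length(bad))
    stopf("%s line %d: malformed glucose value '%s'",
          rows$.file[bad[1]], rows$.line[bad[1]], rows$glucose_mgdl[bad[1]])
  oob <- which(g < clip_low | g > clip_high)
  if (length(oob))
    stopf("%s line %d: glucose %.1f mg/dL outside the sensor range %g-%g",
          rows$.file[oob[1]], rows$.line[oob[1]], g[oob[1]],
          clip_low, clip_high)
  ts <- parse_ts(rows$timestamp)
  bad <- which(is.na(ts))
  if (length(bad))
    stopf("%s line %d: malformed timestamp '%s'",
          rows$.file[bad[1]], rows$.line[bad[1]], rows$timestamp[bad[1]])
  if (!all(rows$flag %in% c("ok", "low", "high")))
    stopf("invalid flag value; expected ok/low/high")

  out <- list()
  for (pid in unique(rows$patient_id)) {
    sel <- rows$patient_id == pid
    o <- order(ts[sel])
    tsp <- ts[sel][o]
    if (anyDuplicated(as.numeric(tsp)))
      stopf("duplicate timestamps for patient %s", pid)
    out[[pid]] <- structure(list(patient_id = pid, timestamps = tsp,
                                 values = g[sel][o], flags = rows$flag[sel][o]),
                            class = "sensor_trace")
  }
  out
}

#' Assemble a serializable run configuration
#'
#' Bundles cohort, sensor and evaluation settings with the master seed into
#' one object whose JSON round-trip ([write_run_config()] /
#' [read_run_config()]) is lossless, so a completed run is reproducible from
#' its config file alone.
#'
#' @param sim A [sim_params()] object.
#' @param sensor A [sensor_params()] object.
#' @param eval A [eval_config()] object.
#' @param n_patients,duration_days Cohort dimensions.
#' @param out_dir Output directory recorded for the run.
#' @param seed Master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(sim = sim_params(), sensor = sensor_params(),
                       eval = eval_config(), n_patients = 25,
                       duration_days = 14, out_dir = ".", seed = 1) {
  structure(list(sim = sim, sensor = sensor, eval = eval,
                 n_patients = n_patients, duration_days = duration_days,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  x <- list(sim = unclass(config$sim), sensor = unclass(config$sensor),
            eval = unclass(config$eval), n_patients = config$n_patients,
            duration_days = config$duration_days, out_dir = config$out_dir,
            seed = config$seed)
  drop_null <- function(l) Filter(Negate(is.null), l)
  x$eval$rf <- drop_null(unclass(x$eval$rf))
  x$eval$svr <- drop_null(unclass(x$eval$svr))
  x$eval$order_grid <- as.list(x$eval$order_grid)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- x$eval
  run_config(sim = do.call(sim_params, x$sim),
             sensor = do.call(sensor_params, x$sensor),
             eval = eval_config(psw_hours = ev$psw_hours, sf_min = ev$sf_min,
                                ph_min = ev$ph_min, methods = ev$methods,
                                refit_every = ev$refit_every,
                                burn_in_hours = ev$burn_in_hours,
                                m = ev$m, seed = ev$seed,
                                rf = do.call(rf_params, as.list(ev$rf)),
                                svr = do.call(svr_params, as.list(ev$svr)),
                                order_grid = as.data.frame(ev$order_grid)),
             n_patients = x$n_patients, duration_days = x$duration_days,
             out_dir = x$out_dir, seed = x$seed)
}
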