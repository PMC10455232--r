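#' Catheterisation pressure-volume trace
#'
#' A `profile_trace` holds one catheterisation's sampled time series: time
#' since catheter insertion (s), cumulative drained volume (mL) and
#' intra-catheter pressure (cmH2O, corrected for atmospheric pressure, so
#' suction is negative). Traces are recorded at a nominal ~2.5 Hz by the lab
#' logging system; cumulative mass from the precision scale is converted to
#' volume at a urine density of 1 g/mL.
#'
#' Scale noise can make the raw cumulative reading decrease between adjacent
#' samples even though drained volume is physically non-decreasing. The
#' constructor repairs this with a running maximum (so the derived flowrate is
#' non-negative by construction) and records how many samples were touched in
#' the `"n_repaired"` attribute.
#'
#' @param subject_id Opaque subject identifier.
#' @param device `"MHZC"` (micro-hole zone catheter) or `"CEC"` (conventional
#'   eyelet catheter).
#' @param visit Visit number, 1 or 2.
#' @param t Numeric vector of timestamps (s), strictly increasing.
#' @param volume Cumulative drained volume (mL), same length as `t`.
#' @param pressure Intra-catheter pressure (cmH2O), same length as `t`.
#' @param sampling_rate_nominal Nominal sampling rate in Hz (default 2.5).
#' @param repair Apply the running-maximum monotone repair (default `TRUE`).
#'
#' @return An object of class `profile_trace`: a list with elements
#'   `subject_id`, `device`, `visit`, `t`, `volume`, `pressure`,
#'   `sampling_rate_nominal`, with attributes `n_repaired` (number of samples
#'   raised by the monotone repair) and `dropouts` (indices of sampling gaps
#'   longer than 2 s, flagged but never interpolated).
#' @examples
#' tr <- profile_trace("S01", "MHZC", 1, t = c(0, 0.4, 0.8),
#'                     volume = c(0, 1, 2), pressure = c(0, 0, 0))
#' tr$volume
#' @export
profile_trace <- function(subject_id, device, visit, t, volume, pressure,
                          sampling_rate_nominal = 2.5, repair = TRUE) {
  check_device(device)
  if (!visit %in% c(1L, 2L)) cf_data_error("`visit` must be 1 or 2")
  t <- as.numeric(t); volume <- as.numeric(volume)
  pressure <- as.numeric(pressure)
  n <- length(t)
  if (n < 2L)
    cf_data_error("a trace needs at least 2 samples")
  if (length(volume) != n || length(pressure) != n)
    cf_data_error("`t`, `volume` and `pressure` must have equal length")
  if (anyNA(t) || anyNA(volume) || anyNA(pressure))
    cf_data_error("trace samples must not contain NA")
  if (any(diff(t) <= 0))
    cf_data_error("`t` must be strictly increasing")
  if (!is.numeric(sampling_rate_nominal) || sampling_rate_nominal <= 0)
    cf_data_error("`sampling_rate_nominal` must be positive")

  n_repaired <- 0L
  if (repair) {
    repaired <- cummax(volume)
    n_repaired <- sum(repaired > volume)
    volume <- repaired
  } else if (any(diff(volume) < 0)) {
    cf_data_error("cumulative volume decreases and `repair` is FALSE")
  }

  dt_med <- median(diff(t))
  if (abs(sampling_rate_nominal - 2.5) < 1e-9 &&
      (dt_med < 0.2 || dt_med > 0.8))
    cf_data_error(sprintf(
      "median sampling interval %.3f s is outside [0.2, 0.8] s for a ~2.5 Hz trace",
      dt_med))

  structure(
    list(subject_id = as.character(subject_id), device = device,
         visit = as.integer(visit), t = t, volume = volume,
         pressure = pressure,
         sampling_rate_nominal = sampling_rate_nominal),
    n_repaired = n_repaired,
    dropouts = which(diff(t) > 2),
    class = "profile_trace"
  )
}

#' @export
print.profile_trace <- function(x, ...) {
  cat(sprintf(
    "<profile_trace> subject %s, %s, visit %d: %d samples over %.1f s, %.1f mL drained\n",
    x$subject_id, x$device, x$visit, length(x$t),
    x$t[length(x$t)] - x$t[1], max(x$volume)))
  if (attr(x, "n_repaired") > 0)
    cat(sprintf("  %d sample(s) monotone-repaired\n", attr(x, "n_repaired")))
  if (length(attr(x, "dropouts")) > 0)
    cat(sprintf("  %d sampling gap(s) > 2 s flagged\n",
                length(attr(x, "dropouts"))))
  invisible(x)
}

#' Column mapping for trace CSV files
#'
#' Describes how the columns of an on-disk trace CSV map onto the trace
#' fields. The drained amount may be logged either as volume (`volume_ml`) or
#' as mass from the weighing scale (`mass_g`); mass is converted to volume at
#' `density` g/mL (urine taken as 1.000).
#'
#' @param time,volume,mass,pressure Column names. Exactly one of the
#'   volume/mass columns must be present in a given file; if both are
#'   resolvable, `volume` wins.
#' @param density Mass-to-volume conversion factor (g/mL).
#' @return A list of class `trace_dialect`.
#' @export
trace_dialect <- function(time = "time_s", volume = "volume_ml",
                          mass = "mass_g", pressure = "pressure_cmh2o",
                          density = 1.0) {
  if (!is.numeric(density) || density <= 0)
    cf_config_error("`density` must be positive")
  structure(list(time = time, volume = volume, mass = mass,
                 pressure = pressure, density = density),
            class = "trace_dialect")
}

#' Read a trace dialect from a YAML config
#'
#' @param path Path to a YAML file whose keys are a subset of the
#'   [trace_dialect()] arguments.
#' @return A `trace_dialect`.
#' @export
read_dialect <- function(path) {
  if (!file.exists(path)) cf_config_error(sprintf("no such file: %s", path))
  cfg <- yaml::read_yaml(path)
  known <- names(formals(trace_dialect))
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0)
    cf_config_error(sprintf("unknown dialect key(s): %s",
                            paste(bad, collapse = ", ")))
  do.call(trace_dialect, cfg)
}

#' Read a catheterisation trace from CSV
#'
#' Reads one trace CSV (header row, comma separated), resolves columns via
#' the dialect, converts mass to volume when the file logs mass, applies the
#' monotone repair and validates the result. Metadata not stored in the file
#' (subject, device, visit) is passed through the arguments.
#'
#' @param path CSV file path.
#' @param dialect A [trace_dialect()].
#' @inheritParams profile_trace
#' @param quiet Suppress the repair-count message.
#' @return A [profile_trace()].
#' @export
read_trace <- function(path, dialect = trace_dialect(), subject_id = "?",
                       device = "MHZC", visit = 1,
                       sampling_rate_nominal = 2.5, quiet = FALSE) {
  if (!file.exists(path)) cf_format_error(sprintf("no such file: %s", path))
  df <- read.csv(path, check.names = FALSE)
  if (nrow(df) < 2L) cf_data_error("trace file has fewer than 2 samples")
  need <- function(col) {
    if (!col %in% names(df))
      cf_format_error(sprintf("column '%s' not found in %s", col, path))
    as.numeric(df[[col]])
  }
  t <- need(dialect$time)
  if (dialect$volume %in% names(df)) {
    vol <- as.numeric(df[[dialect$volume]])
  } else if (dialect$mass %in% names(df)) {
    vol <- as.numeric(df[[dialect$mass]]) / dialect$density
  } else {
    cf_format_error(sprintf("neither '%s' nor '%s' found in %s",
                            dialect$volume, dialect$mass, path))
  }
  p <- need(dialect$pressure)
  tr <- profile_trace(subject_id, device, visit, t, vol, p,
                      sampling_rate_nominal = sampling_rate_nominal)
  if (!quiet && attr(tr, "n_repaired") > 0)
    message(sprintf("%s: monotone repair raised %d sample(s)",
                    basename(path), attr(tr, "n_repaired")))
  tr
}

#' Write a catheterisation trace to CSV
#'
#' Inverse of [read_trace()]: `read_trace(write_trace(x, f))` reproduces `x`
#' to numeric round-trip tolerance.
#'
#' @param trace A [profile_trace()].
#' @param path Output CSV path.
#' @param dialect A [trace_dialect()]; the volume column name is used.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, dialect = trace_dialect()) {
  if (!inherits(trace, "profile_trace"))
    cf_data_error("`trace` must be a profile_trace")
  df <- data.frame(trace$t, trace$volume, trace$pressure)
  names(df) <- c(dialect$time, dialect$volume, dialect$pressure)
  ok <- tryCatch({
    write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) cf_format_error(sprintf("cannot write %s", path))
  invisible(path)
}

#' Catheter drainage-zone geometry
#'
#' The micro-hole zone catheter used here has 120 micro-holes of 0.13 mm^2
#' each over a 60 mm zone; the conventional eyelet comparator has two ~5 mm^2
#' eyelets at the tip.
#'
#' @param device `"MHZC"` or `"CEC"`.
#' @param n_holes Number of drainage openings.
#' @param hole_area Area per opening (mm^2).
#' @param zone_length Length of the drainage zone (mm).
#' @return A `catheter_spec` list.
#' @examples
#' total_drainage_area(catheter_spec("MHZC", 120, 0.13, 60))  # 15.6 mm^2
#' total_drainage_area(catheter_spec("CEC", 2, 5, 10))        # 10 mm^2
#' @export
catheter_spec <- function(device, n_holes, hole_area, zone_length = NA_real_) {
  check_device(device)
  if (!is.numeric(n_holes) || n_holes < 1 || n_holes != round(n_holes))
    cf_data_error("`n_holes` must be a positive integer count")
  if (!is.numeric(hole_area) || hole_area <= 0)
    cf_data_error("`hole_area` must be positive")
  structure(list(device = device, n_holes = as.integer(n_holes),
                 hole_area = hole_area, zone_length = zone_length),
            class = "catheter_spec")
}

#' @rdname catheter_spec
#' @param spec A `catheter_spec`.
#' @return `total_drainage_area()`: total open drainage area in mm^2.
#' @export
total_drainage_area <- function(spec) {
  if (!inherits(spec, "catheter_spec"))
    cf_data_error("`spec` must be a catheter_spec")
  spec$n_holes * spec$hole_area
}
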