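#' CGM trace on a 5-minute grid
#'
#' A `cgm_trace` holds one patient's timestamped glucose series aligned to a
#' nominal grid (default 5 minutes). Timestamps are strictly increasing and
#' every inter-reading interval is a positive integer multiple of the grid
#' step; a multiple greater than one encodes a sensor gap. Glucose values are
#' in mg/dL and must lie in (0, 500], the plausible sensor range.
#'
#' @param patient_id scalar identifier.
#' @param time `POSIXct` vector (or character parseable as UTC timestamps).
#' @param glucose numeric vector, mg/dL.
#' @param grid_step grid spacing in minutes (default 5).
#' @return an object of class `cgm_trace`: a list with elements `patient_id`,
#'   `time`, `glucose`, `grid_step`.
#' @examples
#' tr <- cgm_trace("p1", as.POSIXct("2023-01-01", tz = "UTC") + 300 * (0:5),
#'                 c(110, 100, 90, 69, 68, 75))
#' tr
#' @export
cgm_trace <- function(patient_id, time, glucose, grid_step = 5) {
  if (is.character(time)) {
    time <- parse_timestamps(time)
  }
  stopifnot(inherits(time, "POSIXct"), length(time) == length(glucose))
  if (anyNA(time) || anyNA(glucose)) {
    stop("cgm_trace: NA timestamps or glucose values are not allowed")
  }
  if (any(glucose <= 0 | glucose > 500)) {
    stop("cgm_trace: glucose outside (0, 500] mg/dL")
  }
  if (length(time) > 1) {
    dt <- as.numeric(diff(time), units = "mins")
    if (any(dt <= 0)) stop("cgm_trace: timestamps must be strictly increasing")
    mult <- dt / grid_step
    if (any(abs(mult - round(mult)) > 1e-6)) {
      stop("cgm_trace: inter-reading intervals must be integer multiples of ",
           grid_step, " minutes")
    }
  }
  structure(list(patient_id = as.character(patient_id),
                 time = time, glucose = as.numeric(glucose),
                 grid_step = grid_step),
            class = "cgm_trace")
}

#' @export
print.cgm_trace <- function(x, ...) {
  n <- length(x$glucose)
  cat(sprintf("<cgm_trace> patient %s: %d readings, %g-min grid\n",
              x$patient_id, n, x$grid_step))
  if (n > 0) {
    gaps <- sum(as.numeric(diff(x$time), units = "mins") > x$grid_step)
    cat(sprintf("  %s .. %s, %d gap(s), glucose %g-%g mg/dL\n",
                format(x$time[1]), format(x$time[n]), gaps,
                min(x$glucose), max(x$glucose)))
  }
  invisible(x)
}

#' @export
length.cgm_trace <- function(x) length(x$glucose)

# Expand a trace to its full lattice: glucose vector with NA at missing grid
# points, plus the matching time vector. Internal workhorse for event
# detection, feature extraction and forecast targets.
as_grid <- function(trace) {
  step_s <- trace$grid_step * 60
  n_grid <- as.integer(round(as.numeric(trace$time[length(trace$time)] -
                                          trace$time[1], units = "secs") /
                               step_s)) + 1L
  idx <- as.integer(round(as.numeric(trace$time - trace$time[1],
                                     units = "secs") / step_s)) + 1L
  g <- rep(NA_real_, n_grid)
  g[idx] <- trace$glucose
  list(glucose = g,
       time = trace$time[1] + step_s * (seq_len(n_grid) - 1L),
       index = idx)
}

parse_timestamps <- function(x) {
  out <- as.POSIXct(strptime(x, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  for (f in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], f, tz = "UTC"))
  }
  out
}

#' Read CGM traces from CSV
#'
#' Reads a long-format CSV with columns `patient_id`, `timestamp`, `glucose`
#' (mg/dL) and returns one [cgm_trace()] per patient. Raw timestamps are
#' aligned to a per-patient lattice anchored at the first reading: each
#' reading snaps to the nearest lattice point (Dexcom-style cadence jitter of
#' up to `snap_tolerance_s` seconds is absorbed); readings farther off-grid
#' are still aligned to the nearest whole number of grid steps and counted in
#' the ingest log. Readings with glucose outside (0, 500], unparseable
#' timestamps, or colliding on one grid point (later one) are dropped and the
#' counts reported via `message()`.
#'
#' @param path CSV file path.
#' @param grid_step grid spacing, minutes.
#' @param snap_tolerance_s jitter tolerance around a lattice point, seconds.
#' @return named list of `cgm_trace` objects (one per patient, names are
#'   patient ids) with attribute `ingest_log`, a named integer vector of
#'   dropped/adjusted row counts.
#' @export
read_cgm_csv <- function(path, grid_step = 5, snap_tolerance_s = 90) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "timestamp", "glucose")
  if (!all(need %in% names(df))) {
    stop("read_cgm_csv: missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  df$patient_id <- as.character(df$patient_id)
  ts <- suppressWarnings(parse_timestamps(as.character(df$timestamp)))
  gl <- suppressWarnings(as.numeric(df$glucose))
  bad_time <- is.na(ts)
  bad_gluc <- !bad_time & (is.na(gl) | gl <= 0 | gl > 500)
  keep <- !bad_time & !bad_gluc
  log <- c(unparseable_timestamp = sum(bad_time),
           out_of_range_glucose = sum(bad_gluc),
           duplicate_grid_point = 0L, off_grid_aligned = 0L)
  df <- data.frame(patient_id = df$patient_id[keep], time = ts[keep],
                   glucose = gl[keep])
  step_s <- grid_step * 60
  traces <- list()
  for (pid in unique(df$patient_id)) {
    d <- df[df$patient_id == pid, , drop = FALSE]
    d <- d[order(d$time), , drop = FALSE]
    n <- nrow(d)
    snapped <- d$time
    keep_i <- rep(TRUE, n)
    last <- d$time[1]
    for (i in seq_len(n)[-1]) {
      dt <- as.numeric(d$time[i] - last, units = "secs")
      k <- round(dt / step_s)
      if (k < 1) {
        keep_i[i] <- FALSE
        log["duplicate_grid_point"] <- log["duplicate_grid_point"] + 1L
        next
      }
      cand <- last + k * step_s
      if (abs(as.numeric(d$time[i] - cand, units = "secs")) > snap_tolerance_s) {
        log["off_grid_aligned"] <- log["off_grid_aligned"] + 1L
      }
      snapped[i] <- cand
      last <- cand
    }
    traces[[pid]] <- cgm_trace(pid, snapped[keep_i], d$glucose[keep_i],
                               grid_step = grid_step)
  }
  dropped <- sum(log[c("unparseable_timestamp", "out_of_range_glucose",
                       "duplicate_grid_point")])
  if (dropped > 0) {
    message(sprintf("read_cgm_csv: dropped %d row(s) [%s]", dropped,
                    paste(names(log), log, sep = "=", collapse = ", ")))
  }
  attr(traces, "ingest_log") <- log
  traces
}

#' Write CGM traces to CSV
#'
#' Inverse of [read_cgm_csv()]: writes the long-format
#' `patient_id,timestamp,glucose` dialect.
#'
#' @param traces a `cgm_trace` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cgm_csv <- function(traces, path) {
  if (inherits(traces, "cgm_trace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(patient_id = tr$patient_id,
               timestamp = format(tr$time, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
               glucose = tr$glucose)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
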