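#' Detect hypoglycemic events in a CGM trace
#'
#' A hypoglycemic event is a maximal run of consecutive readings with glucose
#' strictly below `threshold` (default 70 mg/dL); the event ends when the
#' glucose rises back to at least the threshold. "Consecutive" means adjacent
#' on the 5-minute grid: a sensor gap terminates a run, since the event
#' definition cannot span unobserved time. Events lasting at least 15 minutes
#' (three readings at the 5-minute cadence) are classed `sustained`, shorter
#' ones `transient`. A reading exactly at the threshold is never inside an
#' event.
#'
#' @param x a [cgm_trace()] or a list of them.
#' @param threshold hypoglycemia threshold, mg/dL (strict `<`).
#' @param sustained_min minimum duration in minutes for the sustained class.
#' @param ... unused.
#' @return a `data.frame` of class `hypo_events` with columns `patient_id`,
#'   `start_index` (reading index in the trace), `grid_index` (lattice index),
#'   `onset_time`, `run_length`, `duration_min`, `event_class`.
#' @examples
#' tr <- cgm_trace("p1", as.POSIXct("2023-01-01", tz = "UTC") + 300 * (0:3),
#'                 c(80, 65, 68, 72))
#' detect_events(tr)
#' @export
detect_events <- function(x, threshold = 70, sustained_min = 15, ...) {
  UseMethod("detect_events")
}

#' @export
detect_events.list <- function(x, threshold = 70, sustained_min = 15, ...) {
  out <- do.call(rbind, lapply(x, detect_events, threshold = threshold,
                               sustained_min = sustained_min))
  if (is.null(out)) out <- empty_events()
  rownames(out) <- NULL
  class(out) <- c("hypo_events", "data.frame")
  out
}

#' @export
detect_events.cgm_trace <- function(x, threshold = 70, sustained_min = 15,
                                    ...) {
  n <- length(x$glucose)
  if (n == 0) return(empty_events())
  grid <- as_grid(x)
  below <- x$glucose < threshold
  # segment id increments after every gap; runs cannot cross segments
  gap_after <- c(FALSE, as.numeric(diff(x$time), units = "mins") > x$grid_step)
  seg <- cumsum(gap_after)
  run_id <- cumsum(c(TRUE, diff(seg) != 0 | diff(below) != 0))
  starts <- which(!duplicated(run_id) & below)
  if (length(starts) == 0) return(empty_events())
  len <- as.integer(table(run_id)[as.character(run_id[starts])])
  dur <- len * x$grid_step
  out <- data.frame(
    patient_id = x$patient_id,
    start_index = starts,
    grid_index = grid$index[starts],
    onset_time = x$time[starts],
    run_length = len,
    duration_min = dur,
    event_class = ifelse(dur >= sustained_min, "sustained", "transient"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("hypo_events", "data.frame")
  out
}

empty_events <- function() {
  out <- data.frame(patient_id = character(), start_index = integer(),
                    grid_index = integer(),
                    onset_time = as.POSIXct(character(), tz = "UTC"),
                    run_length = integer(), duration_min = numeric(),
                    event_class = character(), stringsAsFactors = FALSE)
  class(out) <- c("hypo_events", "data.frame")
  out
}

#' Population statistics of hypoglycemic events
#'
#' Tabulates the duration distribution of a set of events into 5-minute bins
#' (5, 10, ..., 45, >45 minutes), the transient/sustained split, and the
#' prevalence of hypoglycemic readings. Percentages are computed on unrounded
#' arithmetic; the print method reports them half-up to two decimals. With
#' zero events the percentages are undefined and reported as `NA`, not 0.
#'
#' @param events a `hypo_events` data frame from [detect_events()].
#' @param n_total_readings total number of readings the events came from.
#' @param grid_step grid spacing, minutes.
#' @return an object of class `event_stats`.
#' @export
event_stats <- function(events, n_total_readings, grid_step = 5) {
  n_events <- nrow(events)
  n_hypo <- sum(events$run_length)
  if (n_total_readings < n_hypo) {
    stop("event_stats: n_total_readings smaller than total hypoglycemic readings")
  }
  brk <- c(seq(grid_step, 9 * grid_step, by = grid_step), Inf)
  labs <- c(paste0(seq(grid_step, 9 * grid_step, by = grid_step), " min"),
            paste0(">", 9 * grid_step, " min"))
  if (n_events > 0) {
    bin <- cut(events$duration_min, breaks = c(0, brk), labels = labs,
               right = TRUE)
    counts <- as.integer(table(bin))
  } else {
    counts <- integer(length(labs))
  }
  names(counts) <- labs
  n_sust <- sum(events$event_class == "sustained")
  n_tran <- n_events - n_sust
  structure(list(
    n_events = n_events,
    duration_histogram = data.frame(
      bin = labs, count = counts,
      percent = vapply(counts, pct_of, numeric(1), den = n_events),
      row.names = NULL),
    n_transient = n_tran, n_sustained = n_sust,
    pct_transient = pct_of(n_tran, n_events),
    pct_sustained = pct_of(n_sust, n_events),
    n_hypo_readings = n_hypo,
    n_total_readings = n_total_readings,
    pct_hypo_readings = pct_of(n_hypo, n_total_readings)),
    class = "event_stats")
}

#' @export
print.event_stats <- function(x, ...) {
  cat(sprintf("Hypoglycemic event statistics (n = %d events)\n", x$n_events))
  cat(sprintf("  transient: %d (%s%%)   sustained: %d (%s%%)\n",
              x$n_transient, fmt_pct(x$pct_transient),
              x$n_sustained, fmt_pct(x$pct_sustained)))
  cat(sprintf("  hypoglycemic readings: %d of %d (%s%%)\n",
              x$n_hypo_readings, x$n_total_readings,
              fmt_pct(x$pct_hypo_readings)))
  cat("  duration distribution:\n")
  h <- x$duration_histogram
  for (i in seq_len(nrow(h))) {
    cat(sprintf("    %-8s %6d (%s%%)\n", h$bin[i], h$count[i],
                fmt_pct(h$percent[i])))
  }
  invisible(x)
}

#' Export an event list to CSV
#'
#' @param events a `hypo_events` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  df <- data.frame(patient_id = events$patient_id,
                   onset_time = format(events$onset_time,
                                       "%Y-%m-%d %H:%M:%S", tz = "UTC"),
                   run_length = events$run_length,
                   duration_min = events$duration_min,
                   event_class = events$event_class)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# event_stats serialization used by the CLI
event_stats_to_list <- function(x) {
  list(n_events = x$n_events,
       duration_histogram = x$duration_histogram,
       n_transient = x$n_transient, n_sustained = x$n_sustained,
       pct_transient = x$pct_transient, pct_sustained = x$pct_sustained,
       n_hypo_readings = x$n_hypo_readings,
       n_total_readings = x$n_total_readings,
       pct_hypo_readings = x$pct_hypo_readings)
}
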