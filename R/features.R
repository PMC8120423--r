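#' Feature extraction configuration
#'
#' Controls the predictor set built by [extract_features()]. All windows are
#' in minutes and must be multiples of the grid step. The default history
#' window is 4 hours: a feature row is emitted for every observed grid point
#' with at least 4 h of trailing grid behind it, and the row is `complete`
#' only when that whole window is observed (no gap intrusion).
#'
#' @param lags_min lagged-glucose offsets, minutes.
#' @param diff_windows_min first-difference windows, minutes.
#' @param rolling_windows_min trailing rolling-statistic windows, minutes.
#' @param history_hours trailing history required per row, hours.
#' @param use_demographics include per-patient demographics (age, HbA1c,
#'   diabetes duration) when a demographics table is supplied. Off by
#'   default: the headline model uses only CGM history and calendar context.
#' @return a list of class `feature_config`.
#' @export
feature_config <- function(lags_min = c(5, 10, 15, 30, 60, 120, 240),
                           diff_windows_min = c(5, 15, 30),
                           rolling_windows_min = c(30, 60, 240),
                           history_hours = 4,
                           use_demographics = FALSE) {
  structure(list(lags_min = lags_min, diff_windows_min = diff_windows_min,
                 rolling_windows_min = rolling_windows_min,
                 history_hours = history_hours,
                 use_demographics = use_demographics),
            class = "feature_config")
}

#' Build predictor rows from CGM history
#'
#' Emits one row per observed grid point that has at least `history_hours` of
#' trailing grid available. Predictors fall in five categories:
#' \describe{
#'   \item{dynamic}{current glucose; lagged glucose; first differences over
#'     short windows; trailing rolling mean/sd/min/max.}
#'   \item{snowball}{length (readings) and cumulative change of the current
#'     monotone stretch of consecutive same-sign 5-minute differences; a zero
#'     or sign-flipped difference resets the stretch.}
#'   \item{interaction}{current glucose times the 15-minute slope; 60-minute
#'     rolling sd times the 15-minute slope.}
#'   \item{contextual}{hour of day as a sine/cosine pair (avoiding the 23->0
#'     discontinuity) and ordinal day of week (0 = Sunday).}
#'   \item{demographic}{optional age, HbA1c, diabetes duration.}
#' }
#' Extraction is causal: a row depends only on readings at or before its
#' decision time. Rows whose trailing window touches a gap are marked
#' `complete = FALSE` and carry `NA` predictors where the dependency is
#' missing; [drop_incomplete()] removes them.
#'
#' @param x a [cgm_trace()] or list of traces.
#' @param demographics optional data frame with columns `patient_id`, `age`,
#'   `hba1c`, `diabetes_duration`.
#' @param config a [feature_config()].
#' @param ... unused.
#' @return data frame with key columns `patient_id`, `decision_time`,
#'   `grid_index`, `complete` followed by the predictor columns (fixed,
#'   documented order). Zero rows if the trace is shorter than the history
#'   window.
#' @export
extract_features <- function(x, demographics = NULL,
                             config = feature_config(), ...) {
  UseMethod("extract_features")
}

#' @export
extract_features.list <- function(x, demographics = NULL,
                                  config = feature_config(), ...) {
  out <- do.call(rbind, lapply(x, extract_features, demographics = demographics,
                               config = config))
  rownames(out) <- NULL
  out
}

#' @export
extract_features.cgm_trace <- function(x, demographics = NULL,
                                       config = feature_config(), ...) {
  step <- x$grid_step
  H <- as.integer(round(config$history_hours * 60 / step))
  grid <- as_grid(x)
  g <- grid$glucose
  n <- length(g)
  if (n <= H) return(empty_feature_rows(x, config, demographics))

  obs <- !is.na(g)
  nc <- cumsum(!obs)                      # running count of missing points
  i <- which(obs)
  i <- i[i > H]
  if (length(i) == 0) return(empty_feature_rows(x, config, demographics))
  # missing points in the closed window [i-H, i]
  m <- i - H - 1L
  n_missing <- nc[i] - ifelse(m >= 1, nc[pmax(m, 1L)], 0)
  complete <- n_missing == 0

  out <- data.frame(patient_id = x$patient_id,
                    decision_time = grid$time[i],
                    grid_index = i,
                    complete = complete,
                    glucose = g[i])

  for (L in config$lags_min) {
    out[[paste0("lag_", L)]] <- g[i - as.integer(L / step)]
  }
  for (w in config$diff_windows_min) {
    out[[paste0("diff_", w)]] <- g[i] - g[i - as.integer(w / step)]
  }

  # trailing-window stats over the last w minutes (w/step readings incl. now)
  gz <- ifelse(obs, g, 0)
  cs <- cumsum(gz)
  cs2 <- cumsum(gz^2)
  ncum <- cumsum(!obs)
  roll <- list()
  for (w in config$rolling_windows_min) {
    k <- as.integer(w / step)
    lo <- i - k                            # window is (lo, i]
    full <- (ncum[i] - ifelse(lo >= 1, ncum[pmax(lo, 1L)], 0)) == 0 & lo >= 0
    s1 <- cs[i] - ifelse(lo >= 1, cs[pmax(lo, 1L)], 0)
    s2 <- cs2[i] - ifelse(lo >= 1, cs2[pmax(lo, 1L)], 0)
    m <- s1 / k
    v <- pmax((s2 - k * m^2) / (k - 1), 0)
    ghi <- ifelse(obs, g, -Inf)
    glo <- ifelse(obs, g, Inf)
    rmax <- zoo::rollmax(ghi, k, fill = NA, align = "right")[i]
    rmin <- -zoo::rollmax(-glo, k, fill = NA, align = "right")[i]
    m[!full] <- NA; v[!full] <- NA; rmax[!full] <- NA; rmin[!full] <- NA
    out[[paste0("roll_mean_", w)]] <- m
    out[[paste0("roll_sd_", w)]] <- sqrt(v)
    out[[paste0("roll_min_", w)]] <- rmin
    out[[paste0("roll_max_", w)]] <- rmax
    roll[[paste0("sd_", w)]] <- sqrt(v)
  }

  sb <- snowball_stats(g)
  out$snowball_len <- sb$len[i]
  out$snowball_change <- sb$change[i]

  slope15 <- (g[i] - g[i - as.integer(15 / step)]) / 15
  out$inter_gluc_slope15 <- g[i] * slope15
  sd60 <- if (!is.null(roll$sd_60)) roll$sd_60 else {
    w <- config$rolling_windows_min[1]
    roll[[paste0("sd_", w)]]
  }
  out$inter_sd60_slope15 <- sd60 * slope15

  lt <- as.POSIXlt(grid$time[i], tz = "UTC")
  hour_frac <- lt$hour + lt$min / 60 + lt$sec / 3600
  out$hour_sin <- sin(2 * pi * hour_frac / 24)
  out$hour_cos <- cos(2 * pi * hour_frac / 24)
  out$day_of_week <- lt$wday

  if (isTRUE(config$use_demographics) && !is.null(demographics)) {
    j <- match(x$patient_id, as.character(demographics$patient_id))
    out$age <- demographics$age[j]
    out$hba1c <- demographics$hba1c[j]
    out$diabetes_duration <- demographics$diabetes_duration[j]
  }

  # any missing dependency marks the row incomplete
  pred <- setdiff(names(out), feature_meta_cols())
  out$complete <- out$complete & !apply(is.na(out[, pred, drop = FALSE]), 1, any)
  rownames(out) <- NULL
  out
}

# trailing monotone-run statistics of the gridded signal; a gap, a zero
# difference or a sign change resets the run
snowball_stats <- function(g) {
  n <- length(g)
  len <- integer(n)
  change <- numeric(n)
  if (n < 2) return(list(len = len, change = change))
  d <- c(NA, diff(g))
  for (t in 2:n) {
    if (is.na(d[t]) || d[t] == 0) {
      len[t] <- 0L
      change[t] <- 0
    } else if (!is.na(d[t - 1]) && d[t - 1] != 0 &&
               sign(d[t]) == sign(d[t - 1])) {
      len[t] <- len[t - 1] + 1L
      change[t] <- change[t - 1] + d[t]
    } else {
      len[t] <- 1L
      change[t] <- d[t]
    }
  }
  len[is.na(g)] <- 0L
  change[is.na(g)] <- 0
  list(len = len, change = change)
}

feature_meta_cols <- function() {
  c("patient_id", "decision_time", "grid_index", "complete")
}

#' Names of the predictor columns of a feature-row data frame
#'
#' @param rows data frame from [extract_features()].
#' @return character vector of predictor column names.
#' @export
feature_columns <- function(rows) {
  setdiff(names(rows), feature_meta_cols())
}

empty_feature_rows <- function(trace, config, demographics) {
  tmpl <- cgm_trace(trace$patient_id,
                    as.POSIXct("2000-01-01", tz = "UTC") +
                      (0:(config$history_hours * 12)) * trace$grid_step * 60,
                    rep(100, config$history_hours * 12 + 1),
                    grid_step = trace$grid_step)
  out <- extract_features.cgm_trace(tmpl, demographics = demographics,
                                    config = config)
  out[0, , drop = FALSE]
}

#' Drop incomplete feature rows
#'
#' Removes rows depending on a missing CGM value (and therefore every
#' time-lagged row whose window covers the hole). The number of dropped rows
#' is reported via `message()` when nonzero.
#'
#' @param rows data frame from [extract_features()].
#' @return the complete rows.
#' @export
drop_incomplete <- function(rows) {
  dropped <- sum(!rows$complete)
  if (dropped > 0) {
    vlog("drop_incomplete: removed %d incomplete row(s)", dropped)
  }
  out <- rows[rows$complete, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a feature matrix to CSV
#'
#' Wide CSV, one row per (patient, decision time), columns in the
#' deterministic order produced by [extract_features()].
#'
#' @param rows feature-row data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(rows, path) {
  rows$decision_time <- format(rows$decision_time, "%Y-%m-%d %H:%M:%S",
                               tz = "UTC")
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
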