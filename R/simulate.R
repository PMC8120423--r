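#' Duration distribution of hypoglycemic events, reference mix
#'
#' The categorical distribution of event durations (in readings at the
#' 5-minute cadence) used as the simulator default: probabilities for
#' 1, 2, ..., 9 readings and an open-ended 10+ bin. The reference mix puts
#' 22.75% of mass on 1-2-reading events and 77.25% on events of 3+ readings.
#'
#' @return named numeric vector of probabilities (names `"1"`..`"9"`,
#'   `"10+"`), summing to 1.
#' @export
table2_duration_proportions <- function() {
  counts <- c(572, 796, 885, 842, 676, 562, 391, 283, 209, 794)
  p <- counts / sum(counts)
  names(p) <- c(as.character(1:9), "10+")
  p
}

#' Synthetic CGM cohort configuration
#'
#' Parameters of [simulate_cohort()]. Glucose dynamics are a mean-reverting
#' (Ornstein-Uhlenbeck) deviation around a circadian baseline — the pipeline
#' needs realistic autocorrelation and event structure, not metabolic
#' fidelity. Hypoglycemic excursions are planted on top: sustained
#' excursions (3+ readings) are preceded by a `descent_signature_min` linear
#' decline, making them learnable from lag features, while transient
#' excursions are injected as short signature-free noise dips — transient
#' dips in real data often reflect random glycemic variation rather than a
#' stable pattern. Ambient (non-excursion) glucose is floored at
#' `ambient_floor` so every sub-70 reading belongs to a planted event.
#'
#' @param n_patients number of patients.
#' @param days_min,days_max per-patient duration range, days (drawn
#'   uniformly).
#' @param grid_step grid spacing, minutes.
#' @param baseline_mean circadian baseline mean, mg/dL.
#' @param circadian_amplitude circadian swing around the mean, mg/dL (nadir
#'   near 04:00).
#' @param ou_reversion_rate OU mean-reversion rate, per minute.
#' @param ou_volatility OU volatility, mg/dL per sqrt-minute (stationary SD
#'   is `ou_volatility / sqrt(2 * ou_reversion_rate)`).
#' @param sensor_noise_sd additive sensor noise SD, mg/dL.
#' @param gap_rate expected sensor gaps per day.
#' @param gap_length_mean mean gap length, readings (geometric).
#' @param events_per_day expected planted hypoglycemic events per day.
#' @param sustained_fraction optional target share of sustained (3+
#'   readings) events; when given, `duration_distribution` is reweighted so
#'   its 3+ mass equals this share.
#' @param duration_distribution probabilities over event durations
#'   1..9, 10+ readings; default [table2_duration_proportions()].
#' @param descent_signature_min pre-onset linear-descent length for
#'   sustained events, minutes.
#' @param ambient_floor lower clamp of ambient glucose, mg/dL.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 20, days_min = 30, days_max = 90,
                       grid_step = 5, baseline_mean = 140,
                       circadian_amplitude = 25, ou_reversion_rate = 0.003,
                       ou_volatility = 3.1, sensor_noise_sd = 2,
                       gap_rate = 0.5, gap_length_mean = 6,
                       events_per_day = 1, sustained_fraction = NULL,
                       duration_distribution = table2_duration_proportions(),
                       descent_signature_min = 30, ambient_floor = 80,
                       seed = 1) {
  stopifnot(n_patients >= 1, days_min >= 1, days_max >= days_min,
            ou_reversion_rate > 0, ou_volatility >= 0, sensor_noise_sd >= 0,
            gap_rate >= 0, events_per_day >= 0,
            length(duration_distribution) == 10,
            all(duration_distribution >= 0))
  p <- duration_distribution / sum(duration_distribution)
  if (!is.null(sustained_fraction)) {
    stopifnot(sustained_fraction > 0, sustained_fraction < 1)
    tr_mass <- sum(p[1:2]); su_mass <- sum(p[3:10])
    p[1:2] <- p[1:2] / tr_mass * (1 - sustained_fraction)
    p[3:10] <- p[3:10] / su_mass * sustained_fraction
  }
  steps_per_day <- 24 * 60 / grid_step
  mean_len <- sum(p * c(1:9, 12))                 # 10+ bin averages ~12
  footprint <- mean_len + descent_signature_min / grid_step + 6 + 24
  if (events_per_day * footprint > 0.8 * steps_per_day) {
    stop("sim_config: infeasible event rate - events would cover the day")
  }
  structure(list(n_patients = n_patients, days_min = days_min,
                 days_max = days_max, grid_step = grid_step,
                 baseline_mean = baseline_mean,
                 circadian_amplitude = circadian_amplitude,
                 ou_reversion_rate = ou_reversion_rate,
                 ou_volatility = ou_volatility,
                 sensor_noise_sd = sensor_noise_sd, gap_rate = gap_rate,
                 gap_length_mean = gap_length_mean,
                 events_per_day = events_per_day,
                 duration_distribution = p,
                 sustained_fraction = sum(p[3:10]),
                 descent_signature_min = descent_signature_min,
                 ambient_floor = ambient_floor, seed = seed),
            class = "sim_config")
}

#' Simulator preset with the reference duration mix
#'
#' [sim_config()] preconfigured with the reference event-duration
#' distribution ([table2_duration_proportions()]); any other parameter can
#' be overridden through `...`.
#'
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
table2_preset <- function(...) {
  sim_config(duration_distribution = table2_duration_proportions(), ...)
}

#' Simulate a multi-patient CGM cohort with planted hypoglycemia
#'
#' Generates one trace per patient under `config` (see [sim_config()] for
#' the generative model) and records the ground truth of every planted
#' event. With `sensor_noise_sd = 0` and `gap_rate = 0`, running
#' [detect_events()] on the simulated traces recovers exactly the planted
#' onsets and run lengths. The simulation is bit-reproducible for a fixed
#' seed.
#'
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return list with elements `traces` (named list of [cgm_trace()]),
#'   `truth` (data frame: `patient_id`, `onset_time`, `onset_index`,
#'   `run_length`, `planted_class`) and `config`.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  step <- config$grid_step
  step_s <- step * 60
  steps_per_day <- as.integer(24 * 60 / step)
  D <- as.integer(round(config$descent_signature_min / step))
  Rr <- 6L                                        # recovery ramp, readings
  t0 <- as.POSIXct("2023-01-01 00:00:00", tz = "UTC")
  phi <- exp(-config$ou_reversion_rate * step)
  sd_st <- config$ou_volatility / sqrt(2 * config$ou_reversion_rate)
  sd_inc <- sd_st * sqrt(1 - phi^2)

  traces <- list()
  truth <- list()
  for (pt in seq_len(config$n_patients)) {
    set.seed(derive_seed(seed, pt))
    pid <- sprintf("S%03d", pt)
    days <- if (config$days_max > config$days_min) {
      sample(config$days_min:config$days_max, 1)
    } else config$days_min
    n <- days * steps_per_day
    tm <- t0 + step_s * (0:(n - 1))
    hour <- (as.numeric(tm - t0, units = "hours")) %% 24
    base <- config$baseline_mean -
      config$circadian_amplitude * cos(2 * pi * (hour - 4) / 24)
    x <- as.numeric(stats::filter(stats::rnorm(n, 0, sd_inc), phi,
                                  method = "recursive",
                                  init = stats::rnorm(1, 0, sd_st)))
    g <- pmax(base + x, config$ambient_floor)

    # plant events: durations from the configured mix, onsets kept apart
    n_ev <- stats::rpois(1, config$events_per_day * days)
    ev <- NULL
    if (n_ev > 0) {
      len_bin <- sample(1:10, n_ev, replace = TRUE,
                        prob = config$duration_distribution)
      len <- ifelse(len_bin < 10, len_bin,
                    10L + stats::rgeom(n_ev, 1 / 3))
      len <- pmin(len, 30L)
      cand <- sort(sample((D + 2):(n - max(len) - Rr - 1), n_ev,
                          replace = TRUE))
      onset <- integer(0); li <- integer(0); last_end <- -Inf
      for (o in cand) {
        L <- len[length(onset) + 1]
        if (o > last_end + 24) {                  # 2-h clearance
          onset <- c(onset, o); li <- c(li, L)
          last_end <- o + L + Rr
        }
      }
      if (length(onset) > 0) {
        cls <- ifelse(li * step >= 15, "sustained", "transient")
        for (j in seq_along(onset)) {
          o <- onset[j]; L <- li[j]
          nadir <- stats::runif(1, 52, 62)
          prof <- 70 - (70 - nadir) * sin(pi * ((1:L) - 0.5) / L)
          if (cls[j] == "sustained") {
            # deterministic signature: every sustained event is preceded by
            # the same linear descent from the euglycemic range (132 mg/dL)
            # down to the threshold over the signature window, so the
            # pre-onset pattern is identifiable from lag features
            g[(o - D):(o - 1)] <- seq(132, 72, length.out = D + 1)[-1]
            g[o:(o + L - 1)] <- prof
            g[(o + L):(o + L + Rr - 1)] <-
              seq(74, max(g[o + L + Rr], config$ambient_floor),
                  length.out = Rr)
          } else {
            g[o:(o + L - 1)] <- stats::runif(L, 62, 68)
          }
        }
        ev <- data.frame(patient_id = pid, onset_time = tm[onset],
                         onset_index = onset, run_length = li,
                         planted_class = cls, stringsAsFactors = FALSE)
      }
    }

    # sensor noise, then clamp to the plausible range
    if (config$sensor_noise_sd > 0) {
      g <- g + stats::rnorm(n, 0, config$sensor_noise_sd)
    }
    g <- pmin(pmax(round(g), 40), 450)

    # sensor gaps, avoiding planted event windows
    drop_idx <- integer(0)
    n_gap <- if (config$gap_rate > 0) stats::rpois(1, config$gap_rate * days)
             else 0L
    if (n_gap > 0) {
      protected <- rep(FALSE, n)
      if (!is.null(ev)) {
        for (j in seq_len(nrow(ev))) {
          lo <- max(1, ev$onset_index[j] - D - 1)
          hi <- min(n, ev$onset_index[j] + ev$run_length[j] + Rr)
          protected[lo:hi] <- TRUE
        }
      }
      glen <- 1L + stats::rgeom(n_gap, 1 / config$gap_length_mean)
      gpos <- sample(2:(n - 1), n_gap)
      for (j in seq_len(n_gap)) {
        idx <- gpos[j]:min(n - 1, gpos[j] + glen[j] - 1)
        drop_idx <- c(drop_idx, idx[!protected[idx]])
      }
      drop_idx <- unique(drop_idx)
    }
    keep <- setdiff(seq_len(n), drop_idx)
    traces[[pid]] <- cgm_trace(pid, tm[keep], g[keep], grid_step = step)
    if (!is.null(ev)) truth[[pid]] <- ev
  }
  truth <- if (length(truth) > 0) do.call(rbind, truth) else
    data.frame(patient_id = character(), onset_time = t0[0],
               onset_index = integer(), run_length = integer(),
               planted_class = character())
  rownames(truth) <- NULL
  list(traces = traces, truth = truth, config = config)
}

#' Write the simulator ground truth to CSV
#'
#' @param truth the `truth` element of a [simulate_cohort()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  df <- data.frame(patient_id = truth$patient_id,
                   onset_time = format(truth$onset_time,
                                       "%Y-%m-%d %H:%M:%S", tz = "UTC"),
                   run_length = truth$run_length,
                   planted_class = truth$planted_class)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
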