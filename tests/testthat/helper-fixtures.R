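# shared fixtures: traces built in code, plus independent brute-force oracles

t_origin <- as.POSIXct("2023-01-01 00:00:00", tz = "UTC")

# trace from a glucose vector on a regular grid; drop = grid points removed
# to create gaps
make_trace <- function(glucose, patient = "p1", step = 5, drop = integer(0),
                       start = t_origin) {
  idx <- setdiff(seq_along(glucose), drop)
  cgm_trace(patient, start + (idx - 1) * step * 60, glucose[idx],
            grid_step = step)
}

# random trace in a glucose band, optionally with random gaps
rand_trace <- function(n, seed, lo = 40, hi = 180, gap_prob = 0,
                       patient = "p1") {
  set.seed(seed)
  g <- round(runif(n, lo, hi), 1)
  drop <- if (gap_prob > 0) which(runif(n) < gap_prob) else integer(0)
  drop <- setdiff(drop, c(1, n))
  make_trace(g, patient = patient, drop = drop)
}

# ORACLE: event detection by a plain index walk, independent of the rle
# implementation in the package
brute_events <- function(trace, threshold = 70) {
  g <- trace$glucose
  gap_before <- c(FALSE,
                  as.numeric(diff(trace$time), units = "mins") >
                    trace$grid_step)
  out <- NULL
  i <- 1
  while (i <= length(g)) {
    if (g[i] < threshold) {
      j <- i
      while (j + 1 <= length(g) && g[j + 1] < threshold &&
             !gap_before[j + 1]) {
        j <- j + 1
      }
      out <- rbind(out, data.frame(start_index = i, run_length = j - i + 1))
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

# ORACLE: consecutive-run alert rule by explicit counter
brute_run_alert <- function(x, cutoff, mc) {
  run <- 0
  for (v in x) {
    run <- if (v < cutoff) run + 1 else 0
    if (run >= mc) return(TRUE)
  }
  FALSE
}

# tiny labeled instance frame for confusion tests
random_instances <- function(n, seed) {
  set.seed(seed)
  inst <- data.frame(
    patient_id = "p1",
    decision_time = t_origin + 300 * seq_len(n),
    label = runif(n) < 0.3,
    has_sustained = logical(n),
    has_transient = runif(n) < 0.2)
  inst$has_sustained <- inst$label
  attr(inst, "ph_min") <- 30
  attr(inst, "label_window_min") <- 20
  inst
}

# deterministic linear-ramp trace for closed-form feature checks
ramp_trace <- function(n = 60, start_val = 400, slope = -2, patient = "p1") {
  make_trace(start_val + slope * (seq_len(n) - 1), patient = patient)
}
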