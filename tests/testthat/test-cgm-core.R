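test_that("trace construction enforces the grid and sensor-range invariants", {
  expect_s3_class(make_trace(c(100, 110, 120)), "cgm_trace")
  expect_error(cgm_trace("p", t_origin + c(0, 300, 200), c(1, 2, 3) * 100),
               "strictly increasing")
  expect_error(cgm_trace("p", t_origin + c(0, 400), c(100, 100)),
               "integer multiples")
  expect_error(cgm_trace("p", t_origin + c(0, 300), c(100, 600)),
               "glucose")
  expect_error(cgm_trace("p", t_origin + c(0, 300), c(0, 100)),
               "glucose")
})

test_that("CSV ingest snaps jittered timestamps to the 5-minute lattice", {
  csv <- tempfile(fileext = ".csv")
  on.exit(unlink(csv))

  # already on grid
  writeLines(c("patient_id,timestamp,glucose",
               "a,2023-01-01 00:00:00,100",
               "a,2023-01-01 00:05:00,101",
               "a,2023-01-01 00:10:00,102"), csv)
  tr <- read_cgm_csv(csv)[["a"]]
  expect_equal(length(tr), 3)
  expect_equal(as.numeric(diff(tr$time), units = "mins"), c(5, 5))

  # Dexcom-style jitter within +/- 90 s snaps cleanly
  writeLines(c("patient_id,timestamp,glucose",
               "a,2023-01-01 00:00:00,100",
               "a,2023-01-01 00:04:40,101",
               "a,2023-01-01 00:10:05,102"), csv)
  tr <- read_cgm_csv(csv)[["a"]]
  expect_equal(format(tr$time, "%H:%M:%S"),
               c("00:00:00", "00:05:00", "00:10:00"))

  # a 15-minute jump encodes two missing grid points
  writeLines(c("patient_id,timestamp,glucose",
               "a,2023-01-01 00:00:00,100",
               "a,2023-01-01 00:15:00,101"), csv)
  tr <- read_cgm_csv(csv)[["a"]]
  expect_equal(as.numeric(diff(tr$time), units = "mins"), 15)
  expect_equal(sum(is.na(hypoalert:::as_grid(tr)$glucose)), 2)
})

test_that("CSV ingest drops bad rows and grid collisions with a logged count", {
  csv <- tempfile(fileext = ".csv")
  on.exit(unlink(csv))
  writeLines(c("patient_id,timestamp,glucose",
               "a,2023-01-01 00:00:00,100",
               "a,2023-01-01 00:05:00,700",     # out of range
               "a,not-a-time,100",              # unparseable
               "a,2023-01-01 00:05:30,102",     # usable 00:05 reading
               "a,2023-01-01 00:06:00,103"),    # collides with 00:05
             csv)
  expect_message(traces <- read_cgm_csv(csv), "dropped 3 row")
  log <- attr(traces, "ingest_log")
  expect_equal(unname(log["out_of_range_glucose"]), 1L)
  expect_equal(unname(log["unparseable_timestamp"]), 1L)
  expect_equal(unname(log["duplicate_grid_point"]), 1L)
  expect_equal(traces[["a"]]$glucose, c(100, 102))
  expect_error(read_cgm_csv({
    f <- tempfile(); writeLines("patient,when,value\na,b,c", f); f
  }), "missing column")
})

test_that("round-trip through the CSV dialect preserves a trace", {
  tr <- make_trace(c(100, 65, 68, 72, 80), drop = 4)
  csv <- tempfile(fileext = ".csv")
  on.exit(unlink(csv))
  write_cgm_csv(tr, csv)
  back <- read_cgm_csv(csv)[["p1"]]
  expect_equal(back$glucose, tr$glucose)
  expect_equal(as.numeric(back$time), as.numeric(tr$time))
})

test_that("event detection matches the definition on hand-built traces", {
  ev <- detect_events(make_trace(c(80, 65, 68, 72)))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$run_length, 2L)
  expect_equal(ev$duration_min, 10)
  expect_equal(ev$event_class, "transient")
  expect_equal(ev$start_index, 2L)

  # 3 readings = 15 minutes is the sustained boundary
  ev <- detect_events(make_trace(c(69, 69, 69, 72)))
  expect_equal(ev$run_length, 3L)
  expect_equal(ev$duration_min, 15)
  expect_equal(ev$event_class, "sustained")

  # a reading of exactly 70 never belongs to an event
  ev <- detect_events(make_trace(c(70, 70, 70)))
  expect_equal(nrow(ev), 0)

  # a gap terminates the run: 2 + 2 sub-70 readings around a hole
  ev <- detect_events(make_trace(c(80, 65, 66, 67, 68, 80), drop = 4))
  expect_equal(ev$run_length, c(2L, 1L))

  expect_equal(nrow(detect_events(make_trace(numeric(0)))), 0)
})

test_that("event detection equals the brute-force maximal-run scan", {
  for (seed in 1:50) {
    tr <- rand_trace(500, seed, gap_prob = ifelse(seed %% 2 == 0, 0.02, 0))
    got <- detect_events(tr)
    want <- brute_events(tr)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$start_index, want$start_index)
      expect_equal(got$run_length, want$run_length)
    }
  }
})

test_that("events partition the sub-threshold readings and respect threshold monotonicity", {
  thresholds <- c(54, 70, 80)
  for (seed in 51:70) {
    tr <- rand_trace(400, seed, gap_prob = 0.03)
    n_below_prev <- -1
    for (th in thresholds) {
      ev <- detect_events(tr, threshold = th)
      n_below <- sum(tr$glucose < th)
      # partition: each sub-threshold reading is in exactly one event
      expect_equal(sum(ev$run_length), n_below)
      covered <- unlist(mapply(function(s, l) s:(s + l - 1), ev$start_index,
                               ev$run_length, SIMPLIFY = FALSE))
      expect_true(!any(duplicated(covered)))
      expect_true(all(tr$glucose[covered] < th))
      # monotonicity in the threshold
      expect_gte(n_below, n_below_prev)
      n_below_prev <- n_below
    }
  }
})

test_that("event statistics reproduce reference-table arithmetic", {
  # construct an event list with the reference duration counts
  counts <- c(572, 796, 885, 842, 676, 562, 391, 283, 209, 794)
  durations <- rep(c(5 * (1:9), 50), counts)
  ev <- data.frame(patient_id = "x", start_index = 1, grid_index = 1,
                   onset_time = t_origin, run_length = durations / 5,
                   duration_min = durations,
                   event_class = ifelse(durations >= 15, "sustained",
                                        "transient"))
  st <- event_stats(ev, n_total_readings = 1644875)
  expect_equal(st$n_events, 6010)
  expect_equal(st$duration_histogram$count, counts)
  expect_equal(round_half_up(st$duration_histogram$percent[2]), 13.24)
  expect_equal(round_half_up(st$duration_histogram$percent[3]), 14.73)
  expect_equal(st$n_transient + st$n_sustained, st$n_events)
  expect_equal(sum(st$duration_histogram$count), st$n_events)
  expect_equal(st$n_hypo_readings, sum(ev$run_length))

  # zero events: percentages are undefined, not zero
  st0 <- event_stats(detect_events(make_trace(c(100, 100))), 2)
  expect_true(is.na(st0$pct_transient))
  expect_true(all(is.na(st0$duration_histogram$percent)))
  expect_equal(st0$pct_hypo_readings, 0)   # readings denominator is defined
  expect_error(event_stats(ev, n_total_readings = 10), "smaller")
})
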