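test_that("confusion accounting matches the definitions on forced cases", {
  # all negative, no alerts -> pure tn
  inst <- random_instances(50, seed = 1)
  inst$label <- FALSE; inst$has_sustained <- FALSE; inst$has_transient <- FALSE
  cc <- confusion(inst, rep(FALSE, 50))
  expect_equal(c(cc$tp, cc$fp, cc$fn), c(0, 0, 0))
  expect_equal(cc$tn, 50)

  # 1 positive alerted + 1 negative alerted with a transient onset in horizon
  inst <- random_instances(2, seed = 2)
  inst$label <- c(TRUE, FALSE)
  inst$has_sustained <- c(TRUE, FALSE)
  inst$has_transient <- c(FALSE, TRUE)
  cc <- confusion(inst, c(TRUE, TRUE))
  expect_equal(c(cc$tp, cc$fp, cc$fp_transient, cc$fp_nonhypo),
               c(1, 1, 1, 0))

  expect_error(confusion(inst, TRUE), "misaligned")
})

test_that("confusion tabulation equals brute force on random instance sets", {
  set.seed(99)
  inst <- random_instances(2000, seed = 99)
  alerts <- runif(2000) < 0.4
  cc <- confusion(inst, alerts)
  # ORACLE: explicit element-wise tally
  tp <- fp <- tn <- fn <- fpt <- 0
  for (i in 1:2000) {
    if (inst$label[i] && alerts[i]) tp <- tp + 1
    if (inst$label[i] && !alerts[i]) fn <- fn + 1
    if (!inst$label[i] && !alerts[i]) tn <- tn + 1
    if (!inst$label[i] && alerts[i]) {
      fp <- fp + 1
      if (inst$has_transient[i]) fpt <- fpt + 1
    }
  }
  expect_equal(c(cc$tp, cc$fp, cc$tn, cc$fn, cc$fp_transient),
               c(tp, fp, tn, fn, fpt))
  expect_equal(cc$fp_nonhypo + cc$fp_transient, cc$fp)
  expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, 2000)
})

test_that("metric arithmetic reproduces reference figures and hand computation", {
  # FAR from reference alert counts: 40,502 false of 47,683 alerts -> 84.94%
  m <- metrics_from_counts(tp = 47683 - 40502, fp = 40502, tn = 0, fn = 0)
  expect_equal(round_half_up(m$far), 84.94)

  m <- metrics_from_counts(tp = 3, fp = 1, tn = 96, fn = 0,
                           fp_nonhypo = 1, fp_transient = 0)
  expect_equal(m$sensitivity, 100)
  expect_equal(round_half_up(m$specificity), 98.97)   # 96 of 97 negatives
  expect_equal(m$far, 25)

  # fp = 0 with alerts -> FAR 0; no alerts at all -> FAR undefined
  expect_equal(metrics_from_counts(5, 0, 10, 0)$far, 0)
  expect_true(is.na(metrics_from_counts(0, 0, 10, 2)$far))
})

test_that("metrics equal hand arithmetic on 1,000 random count tables", {
  set.seed(5)
  for (i in 1:1000) {
    tp <- rpois(1, 50); fn <- rpois(1, 10)
    fpn <- rpois(1, 20); fpt <- rpois(1, 8); tn <- rpois(1, 500)
    m <- metrics_from_counts(tp, fpn + fpt, tn, fn, fp_nonhypo = fpn,
                             fp_transient = fpt)
    if (tp + fn > 0) expect_equal(m$sensitivity, 100 * tp / (tp + fn))
    if (tn + fpn + fpt > 0) {
      expect_equal(m$specificity, 100 * tn / (tn + fpn + fpt))
    }
    if (tp + fpn + fpt > 0) {
      expect_equal(m$far, 100 * (fpn + fpt) / (tp + fpn + fpt))
      # variant B never exceeds variant A
      if (tp + fpn > 0) expect_lte(m$far_nonhypo_only, m$far + 1e-12)
    }
  }
})

test_that("metrics are invariant to instance order and patient relabeling", {
  inst <- random_instances(500, seed = 7)
  alerts <- runif(500) < 0.3
  m1 <- alert_metrics(confusion(inst, alerts))
  o <- sample(500)
  inst2 <- inst[o, ]; attr(inst2, "label_window_min") <- 20
  inst2$patient_id <- paste0("z", seq_len(500) %% 7)
  m2 <- alert_metrics(confusion(inst2, alerts[o]))
  expect_equal(m1$sensitivity, m2$sensitivity)
  expect_equal(m1$specificity, m2$specificity)
  expect_equal(m1$far, m2$far)
})

test_that("lead times pair alerts to events as defined", {
  # one sustained event at grid 60; alerts at 20 and 10 min before onset
  g <- rep(120, 72); g[60:63] <- 65
  tr <- make_trace(g)
  ev <- detect_events(tr)
  inst <- label_instances(drop_incomplete(extract_features(tr)), ev,
                          ph_min = 30)
  onset <- as.numeric(ev$onset_time)
  off <- (onset - as.numeric(inst$decision_time)) / 60
  alerts <- off %in% c(20, 10)
  lt <- lead_times(inst, alerts, ev)
  expect_equal(lt$n_events_detected, 1)
  expect_equal(lt$mean_lead_time_min, 20)      # earliest true alert counts

  # alerts only after onset -> undetected
  lt2 <- lead_times(inst, off < 0, ev)
  expect_equal(lt2$n_events_detected, 0)
  expect_true(is.na(lt2$mean_lead_time_min))
})

test_that("lead times equal an exhaustive pairing oracle on simulated alerts", {
  cfg <- sim_config(n_patients = 3, days_min = 6, days_max = 6,
                    sensor_noise_sd = 0, gap_rate = 0, seed = 77)
  sim <- simulate_cohort(cfg)
  ev <- detect_events(sim$traces)
  evs <- ev[ev$event_class == "sustained", ]
  rows <- drop_incomplete(extract_features(sim$traces))
  inst <- label_instances(rows, ev, ph_min = 30)
  set.seed(3)
  alerts <- inst$label & runif(nrow(inst)) < 0.7   # drop some true alerts
  alerts[sample(nrow(inst), 40)] <- TRUE           # add noise alerts
  lt <- lead_times(inst, alerts, evs)
  # ORACLE: exhaustive scan per event
  leads <- c()
  det <- 0
  for (i in seq_len(nrow(evs))) {
    o <- as.numeric(evs$onset_time[i])
    sel <- inst$patient_id == evs$patient_id[i] & alerts & inst$label
    t <- as.numeric(inst$decision_time[sel])
    t <- t[t < o & t >= o - 20 * 60]
    if (length(t) > 0) {
      det <- det + 1
      leads <- c(leads, (o - min(t)) / 60)
    }
  }
  expect_equal(lt$n_events_detected, det)
  expect_equal(lt$mean_lead_time_min, mean(leads))
})

test_that("operating-point sweeps are monotone along the alert-loosening axis", {
  cfg <- sim_config(n_patients = 4, days_min = 8, days_max = 8, seed = 21)
  sim <- simulate_cohort(cfg)
  ev <- detect_events(sim$traces)
  rows <- drop_incomplete(extract_features(sim$traces))
  inst <- label_instances(rows, ev, ph_min = 30)
  model <- fit_hypo_model(rows, sim$traces, events = ev, method = "qrf",
                          ph_min = 30, seed = 21)
  sw <- sweep_operating_points(model, inst, knob = "glucose_cutoff",
                               values = c(70, 75, 80),
                               events = ev[ev$event_class == "sustained", ])
  expect_true(all(diff(sw$n_alerts) >= 0))
  expect_true(all(diff(sw$sensitivity) >= 0))
  expect_true(all(diff(sw$specificity) <= 0))

  swq <- sweep_operating_points(model, inst, knob = "quantile",
                                values = c(0.25, 0.5, 0.75))
  # a lower forecast quantile is more alert-eager
  expect_true(all(diff(swq$n_alerts) <= 0))

  # rf probability-threshold sweep: fn non-increasing as threshold drops
  rf <- fit_hypo_model(rows, sim$traces, events = ev, method = "rf",
                       ph_min = 30, seed = 21)
  swp <- sweep_operating_points(rf, inst, knob = "prob_threshold",
                                values = c(0.1, 0.5, 0.9))
  expect_true(all(diff(swp$fn) >= 0))
  expect_true(all(diff(swp$n_alerts) <= 0))
  expect_error(sweep_operating_points(rf, inst, knob = "quantile",
                                      values = 0.5), "qrf")
  expect_error(sweep_operating_points(model, inst, knob = "glucose_cutoff",
                                      values = numeric(0)), "empty")
})

test_that("sweep traces a non-decreasing ROC staircase against the score sort", {
  set.seed(15)
  x <- data.frame(f1 = c(rnorm(150, -1), rnorm(150, 1)))
  y <- rep(c(FALSE, TRUE), each = 150)
  fitc <- train_rf_classifier(x, y, seed = 2)
  p <- predict_prob(fitc, x)
  th <- sort(unique(p))
  sens <- vapply(th, function(t) mean(p[y] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(p[!y] >= t), numeric(1))
  # as the threshold increases both rates fall together: a staircase
  expect_true(all(diff(sens) <= 1e-12))
  expect_true(all(diff(fpr) <= 1e-12))
})
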