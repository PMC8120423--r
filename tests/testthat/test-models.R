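test_that("instance labeling follows the onset-window rule", {
  # 6 h trace, one sustained event planted at grid point 60 (t0 + 295 min)
  g <- rep(120, 72)
  g[60:63] <- 65
  tr <- make_trace(g)
  ev <- detect_events(tr)
  expect_equal(ev$event_class, "sustained")
  rows <- drop_incomplete(extract_features(tr))
  inst <- label_instances(rows, ev, ph_min = 30)
  onset <- as.numeric(ev$onset_time)
  off <- (onset - as.numeric(inst$decision_time)) / 60
  # positive iff the onset is 5-20 min ahead (3 of the event's sub-70
  # readings then fall inside the 30-min horizon)
  expect_equal(inst$label, off >= 5 & off <= 20)
  # the full-horizon flag extends to 30 min ahead
  expect_equal(inst$has_sustained, off >= 5 & off <= 30)
  # in-event instances are excluded (not predictive)
  expect_true(all(inst$glucose >= 70))

  # a transient-only window is negative for the sustained target ...
  g2 <- rep(120, 72); g2[60:61] <- 65
  tr2 <- make_trace(g2)
  ev2 <- detect_events(tr2)
  inst2 <- label_instances(drop_incomplete(extract_features(tr2)), ev2,
                           ph_min = 30)
  expect_false(any(inst2$label))
  expect_true(any(inst2$has_transient))
  # ... but positive for the all-events target, with the full 30-min window
  inst2a <- label_instances(drop_incomplete(extract_features(tr2)), ev2,
                            ph_min = 30, target = "all")
  off2 <- (as.numeric(ev2$onset_time) - as.numeric(inst2a$decision_time)) / 60
  expect_equal(inst2a$label, off2 >= 5 & off2 <= 30)

  # no sub-70 readings anywhere -> all labels negative
  inst3 <- label_instances(drop_incomplete(extract_features(make_trace(
    rep(120, 72)))), detect_events(make_trace(rep(120, 72))), ph_min = 30)
  expect_false(any(inst3$label))
})

test_that("rf classifier separates a separable toy problem and is deterministic", {
  set.seed(7)
  x <- data.frame(f1 = c(rnorm(50, -3), rnorm(50, 3)),
                  f2 = c(rnorm(50, -3), rnorm(50, 3)))
  y <- rep(c(FALSE, TRUE), each = 50)
  fit <- train_rf_classifier(x, y, seed = 11)
  expect_equal(predict_prob(fit, x) >= 0.5, y)   # training accuracy 1.0
  fit2 <- train_rf_classifier(x, y, seed = 11)
  expect_identical(predict_prob(fit, x), predict_prob(fit2, x))
  expect_error(train_rf_classifier(x, rep(TRUE, 100)), "negative")
  expect_error(train_rf_classifier(x, rep(FALSE, 100)), "positive")
})

test_that("rf classifier on permuted labels has chance-level out-of-bag accuracy", {
  set.seed(13)
  n <- 400
  x <- data.frame(f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n))
  y <- sample(rep(c(TRUE, FALSE), each = n / 2))  # labels independent of x
  fit <- train_rf_classifier(x, y, seed = 5)
  # binomial null: accuracy ~ 0.5 +/- a few sd (sd = 0.025 at n = 400)
  expect_gt(fit$oob_accuracy, 0.5 - 5 * 0.025)
  expect_lt(fit$oob_accuracy, 0.5 + 5 * 0.025)
})

test_that("qrf multistep forecaster is exact on degenerate data and monotone in q", {
  # constant-100 traces: every step's median is exactly 100
  traces <- lapply(c("a", "b"), function(p) make_trace(rep(100, 120),
                                                       patient = p))
  names(traces) <- c("a", "b")
  rows <- drop_incomplete(extract_features(traces))
  model <- fit_hypo_model(rows, traces, method = "qrf", ph_min = 30,
                          seed = 3)
  fc <- predict(model, rows, type = "forecast")
  expect_equal(dim(fc), c(nrow(rows), 6))
  expect_true(all(fc == 100))

  # quantile curves are non-decreasing in q, per step
  set.seed(29)
  x <- data.frame(u = runif(300, 80, 200))
  y <- cbind(x$u + rnorm(300, 0, 10), x$u - 5 + rnorm(300, 0, 10))
  qfit <- train_qrf_multistep(x, y, seed = 17)
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  preds <- lapply(qs, function(q) predict_quantiles(qfit, x[1:40, , drop = FALSE], q))
  for (j in seq_len(length(qs) - 1)) {
    expect_true(all(preds[[j + 1]] >= preds[[j]]))
  }
})

test_that("qrf training is reproducible and refuses tiny training sets", {
  set.seed(31)
  x <- data.frame(u = runif(200, 80, 200))
  y <- cbind(x$u + rnorm(200), x$u + rnorm(200))
  a <- train_qrf_multistep(x, y, seed = 9)
  b <- train_qrf_multistep(x, y, seed = 9)
  expect_identical(predict_quantiles(a, x, 0.5), predict_quantiles(b, x, 0.5))
  expect_error(train_qrf_multistep(x[1:10, , drop = FALSE],
                                   y[1:10, , drop = FALSE], seed = 1),
               "training rows")
})

test_that("qrf step-k median recovers the conditional median of a known model", {
  # sawtooth: clean signal descends -2 mg/dL per reading from 250 to 90,
  # then resets; observed = clean + N(0, 3). Conditional median of the
  # glucose k steps ahead given the present is clean(t) - 2k.
  set.seed(41)
  period <- 80
  clean <- rep(seq(250, by = -2, length.out = period), 13)[1:1000]
  obs <- pmin(pmax(clean + rnorm(1000, 0, 3), 40), 450)
  tr <- make_trace(round(obs, 1))
  rows <- drop_incomplete(extract_features(tr))
  model <- fit_hypo_model(rows, list(p1 = tr), method = "qrf", ph_min = 30,
                          seed = 19)
  fc <- predict(model, rows, type = "forecast")
  # judge away from the reset discontinuity
  mid <- rows$glucose > 150 & rows$glucose < 220
  for (k in c(1, 3, 6)) {
    err <- fc[mid, k] - (rows$glucose[mid] - 2 * k)
    expect_lt(median(abs(err)), 6)
  }
})

test_that("the consecutive-prediction rule matches a brute-force run scan", {
  expect_true(infer_sustained(c(65, 66, 68, 72, 80, 85)))
  expect_false(infer_sustained(c(65, 72, 66, 72, 66, 72)))
  expect_error(infer_sustained(c(65, 66)), "shorter")
  set.seed(23)
  m <- matrix(runif(10000 * 6, 50, 90), ncol = 6)
  got <- infer_sustained(m)
  want <- apply(m, 1, brute_run_alert, cutoff = 70, mc = 3)
  expect_equal(got, want)
  # monotonicity: lowering a predicted value never switches an alert off
  on <- which(got)[1:200]
  for (i in on) {
    v <- m[i, ]
    j <- sample(6, 1)
    v[j] <- v[j] - runif(1, 0, 30)
    expect_true(infer_sustained(v))
  }
})

test_that("rf alert operating point uses the >= tie rule and is monotone", {
  set.seed(7)
  x <- data.frame(f1 = c(rnorm(50, -3), rnorm(50, 3)))
  y <- rep(c(FALSE, TRUE), each = 50)
  traces <- list(p1 = make_trace(rep(100, 60)))
  fitc <- train_rf_classifier(x, y, seed = 11)
  p <- predict_prob(fitc, x)
  expect_true(all((p >= 0.5) == (p >= 0.5)))
  # ties alert: threshold exactly at an attained probability
  th <- p[which(y)[1]]
  expect_true((p >= th)[which(y)[1]])
  # sweeping the threshold upward never increases the alert count
  counts <- vapply(seq(0, 1, by = 0.1), function(t) sum(p >= t), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("model artifacts round-trip through disk with metadata", {
  traces <- list(a = make_trace(rep(100, 120), patient = "a"))
  rows <- drop_incomplete(extract_features(traces))
  model <- fit_hypo_model(rows, traces, method = "qrf", ph_min = 30, seed = 3)
  path <- tempfile(fileext = ".rds")
  on.exit(unlink(path))
  save_hypo_model(model, path)
  back <- load_hypo_model(path)
  expect_equal(back$feature_names, model$feature_names)
  expect_identical(predict(back, rows), predict(model, rows))
  meta <- jsonlite::fromJSON(readRDS(path)$metadata_json)
  expect_equal(meta$ph_min, 30)
  expect_equal(meta$method, "qrf")
})
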