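#' Validation run configuration
#'
#' Bundles every knob of the train/predict/evaluate harness run by
#' [run_validation()]. Defaults mirror the reference setup: 30-minute
#' horizon, sustained-event target, lower-quartile QRF forecasts with the
#' three-consecutive-predictions rule, patient splits replicated 5 times,
#' chronological splits at 70/30.
#'
#' @param strategy `"time_based"`, `"patient_based"`, or `"random_split"` —
#'   the last is a diagnostic-only mode: decision rows are sampled uniformly
#'   into train/validation regardless of patient or chronology, the classic
#'   random cross-validation whose autocorrelation leakage the two headline
#'   protocols are designed to avoid. Its (optimistic) numbers are for
#'   comparison, never for reporting model performance.
#' @param method `"qrf"` or `"rf"`.
#' @param ph_min prediction horizon, minutes.
#' @param target `"sustained"` or `"all"`.
#' @param n_train training patients per replication (patient-based);
#'   default `floor(0.65 * n_patients)`.
#' @param n_replications patient-based replications.
#' @param train_fraction chronological training fraction.
#' @param quantile,glucose_cutoff,min_consecutive,prob_threshold,num_trees,min_node_size,max_train_rows
#'   model options passed to [fit_hypo_model()].
#' @param feature a [feature_config()].
#' @param seed integer master seed; all sub-seeds derive from it.
#' @return list of class `validation_config`.
#' @export
validation_config <- function(strategy = c("time_based", "patient_based",
                                           "random_split"),
                              method = c("qrf", "rf"), ph_min = 30,
                              target = c("sustained", "all"),
                              n_train = NULL, n_replications = 5,
                              train_fraction = 0.7, quantile = 0.25,
                              glucose_cutoff = 70, min_consecutive = NULL,
                              prob_threshold = 0.5, num_trees = 200,
                              min_node_size = 5, max_train_rows = 20000,
                              feature = feature_config(), seed = 1) {
  structure(list(strategy = match.arg(strategy), method = match.arg(method),
                 ph_min = ph_min, target = match.arg(target),
                 n_train = n_train, n_replications = n_replications,
                 train_fraction = train_fraction, quantile = quantile,
                 glucose_cutoff = glucose_cutoff,
                 min_consecutive = min_consecutive,
                 prob_threshold = prob_threshold, num_trees = num_trees,
                 min_node_size = min_node_size,
                 max_train_rows = max_train_rows, feature = feature,
                 seed = seed),
            class = "validation_config")
}

#' Run the full train/predict/evaluate harness
#'
#' Detects events, extracts features, splits per the chosen strategy, fits
#' the alert model on the training side, scores the validation side, and
#' aggregates event-class-aware metrics. Patient-based runs report the mean
#' and sample (n-1) SD of each metric over replications; time-based runs
#' pool validation instances across patients (a per-patient breakdown is
#' also emitted). A leakage audit asserting train/validation disjointness
#' (patients, respectively chronology) is run on every call.
#'
#' @param traces named list of [cgm_trace()] objects.
#' @param config a [validation_config()].
#' @param keep_details keep the fitted model(s), instances and alerts in the
#'   report (time-based: the single model; patient-based: last replication).
#' @return object of class `validation_report`.
#' @export
run_validation <- function(traces, config = validation_config(),
                           keep_details = FALSE) {
  if (inherits(traces, "cgm_trace")) traces <- list(traces)
  if (is.null(names(traces)) || any(names(traces) == "")) {
    names(traces) <- vapply(traces, function(tr) tr$patient_id, character(1))
  }
  grid_step <- traces[[1]]$grid_step
  mc <- config$min_consecutive %||%
    (if (config$target == "sustained") 3L else 1L)
  events <- detect_events(traces, threshold = config$glucose_cutoff)
  rows <- drop_incomplete(extract_features(traces, config = config$feature))
  target_events <- if (config$target == "sustained") {
    events[events$event_class == "sustained", , drop = FALSE]
  } else events

  fit_on <- function(train_rows, train_ids, fit_seed) {
    fit_hypo_model(train_rows, traces[train_ids],
                   events = events[events$patient_id %in% train_ids, ,
                                   drop = FALSE],
                   method = config$method, ph_min = config$ph_min,
                   target = config$target, quantile = config$quantile,
                   glucose_cutoff = config$glucose_cutoff,
                   min_consecutive = mc,
                   prob_threshold = config$prob_threshold,
                   num_trees = config$num_trees,
                   min_node_size = config$min_node_size,
                   max_train_rows = config$max_train_rows, seed = fit_seed)
  }
  eval_inst <- function(val_rows) {
    label_instances(val_rows, events, ph_min = config$ph_min,
                    target = config$target, min_consecutive = mc,
                    glucose_cutoff = config$glucose_cutoff,
                    grid_step = grid_step)
  }

  if (config$strategy %in% c("patient_based", "random_split")) {
    if (config$strategy == "patient_based") {
      n_train <- config$n_train %||% floor(0.65 * length(traces))
      plan <- make_patient_split(names(traces), n_train,
                                 config$n_replications, config$seed)
    } else {
      plan <- list(strategy = "random_split",
                   train_fraction = config$train_fraction,
                   n_replications = config$n_replications,
                   seed = config$seed)
    }
    reps <- list()
    details <- NULL
    for (r in seq_len(config$n_replications)) {
      if (config$strategy == "patient_based") {
        a <- plan$assignments[[r]]
        stopifnot(length(intersect(a$train, a$validation)) == 0)  # audit
        train_rows <- rows[rows$patient_id %in% a$train, , drop = FALSE]
        val_rows <- rows[rows$patient_id %in% a$validation, , drop = FALSE]
        train_ids <- a$train
        val_ids <- a$validation
      } else {
        # diagnostic random-sampling split: rows drawn uniformly, ignoring
        # patient identity and chronology (autocorrelation leaks by design)
        set.seed(derive_seed(config$seed, 500 + r))
        pick <- sample.int(nrow(rows),
                           floor(config$train_fraction * nrow(rows)))
        train_rows <- rows[sort(pick), , drop = FALSE]
        val_rows <- rows[-sort(pick), , drop = FALSE]
        train_ids <- val_ids <- names(traces)
      }
      model <- fit_on(train_rows, train_ids,
                      derive_seed(config$seed, 100 + r))
      inst <- eval_inst(val_rows)
      stopifnot(all(inst$patient_id %in% val_ids))              # id audit
      alerts <- predict(model, inst)
      m <- alert_metrics(confusion(inst, alerts))
      lt <- lead_times(inst, alerts,
                       target_events[target_events$patient_id %in% val_ids, ,
                                     drop = FALSE])
      reps[[r]] <- data.frame(
        replication = r, n_instances = nrow(inst),
        n_positive = sum(inst$label), usable = sum(inst$label) > 0,
        tp = m$counts$tp, fp = m$counts$fp, tn = m$counts$tn,
        fn = m$counts$fn, fp_nonhypo = m$counts$fp_nonhypo,
        fp_transient = m$counts$fp_transient,
        sensitivity = m$sensitivity, specificity = m$specificity,
        far = m$far, far_nonhypo_only = m$far_nonhypo_only,
        mean_lead_time_min = lt$mean_lead_time_min,
        n_events_detected = lt$n_events_detected,
        n_events_total = lt$n_events_total)
      if (keep_details) {
        details <- list(model = model, instances = inst, alerts = alerts)
      }
    }
    per_rep <- do.call(rbind, reps)
    if (any(!per_rep$usable)) {
      vlog("run_validation: %d replication(s) without positive validation instances excluded from aggregation",
           sum(!per_rep$usable))
    }
    use <- per_rep[per_rep$usable, , drop = FALSE]
    metric_cols <- c("sensitivity", "specificity", "far",
                     "far_nonhypo_only", "fp", "fp_nonhypo",
                     "mean_lead_time_min")
    aggregate <- list()
    for (mcol in metric_cols) {
      aggregate[[mcol]] <- mean(use[[mcol]], na.rm = TRUE)
      aggregate[[paste0(mcol, "_sd")]] <- stats::sd(use[[mcol]], na.rm = TRUE)
    }
    report <- list(strategy = config$strategy, config = config, plan = plan,
                   per_replication = per_rep, aggregate = aggregate,
                   n_replications_used = nrow(use), details = details)
  } else {
    plan <- make_time_split(traces, config$train_fraction)
    keep <- rows$patient_id %in% names(plan$boundaries)
    rows <- rows[keep, , drop = FALSE]
    bnd <- as.numeric(plan$boundaries[rows$patient_id])
    t <- as.numeric(rows$decision_time)
    # training labels and forecast targets must lie fully before the boundary
    train_rows <- rows[t + config$ph_min * 60 < bnd, , drop = FALSE]
    val_rows <- rows[t >= bnd, , drop = FALSE]
    # leakage audit: strict chronological ordering per patient
    for (pid in unique(val_rows$patient_id)) {
      b <- as.numeric(plan$boundaries[pid])
      tt <- as.numeric(train_rows$decision_time[train_rows$patient_id == pid])
      vv <- as.numeric(val_rows$decision_time[val_rows$patient_id == pid])
      stopifnot(all(tt < b), all(vv >= b))
    }
    model <- fit_on(train_rows, names(plan$boundaries),
                    derive_seed(config$seed, 100))
    inst <- eval_inst(val_rows)
    alerts <- predict(model, inst)
    m <- alert_metrics(confusion(inst, alerts))
    # lead-time accounting covers only events inside the validation period
    val_events <- target_events[
      target_events$patient_id %in% names(plan$boundaries) &
        as.numeric(target_events$onset_time) >=
          as.numeric(plan$boundaries[target_events$patient_id]), ,
      drop = FALSE]
    lt <- lead_times(inst, alerts, val_events)
    per_patient <- do.call(rbind, lapply(unique(inst$patient_id),
                                         function(pid) {
      sel <- inst$patient_id == pid
      mp <- alert_metrics(confusion(inst[sel, , drop = FALSE], alerts[sel]))
      data.frame(patient_id = pid, n_instances = sum(sel),
                 n_positive = sum(inst$label[sel]),
                 tp = mp$counts$tp, fp = mp$counts$fp, tn = mp$counts$tn,
                 fn = mp$counts$fn, sensitivity = mp$sensitivity,
                 specificity = mp$specificity, far = mp$far)
    }))
    aggregate <- list(sensitivity = m$sensitivity,
                      specificity = m$specificity, far = m$far,
                      far_nonhypo_only = m$far_nonhypo_only,
                      fp = m$counts$fp, fp_nonhypo = m$counts$fp_nonhypo,
                      mean_lead_time_min = lt$mean_lead_time_min)
    report <- list(strategy = "time_based", config = config, plan = plan,
                   counts = m$counts, per_patient = per_patient,
                   aggregate = aggregate, lead = lt,
                   n_instances = nrow(inst), n_positive = sum(inst$label),
                   details = if (keep_details)
                     list(model = model, instances = inst, alerts = alerts,
                          events = events) else NULL)
  }
  class(report) <- "validation_report"
  report
}

#' @export
print.validation_report <- function(x, ...) {
  a <- x$aggregate
  if (x$strategy %in% c("patient_based", "random_split")) {
    cat(sprintf("Validation report (%s, %d replications used, method %s, %d-min PH, target %s)\n",
                gsub("_", "-", x$strategy), x$n_replications_used,
                x$config$method, x$config$ph_min, x$config$target))
    cat(sprintf("  sensitivity %s (%s)%%  specificity %s (%s)%%\n",
                fmt_pct(a$sensitivity), fmt_pct(a$sensitivity_sd),
                fmt_pct(a$specificity), fmt_pct(a$specificity_sd)))
    cat(sprintf("  false alerts %s (%s); nonhypoglycemic only %s (%s)\n",
                fmt_pct(a$fp, 1), fmt_pct(a$fp_sd, 1),
                fmt_pct(a$fp_nonhypo, 1), fmt_pct(a$fp_nonhypo_sd, 1)))
    cat(sprintf("  FAR %s (%s)%%  mean lead time %s min\n",
                fmt_pct(a$far), fmt_pct(a$far_sd),
                fmt_pct(a$mean_lead_time_min)))
  } else {
    cat(sprintf("Validation report (time-based, pooled over %d patients, method %s, %d-min PH, target %s)\n",
                nrow(x$per_patient), x$config$method, x$config$ph_min,
                x$config$target))
    cat(sprintf("  %d instances (%d positive)\n", x$n_instances,
                x$n_positive))
    cat(sprintf("  sensitivity %s%%  specificity %s%%\n",
                fmt_pct(a$sensitivity), fmt_pct(a$specificity)))
    cat(sprintf("  false alerts %d (nonhypoglycemic only %d)  FAR %s%% / %s%%\n",
                a$fp, a$fp_nonhypo, fmt_pct(a$far),
                fmt_pct(a$far_nonhypo_only)))
    cat(sprintf("  events detected %d/%d, mean lead time %s min\n",
                x$lead$n_events_detected, x$lead$n_events_total,
                fmt_pct(a$mean_lead_time_min)))
  }
  invisible(x)
}

# plain-list view of a report for JSON export (deterministic, no handles)
report_to_list <- function(report) {
  cfg <- report$config
  out <- list(
    strategy = report$strategy,
    config = list(method = cfg$method, ph_min = cfg$ph_min,
                  target = cfg$target, strategy = cfg$strategy,
                  n_replications = cfg$n_replications,
                  train_fraction = cfg$train_fraction,
                  quantile = cfg$quantile,
                  glucose_cutoff = cfg$glucose_cutoff,
                  prob_threshold = cfg$prob_threshold,
                  num_trees = cfg$num_trees,
                  min_node_size = cfg$min_node_size,
                  max_train_rows = cfg$max_train_rows, seed = cfg$seed),
    aggregate = report$aggregate)
  if (report$strategy == "patient_based") {
    out$per_replication <- report$per_replication
    out$n_replications_used <- report$n_replications_used
  } else {
    out$counts <- unclass(report$counts)
    out$per_patient <- report$per_patient
    out$n_instances <- report$n_instances
    out$n_positive <- report$n_positive
    out$lead <- list(mean_lead_time_min = report$lead$mean_lead_time_min,
                     n_events_detected = report$lead$n_events_detected,
                     n_events_total = report$lead$n_events_total)
  }
  out
}

#' Write a validation report to JSON / CSV
#'
#' The JSON mirrors the report structure; the CSV summary has one row per
#' metric block in the layout sensitivity / specificity / false alerts (both
#' accounting variants) / FAR / mean lead time.
#'
#' @param report a `validation_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_validation_json <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_validation_json
#' @export
write_validation_csv <- function(report, path) {
  a <- report$aggregate
  df <- data.frame(
    metric = c("sensitivity_pct", "specificity_pct", "false_alerts",
               "false_alerts_nonhypo_only", "far_pct",
               "far_nonhypo_only_pct", "mean_lead_time_min"),
    value = c(a$sensitivity, a$specificity, a$fp, a$fp_nonhypo, a$far,
              a$far_nonhypo_only, a$mean_lead_time_min),
    sd = if (report$strategy == "patient_based")
      c(a$sensitivity_sd, a$specificity_sd, a$fp_sd, a$fp_nonhypo_sd,
        a$far_sd, a$far_nonhypo_only_sd %||% NA_real_,
        a$mean_lead_time_min_sd) else NA_real_)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
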