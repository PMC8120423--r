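#' Instance-level confusion counts with event-class-aware false positives
#'
#' Tabulates alert decisions against instance labels at the level of 5-minute
#' decision points. False positives are split by what actually happened in
#' the alert's horizon: `fp_transient` counts false alerts with a transient
#' (but no counted sustained) onset inside `(t, t + ph]`, `fp_nonhypo` the
#' remainder — alerts with no hypoglycemic onset at all. Always
#' `fp = fp_nonhypo + fp_transient` and `tp + fp + tn + fn` equals the number
#' of evaluated instances.
#'
#' @param instances labeled instance data frame from [label_instances()].
#' @param alerts logical vector of alert decisions aligned with `instances`.
#' @return object of class `confusion_counts`.
#' @export
confusion <- function(instances, alerts) {
  alerts <- as.logical(alerts)
  if (length(alerts) != nrow(instances)) {
    stop("confusion: instances and decisions are misaligned (",
         nrow(instances), " vs ", length(alerts), ")")
  }
  lab <- instances$label
  tp <- sum(lab & alerts)
  fn <- sum(lab & !alerts)
  fp <- sum(!lab & alerts)
  tn <- sum(!lab & !alerts)
  fp_transient <- sum(!lab & alerts & instances$has_transient)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 fp_nonhypo = fp - fp_transient,
                 fp_transient = fp_transient,
                 n = length(alerts)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion (n = %d instances): tp %d, fp %d, tn %d, fn %d\n",
              x$n, x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  fp split: %d nonhypoglycemic, %d transient-onset\n",
              x$fp_nonhypo, x$fp_transient))
  invisible(x)
}

#' Sensitivity, specificity and false alert rate from confusion counts
#'
#' All metrics are on the percent scale, computed on unrounded arithmetic:
#' sensitivity `= 100 tp / (tp + fn)`, specificity `= 100 tn / (tn + fp)`,
#' and the false alert rate — the share of issued alerts not followed by the
#' targeted event class — in two accounting variants:
#' variant A (`far`) counts every false positive,
#' `far = 100 fp / (tp + fp)`; variant B (`far_nonhypo_only`) counts only
#' false positives with no hypoglycemic onset at all in the horizon,
#' `100 fp_nonhypo / (tp + fp_nonhypo)`. Variant B can never exceed
#' variant A. A metric with zero denominator is `NA` (not 0).
#'
#' @param counts a `confusion_counts` object (or list with the same fields).
#' @return object of class `alert_metrics`: the counts plus `sensitivity`,
#'   `specificity`, `far`, `far_nonhypo_only` in percent.
#' @examples
#' m <- metrics_from_counts(tp = 7181, fp = 40502, tn = 0, fn = 0,
#'                          fp_nonhypo = 40502, fp_transient = 0)
#' round_half_up(m$far)   # 84.94
#' @export
alert_metrics <- function(counts) {
  structure(list(
    counts = counts,
    sensitivity = pct_of(counts$tp, counts$tp + counts$fn),
    specificity = pct_of(counts$tn, counts$tn + counts$fp),
    far = pct_of(counts$fp, counts$tp + counts$fp),
    far_nonhypo_only = pct_of(counts$fp_nonhypo,
                              counts$tp + counts$fp_nonhypo)),
    class = "alert_metrics")
}

#' @rdname alert_metrics
#' @param tp,fp,tn,fn,fp_nonhypo,fp_transient raw counts.
#' @export
metrics_from_counts <- function(tp, fp, tn, fn, fp_nonhypo = fp,
                                fp_transient = fp - fp_nonhypo) {
  stopifnot(fp_nonhypo + fp_transient == fp)
  alert_metrics(structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                               fp_nonhypo = fp_nonhypo,
                               fp_transient = fp_transient,
                               n = tp + fp + tn + fn),
                          class = "confusion_counts"))
}

#' @export
print.alert_metrics <- function(x, ...) {
  cat(sprintf("sensitivity %s%%  specificity %s%%\n",
              fmt_pct(x$sensitivity), fmt_pct(x$specificity)))
  cat(sprintf("false alert rate %s%% (all FP) / %s%% (nonhypoglycemic FP only)\n",
              fmt_pct(x$far), fmt_pct(x$far_nonhypo_only)))
  invisible(x)
}

#' Lead times of detected events
#'
#' An event is detected when at least one true-positive instance targets it
#' (an alerting positive instance whose label window contains the onset);
#' its lead time is the interval from the earliest such decision time to the
#' onset. Alerts only at or after onset leave the event undetected. The mean
#' is over detected events and `NA` when none is detected.
#'
#' @param instances labeled instances ([label_instances()]); their
#'   `label_window_min` attribute fixes which decision times can target an
#'   event.
#' @param alerts logical alert vector aligned with `instances`.
#' @param events `hypo_events` of the targeted class (pass the sustained
#'   subset for the sustained target).
#' @return object of class `lead_times`: `mean_lead_time_min`,
#'   `n_events_detected`, `n_events_total` and a per-event data frame.
#' @export
lead_times <- function(instances, alerts, events) {
  w_min <- attr(instances, "label_window_min")
  if (is.null(w_min)) stop("lead_times: instances lack a label window attribute")
  alerts <- as.logical(alerts)
  if (length(alerts) != nrow(instances)) stop("lead_times: misaligned inputs")
  hit <- instances$label & alerts
  per <- data.frame(patient_id = events$patient_id,
                    onset_time = events$onset_time,
                    detected = FALSE, lead_time_min = NA_real_)
  for (i in seq_len(nrow(events))) {
    sel <- instances$patient_id == events$patient_id[i] & hit
    if (!any(sel)) next
    t <- as.numeric(instances$decision_time[sel])
    o <- as.numeric(events$onset_time[i])
    t <- t[t >= o - w_min * 60 & t < o]
    if (length(t) > 0) {
      per$detected[i] <- TRUE
      per$lead_time_min[i] <- (o - min(t)) / 60
    }
  }
  structure(list(mean_lead_time_min = if (any(per$detected))
                   mean(per$lead_time_min[per$detected]) else NA_real_,
                 n_events_detected = sum(per$detected),
                 n_events_total = nrow(per),
                 per_event = per),
            class = "lead_times")
}

#' @export
print.lead_times <- function(x, ...) {
  cat(sprintf("events detected: %d of %d; mean lead time %s min\n",
              x$n_events_detected, x$n_events_total,
              ifelse(is.na(x$mean_lead_time_min), "NA",
                     fmt_pct(x$mean_lead_time_min))))
  invisible(x)
}

#' Sweep an alert operating point
#'
#' Re-evaluates a fitted model over a grid of operating-point values for one
#' knob: the rf probability threshold, the qrf glucose cutoff, or the qrf
#' forecast quantile. For knobs that loosen the alert criterion the alert
#' count is non-decreasing along the sweep, so sensitivity is non-decreasing
#' and specificity non-increasing.
#'
#' @param model a `hypo_model`.
#' @param instances labeled instances to score ([label_instances()]).
#' @param knob one of `"prob_threshold"`, `"glucose_cutoff"`, `"quantile"`.
#' @param values numeric vector of knob values (sorted internally).
#' @param events optional `hypo_events` of the targeted class; when given,
#'   mean lead time is reported per operating point.
#' @return data frame of class `alert_sweep`: one row per value with counts,
#'   sensitivity, specificity, both FAR variants and mean lead time.
#' @export
sweep_operating_points <- function(model, instances,
                                   knob = c("prob_threshold",
                                            "glucose_cutoff", "quantile"),
                                   values, events = NULL) {
  knob <- match.arg(knob)
  if (length(values) == 0) stop("sweep_operating_points: empty values")
  values <- sort(values)
  if (knob == "prob_threshold" && model$method != "rf") {
    stop("sweep_operating_points: prob_threshold applies to method 'rf'")
  }
  if (knob %in% c("glucose_cutoff", "quantile") && model$method != "qrf") {
    stop("sweep_operating_points: ", knob, " applies to method 'qrf'")
  }
  score <- NULL; fc <- NULL
  if (knob == "prob_threshold") {
    score <- predict(model, instances, type = "score")
  } else if (knob == "glucose_cutoff") {
    fc <- predict(model, instances, type = "forecast")
  }
  rows <- lapply(values, function(v) {
    alerts <- switch(knob,
      prob_threshold = score >= v,
      glucose_cutoff = as.logical(infer_sustained(
        fc, glucose_cutoff = v, min_consecutive = model$min_consecutive)),
      quantile = predict(model, instances, type = "alert", quantile = v))
    m <- alert_metrics(confusion(instances, alerts))
    lt <- if (!is.null(events)) lead_times(instances, alerts, events) else NULL
    data.frame(value = v, n_alerts = sum(alerts),
               tp = m$counts$tp, fp = m$counts$fp, tn = m$counts$tn,
               fn = m$counts$fn,
               sensitivity = m$sensitivity, specificity = m$specificity,
               far = m$far, far_nonhypo_only = m$far_nonhypo_only,
               mean_lead_time_min = if (is.null(lt)) NA_real_ else
                 lt$mean_lead_time_min)
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- knob
  class(out) <- c("alert_sweep", "data.frame")
  out
}

#' Write an operating-point sweep table to CSV
#'
#' Columns: the swept knob, alert and confusion counts, sensitivity,
#' specificity, both false-alert-rate variants, mean lead time.
#'
#' @param sweep an `alert_sweep` from [sweep_operating_points()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE)
  invisible(path)
}
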