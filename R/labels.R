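#' Label decision instances for alert prediction
#'
#' Builds the instance set evaluated by the alert pipeline. Each complete
#' feature row whose current glucose is at or above `glucose_cutoff` (an alert
#' for an already-ongoing event is not predictive; switch off with
#' `exclude_active = FALSE`) becomes one decision instance. An instance is
#' positive when an event of the targeted class starts soon enough that the
#' alert criterion can in principle see it inside the prediction horizon:
#' for the sustained target the onset must lie in
#' `(t, t + ph_min - (min_consecutive - 1) * grid_step]`, so that at least
#' `min_consecutive` sub-threshold readings of the event fall within the
#' horizon; for the all-events target (`min_consecutive = 1`) this is exactly
#' "onset within `(t, t + ph_min]`".
#'
#' The returned instances also carry `has_sustained` / `has_transient` flags
#' (any onset of that class anywhere in the full horizon `(t, t + ph_min]`),
#' used by [confusion()] to split false positives by event class.
#'
#' @param rows complete feature rows ([extract_features()] then
#'   [drop_incomplete()]).
#' @param events `hypo_events` data frame for the same patients.
#' @param ph_min prediction horizon, minutes (30 or 60 in the reference
#'   setup).
#' @param target `"sustained"` (positive = impending sustained event) or
#'   `"all"` (positive = any impending hypoglycemic event).
#' @param min_consecutive consecutive sub-threshold predictions required by
#'   the alert rule; defaults to 3 for the sustained target and 1 for the
#'   all-events target.
#' @param glucose_cutoff hypoglycemia threshold, mg/dL.
#' @param exclude_active drop instances whose current glucose is below the
#'   cutoff.
#' @param grid_step grid spacing, minutes.
#' @return a data frame of instances: the input feature rows (filtered)
#'   plus logical columns `label`, `has_sustained`, `has_transient`.
#'   Attributes `ph_min`, `label_window_min`, `target` record the settings.
#' @export
label_instances <- function(rows, events, ph_min = 30,
                            target = c("sustained", "all"),
                            min_consecutive = NULL, glucose_cutoff = 70,
                            exclude_active = TRUE, grid_step = 5) {
  target <- match.arg(target)
  if (is.null(min_consecutive)) {
    min_consecutive <- if (target == "sustained") 3L else 1L
  }
  keep <- rows$complete
  if (exclude_active) keep <- keep & rows$glucose >= glucose_cutoff
  out <- rows[keep, , drop = FALSE]
  label_window <- ph_min - (min_consecutive - 1) * grid_step
  if (label_window <= 0) {
    stop("label_instances: min_consecutive too large for the horizon")
  }
  n <- nrow(out)
  out$label <- logical(n)
  out$has_sustained <- logical(n)
  out$has_transient <- logical(n)
  for (pid in unique(out$patient_id)) {
    sel <- out$patient_id == pid
    t <- as.numeric(out$decision_time[sel])
    ev <- events[events$patient_id == pid, , drop = FALSE]
    on_s <- sort(as.numeric(ev$onset_time[ev$event_class == "sustained"]))
    on_t <- sort(as.numeric(ev$onset_time[ev$event_class == "transient"]))
    in_win <- function(onsets, w) {
      if (length(onsets) == 0) return(logical(length(t)))
      (findInterval(t + w * 60, onsets) - findInterval(t, onsets)) > 0
    }
    out$has_sustained[sel] <- in_win(on_s, ph_min)
    out$has_transient[sel] <- in_win(on_t, ph_min)
    if (target == "sustained") {
      out$label[sel] <- in_win(on_s, label_window)
    } else {
      out$label[sel] <- in_win(on_s, label_window) | in_win(on_t, label_window)
    }
  }
  rownames(out) <- NULL
  attr(out, "ph_min") <- ph_min
  attr(out, "label_window_min") <- label_window
  attr(out, "target") <- target
  out
}
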