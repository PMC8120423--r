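#' Random-forest alert classifier (low-level)
#'
#' Fits a probability random forest that classifies decision instances as
#' positive (impending sustained hypoglycemic event) versus negative
#' (transient or no event). This is the building block behind
#' [fit_hypo_model()] `method = "rf"`; it accepts a bare predictor matrix so
#' it can be exercised and tested outside the CGM pipeline.
#'
#' @param x data frame or matrix of predictors.
#' @param y logical (or two-level factor) labels, `TRUE` = positive class.
#' @param num_trees,min_node_size forest hyperparameters.
#' @param mtry candidate features per split; default `floor(sqrt(p))`, the
#'   classification convention.
#' @param seed integer seed; training is bit-reproducible given the seed.
#' @return object of class `rf_alert_classifier` with elements `forest`
#'   (the underlying `ranger` fit), `feature_names`, `oob_accuracy`.
#' @export
train_rf_classifier <- function(x, y, num_trees = 200, min_node_size = 5,
                                mtry = NULL, seed = 1) {
  x <- as.data.frame(x)
  if (is.factor(y)) y <- y == levels(y)[2]
  y <- as.logical(y)
  if (all(y)) stop("train_rf_classifier: training set has no negative instances")
  if (!any(y)) stop("train_rf_classifier: training set has no positive instances")
  d <- x
  d$.y <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  set.seed(seed)                 # ranger may also draw from the R RNG
  fit <- ranger::ranger(dependent.variable.name = ".y", data = d,
                        num.trees = num_trees, min.node.size = min_node_size,
                        mtry = mtry, probability = TRUE, seed = seed,
                        num.threads = 1)
  oob <- fit$predictions[, "pos"]
  oob_acc <- mean((oob >= 0.5) == y, na.rm = TRUE)
  structure(list(forest = fit, feature_names = names(x),
                 num_trees = num_trees, min_node_size = min_node_size,
                 seed = seed, oob_accuracy = oob_acc),
            class = "rf_alert_classifier")
}

#' Positive-class probability from an alert classifier
#'
#' @param object an `rf_alert_classifier`.
#' @param x predictor rows.
#' @return numeric vector of positive-class probabilities.
#' @export
predict_prob <- function(object, x) {
  stopifnot(inherits(object, "rf_alert_classifier"))
  x <- as.data.frame(x)[, object$feature_names, drop = FALSE]
  p <- stats::predict(object$forest, data = x, num.threads = 1)$predictions
  as.numeric(p[, "pos"])
}

#' Multistep quantile-forest forecaster (low-level)
#'
#' Fits one quantile regression forest per forecast step (direct multistep
#' strategy: step k has its own forest predicting glucose k grid steps
#' ahead). Any conditional quantile of each step's distribution can then be
#' queried, so the forecaster is not tied to the conditional mean — accuracy
#' near the hypoglycemic range is what matters for alerts.
#'
#' @param x data frame of predictors (one row per training instance).
#' @param y_future numeric matrix, `nrow(x)` by `n_steps`: column k holds the
#'   glucose observed k steps after each instance. Rows with any `NA` (a gap
#'   inside the horizon) are excluded from training.
#' @param num_trees,min_node_size forest hyperparameters.
#' @param mtry candidate features per split; default `floor(p / 3)`, the
#'   regression-forest convention.
#' @param min_train_rows minimum usable training rows; fewer is an error.
#' @param seed integer seed (each step derives its own sub-seed).
#' @return object of class `qrf_multistep` with one `ranger` quantile forest
#'   per step.
#' @export
train_qrf_multistep <- function(x, y_future, num_trees = 200,
                                min_node_size = 5, mtry = NULL,
                                min_train_rows = 50, seed = 1) {
  x <- as.data.frame(x)
  y_future <- as.matrix(y_future)
  stopifnot(nrow(x) == nrow(y_future))
  ok <- stats::complete.cases(x) & !apply(is.na(y_future), 1, any)
  if (sum(ok) < min_train_rows) {
    stop("train_qrf_multistep: only ", sum(ok),
         " usable training rows (need >= ", min_train_rows, ")")
  }
  x <- x[ok, , drop = FALSE]
  y_future <- y_future[ok, , drop = FALSE]
  n_steps <- ncol(y_future)
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(x) / 3))
  forests <- vector("list", n_steps)
  for (k in seq_len(n_steps)) {
    d <- x
    d$.y <- y_future[, k]
    set.seed(derive_seed(seed, k))   # ranger may also draw from the R RNG
    forests[[k]] <- ranger::ranger(dependent.variable.name = ".y", data = d,
                                   num.trees = num_trees,
                                   min.node.size = min_node_size,
                                   mtry = mtry, quantreg = TRUE,
                                   seed = derive_seed(seed, k),
                                   num.threads = 1)
  }
  structure(list(forests = forests, n_steps = n_steps,
                 feature_names = names(x), num_trees = num_trees,
                 min_node_size = min_node_size, seed = seed,
                 n_train = nrow(x)),
            class = "qrf_multistep")
}

#' Quantile forecasts from a multistep forecaster
#'
#' @param object a `qrf_multistep`.
#' @param x predictor rows.
#' @param quantile a single quantile in (0, 1).
#' @return numeric matrix, `nrow(x)` by `n_steps`, of predicted glucose.
#' @export
predict_quantiles <- function(object, x, quantile = 0.5) {
  stopifnot(inherits(object, "qrf_multistep"), length(quantile) == 1,
            quantile > 0, quantile < 1)
  x <- as.data.frame(x)[, object$feature_names, drop = FALSE]
  out <- matrix(NA_real_, nrow(x), object$n_steps)
  for (k in seq_len(object$n_steps)) {
    p <- stats::predict(object$forests[[k]], data = x, type = "quantiles",
                        quantiles = quantile, num.threads = 1)$predictions
    out[, k] <- as.numeric(p)
  }
  colnames(out) <- paste0("step_", seq_len(object$n_steps))
  out
}

#' Consecutive-prediction inference of sustained hypoglycemia
#'
#' The alert rule applied to a multistep glucose forecast: a sustained
#' hypoglycemic event is inferred when at least `min_consecutive` consecutive
#' predicted values fall strictly below `glucose_cutoff` (default: 3
#' predictions below 70 mg/dL, i.e. at least 15 predicted minutes in the
#' hypoglycemic range). The rule is monotone: lowering any predicted value
#' can only switch the alert on, never off.
#'
#' @param forecast numeric vector of predicted glucose (one horizon), or a
#'   matrix with one horizon per row.
#' @param glucose_cutoff threshold, mg/dL (strict `<`).
#' @param min_consecutive required run length of sub-threshold predictions.
#' @return logical: alert decision(s), one per horizon.
#' @examples
#' infer_sustained(c(65, 66, 68, 72, 80, 85))        # TRUE
#' infer_sustained(c(65, 72, 66, 72, 66, 72))        # FALSE
#' @export
infer_sustained <- function(forecast, glucose_cutoff = 70,
                            min_consecutive = 3) {
  if (is.matrix(forecast)) {
    if (ncol(forecast) < min_consecutive) {
      stop("infer_sustained: forecast shorter than min_consecutive")
    }
    return(apply(forecast, 1, infer_sustained,
                 glucose_cutoff = glucose_cutoff,
                 min_consecutive = min_consecutive))
  }
  if (length(forecast) < min_consecutive) {
    stop("infer_sustained: forecast shorter than min_consecutive")
  }
  r <- rle(forecast < glucose_cutoff)
  any(r$values & r$lengths >= min_consecutive)
}

# future glucose targets for rows, from the trace lattices:
# column k = glucose observed k steps after each row's grid point
future_targets <- function(rows, traces, n_steps) {
  out <- matrix(NA_real_, nrow(rows), n_steps)
  for (pid in unique(rows$patient_id)) {
    sel <- which(rows$patient_id == pid)
    tr <- traces[[pid]]
    if (is.null(tr)) stop("future_targets: no trace for patient ", pid)
    g <- as_grid(tr)$glucose
    idx <- rows$grid_index[sel]
    for (k in seq_len(n_steps)) {
      j <- idx + k
      ok <- j <= length(g)
      out[sel[ok], k] <- g[j[ok]]
    }
  }
  out
}

#' Fit a sustained-hypoglycemia alert model
#'
#' The central fitter. Two methods are available:
#' \describe{
#'   \item{`"rf"`}{direct classification — a probability random forest
#'     trained on labeled decision instances; an alert is issued when the
#'     positive-class probability reaches `prob_threshold`.}
#'   \item{`"qrf"`}{multistep forecasting — one quantile regression forest
#'     per 5-minute step of the prediction horizon (6 forests for 30 min, 12
#'     for 60 min); an alert is issued when at least `min_consecutive`
#'     consecutive predicted values fall below `glucose_cutoff`
#'     ([infer_sustained()]).}
#' }
#' The QRF forests are plain conditional-distribution regressions of future
#' glucose and do not depend on the event taxonomy; `target` affects only
#' labeling (rf training, evaluation) and the default `min_consecutive`.
#' Training rows whose forecast horizon crosses a data gap are excluded from
#' QRF training but can still be scored at prediction time. When the
#' training set exceeds `max_train_rows`, a seed-derived random subsample of
#' that size is used (forests saturate well before the full cohort size and
#' this keeps fitting time flat).
#'
#' @param rows feature rows of the training period/patients (complete rows;
#'   incomplete ones are dropped).
#' @param traces named list of [cgm_trace()] objects covering `rows` (used
#'   for forecast targets and, if `events` is missing, event detection).
#' @param events optional `hypo_events` data frame; detected from `traces`
#'   when omitted.
#' @param method `"qrf"` (default) or `"rf"`.
#' @param ph_min prediction horizon in minutes (30 or 60).
#' @param target `"sustained"` or `"all"` (see [label_instances()]).
#' @param quantile operating quantile of the QRF forecast. The default 0.25
#'   (lower quartile) is deliberately alert-eager: the alert rule asks for
#'   several *consecutive* sub-threshold marginal quantiles, which is
#'   conservative under forecast-timing uncertainty, and a low-glucose alarm
#'   should weight the lower tail of predicted glucose. Set 0.5 for plain
#'   median forecasts.
#' @param glucose_cutoff hypoglycemia threshold, mg/dL.
#' @param min_consecutive consecutive sub-threshold predictions required for
#'   a QRF alert; default 3 for the sustained target, 1 for `"all"`.
#' @param prob_threshold rf alert operating point on the class probability
#'   (alert when probability >= threshold).
#' @param num_trees,min_node_size forest hyperparameters (defaults 200 / 5).
#' @param max_train_rows training-subsample cap.
#' @param min_train_rows minimum usable training rows.
#' @param seed integer seed; fitting is bit-reproducible given the seed.
#' @return object of class `hypo_model`.
#' @export
fit_hypo_model <- function(rows, traces, events = NULL,
                           method = c("qrf", "rf"), ph_min = 30,
                           target = c("sustained", "all"), quantile = 0.25,
                           glucose_cutoff = 70, min_consecutive = NULL,
                           prob_threshold = 0.5, num_trees = 200,
                           min_node_size = 5, max_train_rows = 20000,
                           min_train_rows = 50, seed = 1) {
  method <- match.arg(method)
  target <- match.arg(target)
  if (inherits(traces, "cgm_trace")) traces <- list(traces)
  if (is.null(names(traces)) || any(names(traces) == "")) {
    names(traces) <- vapply(traces, function(tr) tr$patient_id, character(1))
  }
  grid_step <- traces[[1]]$grid_step
  n_steps <- as.integer(round(ph_min / grid_step))
  if (n_steps * grid_step != ph_min) {
    stop("fit_hypo_model: ph_min must be a multiple of the grid step")
  }
  if (is.null(min_consecutive)) {
    min_consecutive <- if (target == "sustained") 3L else 1L
  }
  rows <- drop_incomplete(rows)
  feats <- feature_columns(rows)

  if (method == "qrf") {
    y <- future_targets(rows, traces, n_steps)
    ok <- !apply(is.na(y), 1, any)
    rows_tr <- rows[ok, , drop = FALSE]
    y <- y[ok, , drop = FALSE]
    if (nrow(rows_tr) > max_train_rows) {
      set.seed(derive_seed(seed, 999))
      pick <- sort(sample.int(nrow(rows_tr), max_train_rows))
      rows_tr <- rows_tr[pick, , drop = FALSE]
      y <- y[pick, , drop = FALSE]
    }
    fit <- train_qrf_multistep(rows_tr[, feats, drop = FALSE], y,
                               num_trees = num_trees,
                               min_node_size = min_node_size,
                               min_train_rows = min_train_rows, seed = seed)
  } else {
    if (is.null(events)) events <- detect_events(traces,
                                                 threshold = glucose_cutoff)
    inst <- label_instances(rows, events, ph_min = ph_min, target = target,
                            min_consecutive = min_consecutive,
                            glucose_cutoff = glucose_cutoff,
                            grid_step = grid_step)
    if (nrow(inst) < min_train_rows) {
      stop("fit_hypo_model: only ", nrow(inst), " training instances")
    }
    if (nrow(inst) > max_train_rows) {
      # stratified subsample so both classes survive
      set.seed(derive_seed(seed, 998))
      pos <- which(inst$label); neg <- which(!inst$label)
      n_pos <- max(1L, round(max_train_rows * length(pos) / nrow(inst)))
      n_pos <- min(n_pos, length(pos))
      keep <- sort(c(sample(pos, n_pos),
                     sample(neg, min(length(neg), max_train_rows - n_pos))))
      inst <- inst[keep, , drop = FALSE]
    }
    fit <- train_rf_classifier(inst[, feats, drop = FALSE], inst$label,
                               num_trees = num_trees,
                               min_node_size = min_node_size, seed = seed)
    attr(fit, "n_train_pos") <- sum(inst$label)
  }

  structure(list(method = method, fit = fit, ph_min = ph_min,
                 n_steps = n_steps, grid_step = grid_step, target = target,
                 quantile = quantile, glucose_cutoff = glucose_cutoff,
                 min_consecutive = min_consecutive,
                 prob_threshold = prob_threshold,
                 feature_names = feats, num_trees = num_trees,
                 min_node_size = min_node_size, seed = seed,
                 n_train = if (method == "qrf") fit$n_train else
                   fit$forest$num.samples,
                 version = as.character(utils::packageVersion("hypoalert"))),
            class = "hypo_model")
}

#' Predict alerts, scores or forecasts from a fitted alert model
#'
#' @param object a [fit_hypo_model()] fit.
#' @param newdata feature rows (decision instances) to score.
#' @param type `"alert"` (logical decisions), `"score"` (rf positive-class
#'   probability; `NA` for qrf, whose rule is not probability-based), or
#'   `"forecast"` (qrf only: the per-step quantile forecast matrix).
#' @param quantile,glucose_cutoff,min_consecutive,prob_threshold operating
#'   point overrides; default to the values stored in the model.
#' @param ... unused.
#' @return logical vector, numeric vector, or forecast matrix.
#' @export
predict.hypo_model <- function(object, newdata,
                               type = c("alert", "score", "forecast"),
                               quantile = NULL, glucose_cutoff = NULL,
                               min_consecutive = NULL, prob_threshold = NULL,
                               ...) {
  type <- match.arg(type)
  quantile <- quantile %||% object$quantile
  glucose_cutoff <- glucose_cutoff %||% object$glucose_cutoff
  min_consecutive <- min_consecutive %||% object$min_consecutive
  prob_threshold <- prob_threshold %||% object$prob_threshold
  if (object$method == "qrf") {
    if (type == "score") return(rep(NA_real_, nrow(newdata)))
    fc <- predict_quantiles(object$fit, newdata, quantile = quantile)
    if (type == "forecast") return(fc)
    as.logical(infer_sustained(fc, glucose_cutoff = glucose_cutoff,
                               min_consecutive = min_consecutive))
  } else {
    if (type == "forecast") {
      stop("predict.hypo_model: forecasts are only available for method 'qrf'")
    }
    p <- predict_prob(object$fit, newdata)
    if (type == "score") return(p)
    p >= prob_threshold           # tie at the threshold alerts
  }
}

#' @export
print.hypo_model <- function(x, ...) {
  cat(sprintf("<hypo_model> method %s, %d-min horizon (%d steps), target: %s\n",
              x$method, x$ph_min, x$n_steps, x$target))
  if (x$method == "qrf") {
    cat(sprintf("  alert rule: >= %d consecutive predicted values < %g mg/dL (q = %g)\n",
                x$min_consecutive, x$glucose_cutoff, x$quantile))
  } else {
    cat(sprintf("  alert rule: P(positive) >= %g\n", x$prob_threshold))
  }
  cat(sprintf("  %d trees/forest, min node %d, %d training rows, seed %d\n",
              x$num_trees, x$min_node_size, x$n_train, x$seed))
  invisible(x)
}

#' @export
summary.hypo_model <- function(object, ...) {
  print(object)
  if (object$method == "rf") {
    cat(sprintf("  out-of-bag accuracy: %.4f\n", object$fit$oob_accuracy))
  } else {
    cat(sprintf("  per-step forests: %d, features: %d\n",
                object$n_steps, length(object$feature_names)))
  }
  invisible(object)
}

#' Issue alerts from a random-forest classifier at an operating point
#'
#' Thin convenience wrapper: alert when the predicted positive-class
#' probability is at or above `prob_threshold` (ties alert).
#'
#' @param model a `hypo_model` with `method = "rf"`.
#' @param rows feature rows.
#' @param prob_threshold probability operating point in (0, 1).
#' @return logical vector of alert decisions with the probabilities attached
#'   as attribute `score`.
#' @export
alert_rf <- function(model, rows, prob_threshold = model$prob_threshold) {
  stopifnot(inherits(model, "hypo_model"), model$method == "rf")
  p <- predict(model, rows, type = "score")
  structure(p >= prob_threshold, score = p)
}

#' Save / load a fitted alert model
#'
#' The artifact is a single RDS file whose payload carries a JSON metadata
#' block (feature list, horizon, seed, hyperparameters, package version)
#' alongside the forests.
#'
#' @param model a `hypo_model`.
#' @param path file path.
#' @return `path` (save) or the restored `hypo_model` (load).
#' @export
save_hypo_model <- function(model, path) {
  meta <- list(method = model$method, ph_min = model$ph_min,
               target = model$target, quantile = model$quantile,
               glucose_cutoff = model$glucose_cutoff,
               min_consecutive = model$min_consecutive,
               prob_threshold = model$prob_threshold,
               feature_names = model$feature_names,
               num_trees = model$num_trees,
               min_node_size = model$min_node_size, seed = model$seed,
               version = model$version)
  saveRDS(list(metadata_json = jsonlite::toJSON(meta, auto_unbox = TRUE),
               model = model), path)
  invisible(path)
}

#' @rdname save_hypo_model
#' @export
load_hypo_model <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj$model, "hypo_model"))
  obj$model
}
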