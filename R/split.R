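#' Patient-based train/validation split with replication
#'
#' Each replication draws `n_train` patients uniformly without replacement
#' for training; the remaining patients form the validation set (held-out
#' people, probing generalization to new patients). Replications use
#' independent sub-seeds derived deterministically from `seed`.
#'
#' @param patient_ids character vector of patient identifiers.
#' @param n_train number of training patients per replication (must be less
#'   than the number of patients).
#' @param n_replications number of replications (default 5).
#' @param seed integer seed.
#' @return object of class `split_plan` with `strategy = "patient_based"`
#'   and one `(train, validation)` assignment per replication.
#' @export
make_patient_split <- function(patient_ids, n_train, n_replications = 5,
                               seed = 1) {
  patient_ids <- as.character(patient_ids)
  if (n_train >= length(patient_ids)) {
    stop("make_patient_split: n_train must be smaller than the number of patients")
  }
  assignments <- lapply(seq_len(n_replications), function(r) {
    set.seed(derive_seed(seed, r))
    train <- sort(sample(patient_ids, n_train))
    list(train = train, validation = sort(setdiff(patient_ids, train)))
  })
  structure(list(strategy = "patient_based", assignments = assignments,
                 n_replications = n_replications, seed = seed,
                 patient_ids = patient_ids),
            class = "split_plan")
}

#' Time-based (chronological) train/validation split
#'
#' Per patient, the first `train_fraction` of readings is assigned to
#' training and the rest to validation (generalization to future periods).
#' The boundary is the timestamp of the first validation reading, so every
#' training time is strictly before the boundary and every validation time
#' at or after it. Patients with fewer than `min_readings` readings are
#' excluded with a warning.
#'
#' @param traces named list of [cgm_trace()] objects.
#' @param train_fraction fraction of readings used for training, in (0, 1).
#' @param min_readings minimum readings for a patient to be split.
#' @return object of class `split_plan` with `strategy = "time_based"` and a
#'   named `POSIXct` vector `boundaries` (one per retained patient).
#' @export
make_time_split <- function(traces, train_fraction = 0.7, min_readings = 10) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  if (inherits(traces, "cgm_trace")) traces <- list(traces)
  if (is.null(names(traces)) || any(names(traces) == "")) {
    names(traces) <- vapply(traces, function(tr) tr$patient_id, character(1))
  }
  short <- names(traces)[vapply(traces, length, integer(1)) < min_readings]
  if (length(short) > 0) {
    warning("make_time_split: excluded patient(s) with < ", min_readings,
            " readings: ", paste(short, collapse = ", "))
  }
  keep <- setdiff(names(traces), short)
  boundaries <- do.call(c, lapply(keep, function(pid) {
    tr <- traces[[pid]]
    n_train <- floor(train_fraction * length(tr))
    tr$time[n_train + 1]
  }))
  names(boundaries) <- keep
  structure(list(strategy = "time_based", boundaries = boundaries,
                 train_fraction = train_fraction),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  if (x$strategy == "patient_based") {
    a <- x$assignments[[1]]
    cat(sprintf("<split_plan> patient-based: %d replications, %d train / %d validation patients, seed %d\n",
                x$n_replications, length(a$train), length(a$validation),
                x$seed))
  } else {
    cat(sprintf("<split_plan> time-based: %d patients, train fraction %g\n",
                length(x$boundaries), x$train_fraction))
  }
  invisible(x)
}
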