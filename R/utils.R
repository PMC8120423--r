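# shared internal helpers

#' Round half away from zero
#'
#' Reporting convention used throughout the package: percentages and other
#' summary figures are rounded half-up (0.005 -> 0.01), not banker's-rounded
#' as by [base::round()]. Internal arithmetic is never rounded.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic sub-seed derivation: every source of randomness in the package
# flows from one user seed through this map. Result stays below 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer(((as.numeric(seed) %% 59999) * 31013 + as.numeric(k) * 7919 + 1) %%
               2147483629)
}

# Verbosity-gated logging to stderr (option hypoalert.verbose, default off).
vlog <- function(...) {
  if (isTRUE(getOption("hypoalert.verbose", FALSE))) {
    message(sprintf(...))
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# percent with not-applicable (NA) on zero denominator
pct_of <- function(num, den) {
  if (is.na(den) || den == 0) NA_real_ else 100 * num / den
}

fmt_pct <- function(x, digits = 2) {
  ifelse(is.na(x), "NA", formatC(round_half_up(x, digits), format = "f",
                                 digits = digits))
}
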