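# Shared numeric helpers. Report columns follow the field's printing
# conventions: half-up rounding for tabulated statistics, truncation toward
# zero for combined exclusion powers (conservative for a power claim).

#' Round half away from zero
#'
#' Base `round()` rounds half to even; published tables in forensic genetics
#' round half up. Used for every tabulated report column.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Truncate toward zero at a fixed number of decimals
#'
#' @param x numeric vector.
#' @param digits decimal places kept.
#' @return truncated numeric vector.
#' @keywords internal
truncate_decimal <- function(x, digits) {
  m <- 10^digits
  # tiny epsilon guards against 0.999997 landing at 999996.999... in binary
  sign(x) * floor(abs(x) * m + 1e-9) / m
}

# stop() with a consistent prefix so stage failures are attributable
abort_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
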