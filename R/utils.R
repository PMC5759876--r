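#' @keywords internal
"_PACKAGE"

#' Round half away from zero
#'
#' Fixed-precision rounding with ties going up (0.005 -> 0.01), as used in
#' printed report tables. Base [round()] rounds half to even, which would
#' print 59.985 as 59.98.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Population standard deviation
#'
#' Standard deviation with divisor n (not n - 1), the estimator used for
#' descriptive per-genome summary tables.
#'
#' @param x numeric vector.
#' @return population standard deviation.
#' @export
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

# Derive a per-component sub-seed from the master seed so each output file
# has its own documented stream. Kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_range_pair <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2 || any(is.na(x)) || x[1] > x[2])
    stop_input("%s must be a numeric pair (lo, hi) with lo <= hi", name)
  invisible(x)
}
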