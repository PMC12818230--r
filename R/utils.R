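#' @useDynLib omipipe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom rlnorm median quantile sd cor optimize
#' @importFrom utils head tail write.csv read.csv
"_PACKAGE"

#' Round half away from zero
#'
#' Percentages in cohort summaries are printed to one decimal with halves
#' rounded away from zero (so 5.35 -> 5.4), unlike base `round()`'s
#' round-half-even.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count, printed-style
#'
#' @param num numerator count
#' @param den denominator count
#' @param digits decimals (default 1)
#' @return numeric percentage rounded half-away-from-zero
#' @export
pct_of <- function(num, den, digits = 1) {
  if (den == 0) return(NA_real_)
  round_half_away(100 * num / den, digits)
}

# Deterministic stage seeds derived from one master seed; kept < 2^31.
derive_seed <- function(seed, stage) {
  offsets <- c(cohort = 11L, missingness = 23L, split = 37L,
               encoder = 53L, fusion = 71L, bootstrap = 89L, crops = 97L)
  stopifnot(stage %in% names(offsets))
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}

assert_fraction <- function(x, name, allow_zero = TRUE) {
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || !lo_ok || x > 1)
    stop(sprintf("'%s' must be a fraction in [%s,1], got %s",
                 name, if (allow_zero) "0" else "(0", format(x)), call. = FALSE)
  invisible(x)
}
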