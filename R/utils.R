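#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.5 -> 1), the convention used for
#' all printed percentages and exposure counts in this package. Base R's
#' `round()` rounds half to even, which changes several published-table
#' values (e.g. a raw exposure of 425681.25 must truncate to 425681 while
#' a percentage of 75.55 must print as 75.6).
#'
#' @param x numeric vector
#' @param digits decimal places to keep (default 0)
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  z <- x * 10^digits
  # tiny absolute epsilon guards against representation error just below .5
  floor(z + 0.5 + 1e-7) / 10^digits
}

#' Format a share as a percentage to one decimal
#'
#' @param num numerator count(s)
#' @param den denominator count
#' @return percentage(s) rounded half-up to 1 decimal; NA if `den` is 0
#' @export
pct <- function(num, den) {
  if (den == 0) return(rep(NA_real_, length(num)))
  round_half_up(100 * num / den, 1)
}

#' Normalize a drug name token
#'
#' Lowercases and trims whitespace. Idempotent; the result is the canonical
#' form used for KB keys, graph nodes and all name matching.
#'
#' @param x character vector of drug names
#' @return normalized character vector
#' @export
normalize_drug_name <- function(x) {
  trimws(tolower(as.character(x)))
}

# sample (n-1) or population (n) standard deviation
sd_by <- function(x, type = c("sample", "population")) {
  type <- match.arg(type)
  n <- length(x)
  if (n < 2) return(NA_real_)
  s <- stats::sd(x)
  if (type == "population") s <- s * sqrt((n - 1) / n)
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
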