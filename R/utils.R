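#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going up (0.5 -> 1), unlike
#' [base::round()] which rounds half to even. Used for all printed
#' percentages so that reported values match hand arithmetic.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return numeric vector of the same length.
#' @examples
#' round_half_up(0.5)        # 1
#' round_half_up(52.5641, 0) # 53
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Format a count as a percentage at the conventional precision
#'
#' Percentages at or above 10 are reported as integers, below 10 with one
#' decimal, both rounded half-up; this mirrors the mixed precision commonly
#' used when summarising category counts (e.g. 137/20050 -> 0.7,
#' 10869/20050 -> 54).
#'
#' @param count numeric numerator.
#' @param total numeric denominator (> 0).
#' @param digits optional fixed number of decimals; if `NULL` (default) the
#'   precision rule above is applied per value.
#' @return numeric vector of rounded percentages.
#' @export
percent_of <- function(count, total, digits = NULL) {
  stopifnot(is.numeric(count), is.numeric(total), all(total > 0))
  p <- 100 * count / total
  if (!is.null(digits)) return(round_half_up(p, digits))
  d <- ifelse(p >= 10, 0, 1)
  out <- numeric(length(p))
  for (i in seq_along(p)) out[i] <- round_half_up(p[i], d[i])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: stop() with sprintf formatting
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
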