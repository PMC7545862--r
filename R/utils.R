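#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves going away from zero, the
#' convention used for all printed percentages and summary statistics in this
#' package (base [round()] rounds halves to even, which does not reproduce
#' hand-rounded table arithmetic).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` decimals.
#' @examples
#' roundHalfUp(2.005, 2)   # 2.01, whereas round(2.005, 2) may give 2
#' @export
roundHalfUp <- function(x, digits = 2) {
  m <- 10^digits
  # nudge by one ulp so values that are exactly .5 after decimal scaling do
  # not fall on the wrong side through floating-point representation
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

## log(sum(exp(x))) along rows of a 3-column matrix, underflow-safe
.logSumExpRows <- function(m) {
  mx <- pmax(m[, 1L], m[, 2L], m[, 3L])
  mx + log(exp(m[, 1L] - mx) + exp(m[, 2L] - mx) + exp(m[, 3L] - mx))
}

.assertScalarNumber <- function(x, field, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop("invalid configuration: field '", field, "' must be a number in [",
         min, ", ", max, "]", call. = FALSE)
  }
  invisible(x)
}

## sample-SD with the n = 1 -> 0 convention used throughout
.sampleSD <- function(x) {
  if (length(x) < 2L) return(0)
  stats::sd(x)
}
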