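#' Logit and inverse-logit
#'
#' `logit()` maps a proportion to the log-odds scale; `expit()` is its inverse.
#' Both are vectorized.
#'
#' @param p proportion(s) in (0, 1).
#' @param x real number(s).
#' @return Numeric vector.
#' @examples
#' expit(logit(0.86))
#' @export
logit <- function(p) log(p / (1 - p))

#' @rdname logit
#' @export
expit <- function(x) 1 / (1 + exp(-x))

## Half-up rounding (round() in R rounds half to even). Used for display
## percentages so that e.g. 84.96 -> 85 and 14.09 -> 14.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dta <- function(msg, class) {
  stop(structure(
    class = c(class, "dta_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
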