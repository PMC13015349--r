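# internal helpers

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_field <- function(ok, field, what) {
  if (!ok) stopf("invalid configuration: field '%s' %s", field, what)
}

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (so 84.916 -> 84.9 and 38.55 -> 38.6), the convention used when
#' reporting clone percentages.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
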