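# Small numeric helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

silu <- function(x) x * sigmoid(x)

#' Round half away from zero
#'
#' Decimal rounding with ties going up (`0.05 -> 0.1`), matching how
#' measurement tables are conventionally printed. Base [round()] uses
#' banker's rounding, which would round `2.45` to `2.4`.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  # tiny nudge guards against binary representations just below .5
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name), call. = FALSE)
  }
  invisible(x)
}
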