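#' Round half away from zero
#'
#' Presentation rounding used in the metric tables: exact halves round up
#' (2.5 -> 2.50 at 2 digits becomes 2.5; 94.435 -> 94.44), unlike base
#' [round()], which rounds halves to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(94.435, 2) # 94.44
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # nudge by an ulp-scale epsilon so values printed as exact halves round up
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a child seed from a master seed, kept within 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483629L)
}

abort_param <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "distillecg_param_error")
}
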