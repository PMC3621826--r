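#' Power-transform a marker concentration
#'
#' Concentrations are transformed to a small positive power (default 1/10)
#' to produce approximate normality before entering the component models.
#' Strictly increasing on positives for exponents in (0, 1].
#'
#' @param value Non-negative concentration(s).
#' @param exponent Transform exponent, default 0.1.
#' @param analyte Optional analyte name used in the error message.
#' @return `value ^ exponent`, vectorized.
#' @export
transform_concentration <- function(value, exponent = 0.1, analyte = NULL) {
  if (any(is.na(value))) {
    stop("missing concentration", if (!is.null(analyte)) paste0(" for ", analyte))
  }
  if (any(value < 0)) {
    stop("negative concentration",
         if (!is.null(analyte)) paste0(" for ", analyte),
         ": concentrations must be >= 0")
  }
  value ^ exponent
}

# Half-away-from-zero rounding (not banker's); used once, after scaling.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}
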