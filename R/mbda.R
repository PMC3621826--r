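#' Predict the DAS28-CRP components from serum markers
#'
#' Each component (predicted TJC28, SJC28 and patient global) is a linear
#' model over power-transformed concentrations of its own analyte subset:
#' `intercept + sum(coef * conc^exponent)`.
#'
#' @param cohort Cohort data.frame or a single-record one-row data.frame.
#' @param coeffs `mbda_coefficients`.
#' @return data.frame with columns ptjc28, psjc28, ppga (one row per visit).
#' @export
predict_components <- function(cohort, coeffs) {
  stopifnot(inherits(coeffs, "mbda_coefficients"))
  out <- lapply(coeffs$components, function(m) {
    if (length(m$coefficients) == 0) {
      rep(m$intercept, nrow(cohort))
    } else {
      X <- marker_matrix(cohort, names(m$coefficients), coeffs$exponent)
      as.numeric(m$intercept + X %*% m$coefficients)
    }
  })
  data.frame(ptjc28 = out$ptjc28, psjc28 = out$psjc28, ppga = out$ppga)
}

#' Curds-and-Whey improvement of the joint-count predictions
#'
#' Applies the configured 2x2 shrinkage matrix to `(ptjc28, psjc28)` and
#' truncates negatives to zero (joint counts are non-negative, and the
#' square root taken downstream must be defined). Predicted PGA and CRP are
#' deliberately excluded from the shrinkage: including them impairs
#' performance.
#'
#' @param ptjc28,psjc28 Component predictions (vectorized).
#' @param coeffs `mbda_coefficients` carrying the shrinkage matrix.
#' @return data.frame with columns iptjc, isjc, both >= 0.
#' @export
curds_whey_improve <- function(ptjc28, psjc28, coeffs) {
  M <- coeffs$shrinkage
  iptjc <- pmax(0, M[1, 1] * ptjc28 + M[1, 2] * psjc28)
  isjc  <- pmax(0, M[2, 1] * ptjc28 + M[2, 2] * psjc28)
  data.frame(iptjc = iptjc, isjc = isjc)
}

#' Combine improved predictions with CRP and scale to the integer score
#'
#' `pre_scale = w1*sqrt(IPTJC) + w2*sqrt(ISJC) + w3*ln(CRP+1) + w4*PPGA +
#' c`, analogous to the DAS28-CRP, then
#' `score = clamp(round(pre_scale * scale + offset), bounds)` with
#' half-away-from-zero rounding applied once, after scaling.
#'
#' @param iptjc,isjc Improved joint-count predictions, >= 0.
#' @param crp_mg_l CRP in mg/L, >= 0.
#' @param ppga Predicted patient global assessment (0-10 scale).
#' @param coeffs `mbda_coefficients`.
#' @return data.frame (class `mbda_result`): ptjc-less result columns
#'   iptjc, isjc, pre_scale, score, category, crp_fraction (share of the
#'   score from the CRP term, offset included) and
#'   crp_fraction_nonconstant (share of the non-constant portion).
#' @export
combine_and_scale <- function(iptjc, isjc, crp_mg_l, ppga, coeffs) {
  if (any(crp_mg_l < 0)) stop("CRP must be non-negative")
  if (any(iptjc < 0 | isjc < 0)) stop("improved predictions must be >= 0")
  w <- coeffs$combination
  crp_term <- w["log_crp"] * log(crp_mg_l + 1)
  pre_scale <- w["sqrt_iptjc"] * sqrt(iptjc) + w["sqrt_isjc"] * sqrt(isjc) +
    crp_term + w["ppga"] * ppga + w["constant"]
  raw <- round_half_away(pre_scale * coeffs$scale + coeffs$offset)
  score <- as.integer(pmin(coeffs$bounds[2], pmax(coeffs$bounds[1], raw)))
  const_part <- w["constant"] * coeffs$scale + coeffs$offset
  res <- data.frame(
    iptjc = iptjc, isjc = isjc, pre_scale = as.numeric(pre_scale),
    score = score, category = as.character(mbda_category(score)),
    crp_fraction = as.numeric(crp_term * coeffs$scale / score),
    crp_fraction_nonconstant =
      as.numeric(crp_term * coeffs$scale / (score - const_part)),
    stringsAsFactors = FALSE
  )
  class(res) <- c("mbda_result", "data.frame")
  res
}

#' Score a cohort with the full MBDA pipeline
#'
#' Component prediction, Curds-and-Whey improvement, combination with CRP,
#' scaling and categorization, end to end. Deterministic: identical record
#' and coefficients give an identical result.
#'
#' @param cohort Cohort data.frame; must carry all panel analytes (no
#'   imputation is performed) and `crp`.
#' @param coeffs `mbda_coefficients`, default [default_coefficients()].
#' @return data.frame (class `mbda_result`) with patient_id, visit_id,
#'   ptjc28, psjc28, ppga, iptjc, isjc, pre_scale, score, category,
#'   crp_fraction, crp_fraction_nonconstant.
#' @export
mbda_score <- function(cohort, coeffs = default_coefficients()) {
  if (any(cohort$crp < 0)) stop("CRP must be non-negative")
  comp <- predict_components(cohort, coeffs)
  imp <- curds_whey_improve(comp$ptjc28, comp$psjc28, coeffs)
  res <- combine_and_scale(imp$iptjc, imp$isjc, cohort$crp, comp$ppga, coeffs)
  out <- cbind(
    data.frame(patient_id = cohort$patient_id, visit_id = cohort$visit_id,
               stringsAsFactors = FALSE),
    comp["ptjc28"], comp["psjc28"], ppga = comp$ppga, res)
  class(out) <- c("mbda_result", "data.frame")
  out
}

#' MBDA disease-activity category
#'
#' Remission `<= 25`; low `26-29`; moderate `30-44`; high `>= 45`.
#'
#' @param score Integer score(s) in 1-100.
#' @return Factor with levels remission/low/moderate/high.
#' @export
mbda_category <- function(score) {
  if (any(score < 1 | score > 100)) stop("MBDA score out of range [1, 100]")
  lv <- c("remission", "low", "moderate", "high")
  out <- ifelse(score <= 25, "remission",
         ifelse(score <= 29, "low",
         ifelse(score <= 44, "moderate", "high")))
  factor(out, levels = lv)
}

#' MBDA-scale equivalent of a DAS28-CRP value
#'
#' `round(das * 10.53 + 1)` with half-away-from-zero rounding, not clamped.
#' Used to derive the category cutoffs (2.3 -> 25, 2.7 -> 29, 4.1 -> 44).
#'
#' @param das_value DAS28-CRP value(s), >= 0.
#' @param scale,offset Scaling constants, defaults 10.53 and 1.
#' @return Integer value(s).
#' @export
mbda_equivalent_of_das <- function(das_value, scale = 10.53, offset = 1) {
  if (any(das_value < 0)) stop("DAS28-CRP value must be non-negative")
  as.integer(round_half_away(das_value * scale + offset))
}
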