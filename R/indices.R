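#' Four-variable DAS28-CRP
#'
#' `0.56*sqrt(TJC28) + 0.28*sqrt(SJC28) + 0.36*ln(CRP+1) + 0.014*PGA(0-100)
#' + 0.96`. The patient global assessment enters on the 0-100 mm VAS scale
#' (the 0.014 weight presumes millimetres); a 0-10 input is multiplied by
#' 10 at call time via `pga_scale`.
#'
#' @param tjc28,sjc28 Tender/swollen joint counts, 0-28.
#' @param crp_mg_l CRP in mg/L, >= 0.
#' @param pga Patient global assessment.
#' @param pga_scale Scale of `pga`: `"0-10"` (default, multiplied by 10) or
#'   `"0-100"`.
#' @param weights Coefficients `(sqrt_tjc, sqrt_sjc, log_crp, pga, constant)`.
#' @return DAS28-CRP value(s); all-zero input returns the constant, 0.96.
#' @export
das28_crp4 <- function(tjc28, sjc28, crp_mg_l, pga,
                       pga_scale = c("0-10", "0-100"),
                       weights = c(0.56, 0.28, 0.36, 0.014, 0.96)) {
  pga_scale <- match.arg(pga_scale)
  if (any(tjc28 < 0 | sjc28 < 0 | crp_mg_l < 0 | pga < 0, na.rm = TRUE)) {
    stop("DAS28-CRP inputs must be non-negative")
  }
  pga100 <- if (pga_scale == "0-10") pga * 10 else pga
  weights[1] * sqrt(tjc28) + weights[2] * sqrt(sjc28) +
    weights[3] * log(crp_mg_l + 1) + weights[4] * pga100 + weights[5]
}

#' Four-variable DAS28-ESR
#'
#' `0.56*sqrt(TJC28) + 0.28*sqrt(SJC28) + 0.70*ln(ESR) + 0.014*PGA(0-100)`.
#' ESR must be positive (the formula takes its logarithm).
#'
#' @inheritParams das28_crp4
#' @param esr_mm_h Erythrocyte sedimentation rate, mm/h, > 0.
#' @export
das28_esr4 <- function(tjc28, sjc28, esr_mm_h, pga,
                       pga_scale = c("0-10", "0-100"),
                       weights = c(0.56, 0.28, 0.70, 0.014)) {
  pga_scale <- match.arg(pga_scale)
  if (any(tjc28 < 0 | sjc28 < 0 | pga < 0, na.rm = TRUE)) {
    stop("DAS28-ESR inputs must be non-negative")
  }
  if (any(esr_mm_h <= 0, na.rm = TRUE)) stop("ESR must be > 0")
  pga100 <- if (pga_scale == "0-10") pga * 10 else pga
  weights[1] * sqrt(tjc28) + weights[2] * sqrt(sjc28) +
    weights[3] * log(esr_mm_h) + weights[4] * pga100
}

#' Clinical Disease Activity Index
#'
#' Plain sum of TJC28, SJC28, patient global and evaluator global (both
#' 0-10).
#' @param tjc28,sjc28 Joint counts 0-28.
#' @param pga_0_10,ega_0_10 Patient/evaluator global assessment, 0-10.
#' @export
cdai <- function(tjc28, sjc28, pga_0_10, ega_0_10) {
  if (any(c(tjc28, sjc28, pga_0_10, ega_0_10) < 0, na.rm = TRUE)) {
    stop("CDAI inputs must be non-negative")
  }
  tjc28 + sjc28 + pga_0_10 + ega_0_10
}

#' Simplified Disease Activity Index
#'
#' CDAI plus CRP in mg/dL (the `crp_mg_l` input is divided by 10).
#' @inheritParams cdai
#' @param crp_mg_l CRP in mg/L.
#' @export
sdai <- function(tjc28, sjc28, pga_0_10, ega_0_10, crp_mg_l) {
  if (any(crp_mg_l < 0, na.rm = TRUE)) stop("CRP must be non-negative")
  cdai(tjc28, sjc28, pga_0_10, ega_0_10) + crp_mg_l / 10
}

#' DAS28-CRP disease-activity category
#'
#' Remission `< 2.3`; low `2.3 <= value <= 2.7`; moderate `> 2.7 & <= 4.1`;
#' high `> 4.1`. The published table leaves 2.3 formally between the
#' remission and low bands; it is assigned to "low" here (the remission
#' inequality is strict).
#'
#' @param value DAS28-CRP value(s).
#' @return Factor with levels remission/low/moderate/high.
#' @export
das28_category <- function(value) {
  lv <- c("remission", "low", "moderate", "high")
  out <- ifelse(value < 2.3, "remission",
         ifelse(value <= 2.7, "low",
         ifelse(value <= 4.1, "moderate", "high")))
  factor(out, levels = lv)
}

#' Compute an index table over a cohort
#'
#' @param cohort Cohort data.frame (see [cohort]).
#' @param indices Subset of `c("DAS28CRP4","DAS28ESR4","CDAI","SDAI")`.
#' @return Long data.frame: patient_id, visit_id, index_id, value, category
#'   (category only for DAS28-CRP4).
#' @export
index_table <- function(cohort, indices = c("DAS28CRP4", "CDAI", "SDAI")) {
  ega <- if ("ega" %in% names(cohort)) cohort$ega else cohort$pga
  rows <- lapply(indices, function(id) {
    value <- switch(id,
      DAS28CRP4 = das28_crp4(cohort$tjc28, cohort$sjc28, cohort$crp, cohort$pga),
      DAS28ESR4 = das28_esr4(cohort$tjc28, cohort$sjc28, cohort$esr, cohort$pga),
      CDAI = cdai(cohort$tjc28, cohort$sjc28, cohort$pga, ega),
      SDAI = sdai(cohort$tjc28, cohort$sjc28, cohort$pga, ega, cohort$crp),
      stop("unknown index: ", id))
    data.frame(patient_id = cohort$patient_id, visit_id = cohort$visit_id,
               index_id = id, value = value,
               category = if (id == "DAS28CRP4")
                 as.character(das28_category(value)) else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
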