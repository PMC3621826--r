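#' Area under the ROC curve
#'
#' Mann-Whitney form: the probability that a random positive outscores a
#' random negative, ties counted one half. Invariant under strictly
#' increasing transforms of the scores.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 (or logical) class labels; both classes must be
#'   present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties as half-concordant
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-out cross-validated scores
#'
#' Each patient's score comes from a model trained on all other patients;
#' for multi-visit cohorts all visits of the held-out patient leave the
#' training set together (the cross-validation unit is the patient, not the
#' visit, to prevent within-patient leakage).
#'
#' @param cohort Cohort data.frame with a `patient_id` column.
#' @param trainer `function(train_cohort, test_cohort) -> numeric
#'   predictions for the test rows`.
#' @return Numeric vector aligned with `cohort` rows; folds where the
#'   trainer fails yield NA with a message.
#' @export
loocv_scores <- function(cohort, trainer) {
  ids <- unique(cohort$patient_id)
  if (length(ids) < 3) stop("need at least 3 patients")
  out <- rep(NA_real_, nrow(cohort))
  for (id in ids) {
    te <- cohort$patient_id == id
    pred <- tryCatch(trainer(cohort[!te, , drop = FALSE],
                             cohort[te, , drop = FALSE]),
                     error = function(e) {
                       message("LOOCV fold failed for patient ", id, ": ",
                               conditionMessage(e))
                       rep(NA_real_, sum(te))
                     })
    out[te] <- pred
  }
  out
}

#' Spearman correlation of paired within-patient changes
#'
#' @param delta_a,delta_b Paired change vectors (same patients, same
#'   time-point pairs), length >= 3.
#' @return Spearman rho.
#' @export
change_correlation <- function(delta_a, delta_b) {
  if (length(delta_a) != length(delta_b)) stop("deltas must be paired")
  ok <- stats::complete.cases(delta_a, delta_b)
  if (sum(ok) < 3) stop("need at least 3 paired changes")
  stats::cor(delta_a[ok], delta_b[ok], method = "spearman")
}

#' CRP share of the MBDA score
#'
#' Per-patient percentage of the score attributable to the CRP term
#' (`w3 * ln(CRP+1) * scale`). With `include_constant = TRUE` the
#' denominator is the full score; with FALSE it is the non-constant portion
#' (score minus the scaled constant and offset).
#'
#' @param results An `mbda_result` data.frame from [mbda_score()].
#' @param include_constant Denominator choice, see above.
#' @return List: mean, sd (percent), n_used.
#' @export
crp_contribution <- function(results, include_constant = TRUE) {
  if (!nrow(results)) stop("empty results")
  share <- if (include_constant) results$crp_fraction
           else results$crp_fraction_nonconstant
  ok <- is.finite(share)
  if (any(!ok)) warning(sum(!ok), " patient(s) excluded (zero denominator)")
  list(mean = 100 * mean(share[ok]), sd = 100 * stats::sd(share[ok]),
       n_used = sum(ok))
}

#' Performance report for scores against DAS28-CRP
#'
#' Pearson and Spearman correlation plus AUROC for low vs moderate/high
#' classification at a fixed DAS28-CRP cutoff (2.67) and at the study
#' median. Patients exactly at the median count as the low class
#' (`median_low = TRUE`, switchable).
#'
#' @param scores Numeric scores.
#' @param das DAS28-CRP values, same length.
#' @param fixed_threshold Fixed cutoff, default 2.67.
#' @param median_low At-median patients assigned to low when TRUE (default).
#' @return List (class `mbda_eval`): pearson_r, spearman_rho, auroc_fixed,
#'   auroc_median, thresholds, n.
#' @export
eval_report <- function(scores, das, fixed_threshold = 2.67,
                        median_low = TRUE) {
  stopifnot(length(scores) == length(das))
  med <- stats::median(das)
  lab_fixed <- as.integer(das > fixed_threshold)
  lab_med <- if (median_low) as.integer(das > med) else as.integer(das >= med)
  structure(list(
    pearson_r = stats::cor(scores, das),
    spearman_rho = stats::cor(scores, das, method = "spearman"),
    auroc_fixed = if (length(unique(lab_fixed)) == 2)
      auroc(scores, lab_fixed) else NA_real_,
    auroc_median = if (length(unique(lab_med)) == 2)
      auroc(scores, lab_med) else NA_real_,
    thresholds = c(fixed = fixed_threshold, median = med),
    n = length(scores)), class = "mbda_eval")
}
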