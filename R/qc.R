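#' Duplicate-well CV flag
#'
#' Samples are assayed in duplicate adjacent wells; a sample is flagged for
#' review when the signal coefficient of variation between its duplicates
#' exceeds 20%. The two-replicate CV uses the sample (n-1) standard
#' deviation: `cv = |a - b| / (sqrt(2) * mean(a, b))`. Flagging is
#' scale-invariant.
#'
#' @param signal_a,signal_b Raw duplicate signals, >= 0 (vectorized).
#' @param threshold CV flag threshold, default 0.20.
#' @return data.frame: cv, flagged, reason ("DUP_CV", "no signal" when both
#'   wells read zero, or NA when unflagged).
#' @export
duplicate_cv_flag <- function(signal_a, signal_b, threshold = 0.20) {
  if (any(signal_a < 0 | signal_b < 0)) stop("signals must be >= 0")
  m <- (signal_a + signal_b) / 2
  cv <- ifelse(m > 0, abs(signal_a - signal_b) / (sqrt(2) * m), NA_real_)
  no_signal <- m == 0
  flagged <- no_signal | (!is.na(cv) & cv > threshold)
  data.frame(cv = cv, flagged = flagged,
             reason = ifelse(no_signal, "no signal",
                      ifelse(flagged, "DUP_CV", NA_character_)),
             stringsAsFactors = FALSE)
}

#' Run-control acceptability
#'
#' A control reading is acceptable when it lies within +/- 3 SD of its
#' expected value (boundary inclusive).
#'
#' @param observed,expected Concentrations (vectorized).
#' @param sd Expected-scale standard deviation, > 0.
#' @param n_sd Width of the acceptability band, default 3.
#' @return Logical vector: TRUE iff in range.
#' @export
control_in_range <- function(observed, expected, sd, n_sd = 3) {
  if (any(sd <= 0)) stop("control SD must be > 0")
  abs(observed - expected) <= n_sd * sd
}

#' Plate-level review flag
#'
#' A plate is flagged for review when multiple (default >= 2) control
#' readings fail the acceptability range for any one analyte.
#'
#' @param controls data.frame with columns plate_id, analyte_id, observed,
#'   expected, sd.
#' @param min_failures Number of failing controls per analyte that
#'   triggers review, default 2.
#' @return data.frame: plate_id, analyte_id, n_fail, review.
#' @export
plate_review <- function(controls, min_failures = 2) {
  ok <- control_in_range(controls$observed, controls$expected, controls$sd)
  agg <- stats::aggregate(fail ~ plate_id + analyte_id,
                          data = cbind(controls, fail = !ok), FUN = sum)
  names(agg)[names(agg) == "fail"] <- "n_fail"
  agg$review <- agg$n_fail >= min_failures
  agg
}

#' Out-of-curve imputation
#'
#' Readings below the standard curve are set to the lowest concentration
#' observed for any in-curve sample in the study; readings above the curve
#' are set to the highest. In-curve values pass through unchanged, so
#' imputed values never leave the observed in-curve range.
#'
#' @param values Concentrations for one analyte in one study.
#' @param flag Character vector, same length: "in", "below" or "above".
#' @return data.frame: value (imputed), imputed_reason ("IMPUTED_LOW",
#'   "IMPUTED_HIGH" or NA).
#' @export
impute_out_of_curve <- function(values, flag) {
  stopifnot(length(values) == length(flag),
            all(flag %in% c("in", "below", "above")))
  in_curve <- values[flag == "in"]
  if (!any(flag != "in")) {
    return(data.frame(value = values, imputed_reason = NA_character_,
                      stringsAsFactors = FALSE))
  }
  if (length(in_curve) == 0) {
    stop("all values out-of-curve: no in-curve anchor for imputation")
  }
  out <- values
  out[flag == "below"] <- min(in_curve)
  out[flag == "above"] <- max(in_curve)
  data.frame(value = out,
             imputed_reason = ifelse(flag == "below", "IMPUTED_LOW",
                              ifelse(flag == "above", "IMPUTED_HIGH",
                                     NA_character_)),
             stringsAsFactors = FALSE)
}

#' QC report over well pairs and controls
#'
#' One row per flag, with reason codes DUP_CV, CONTROL_RANGE and
#' PLATE_REVIEW; suitable for writing to CSV.
#'
#' @param pairs Optional data.frame: sample_id, analyte_id, plate_id,
#'   signal_a, signal_b.
#' @param controls Optional data.frame: control_id, analyte_id, plate_id,
#'   observed, expected, sd.
#' @param min_failures Passed to [plate_review()].
#' @return data.frame: unit_id, analyte_id, plate_id, reason, detail.
#' @export
qc_report <- function(pairs = NULL, controls = NULL, min_failures = 2) {
  rows <- list()
  if (!is.null(pairs) && nrow(pairs)) {
    fl <- duplicate_cv_flag(pairs$signal_a, pairs$signal_b)
    sel <- which(fl$flagged)
    if (length(sel)) {
      rows[[length(rows) + 1]] <- data.frame(
        unit_id = as.character(pairs$sample_id[sel]),
        analyte_id = pairs$analyte_id[sel], plate_id = pairs$plate_id[sel],
        reason = "DUP_CV",
        detail = sprintf("cv=%.4f", fl$cv[sel]), stringsAsFactors = FALSE)
    }
  }
  if (!is.null(controls) && nrow(controls)) {
    ok <- control_in_range(controls$observed, controls$expected, controls$sd)
    sel <- which(!ok)
    if (length(sel)) {
      rows[[length(rows) + 1]] <- data.frame(
        unit_id = as.character(controls$control_id[sel]),
        analyte_id = controls$analyte_id[sel],
        plate_id = controls$plate_id[sel],
        reason = "CONTROL_RANGE",
        detail = sprintf("z=%.2f", (controls$observed[sel] -
                         controls$expected[sel]) / controls$sd[sel]),
        stringsAsFactors = FALSE)
    }
    pr <- plate_review(controls, min_failures)
    sel <- which(pr$review)
    if (length(sel)) {
      rows[[length(rows) + 1]] <- data.frame(
        unit_id = as.character(pr$plate_id[sel]),
        analyte_id = pr$analyte_id[sel], plate_id = pr$plate_id[sel],
        reason = "PLATE_REVIEW",
        detail = sprintf("n_fail=%d", pr$n_fail[sel]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(unit_id = character(), analyte_id = character(),
                      plate_id = character(), reason = character(),
                      detail = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
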