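#' @title Cohort tables
#' @description A cohort is a plain data.frame with one row per
#'   patient-visit. Clinical columns: `patient_id`, `visit_id`, `tjc28`,
#'   `sjc28` (integer 0-28), `pga` (0-10), `crp` (mg/L, >= 0), optionally
#'   `esr` (mm/h), `age`, `sex` ("F"/"M"), `rf_status`, `ccp_status`
#'   (logical), `therapy_*` and `comorbid_*` flag columns. Marker columns
#'   are named by analyte id (pg/mL; the CRP analyte is the `crp` column,
#'   mg/L). The PGA scale is recorded explicitly in the schema because
#'   source cohorts differ (0-10 VAS here; 0-100 mm rescaled on load).
#' @name cohort
NULL

cohort_required_columns <- function(markers = mbda_component_analytes()) {
  c("patient_id", "visit_id", "tjc28", "sjc28", "pga", "crp", markers)
}

# Row-level range/type validation shared by load_cohort and validate_cohort.
# Returns character vector of reasons, zero-length when the row is valid.
row_problems <- function(row, markers) {
  reasons <- character()
  num <- function(x) suppressWarnings(as.numeric(x))
  tjc <- num(row[["tjc28"]]); sjc <- num(row[["sjc28"]])
  pga <- num(row[["pga"]]);   crp <- num(row[["crp"]])
  if (is.na(tjc) || is.na(sjc) || is.na(pga) || is.na(crp)) {
    reasons <- c(reasons, "parse")
  } else {
    if (tjc < 0 || tjc > 28 || sjc < 0 || sjc > 28) reasons <- c(reasons, "range")
    if (pga < 0 || pga > 10) reasons <- c(reasons, "range")
    if (crp < 0) reasons <- c(reasons, "range")
  }
  for (m in markers) {
    v <- num(row[[m]])
    if (is.na(v)) reasons <- c(reasons, "parse")
    else if (v < 0) reasons <- c(reasons, "range")
  }
  unique(reasons)
}

#' Load a cohort CSV
#'
#' Reads a one-row-per-patient-visit CSV, checks the schema (required
#' columns) and row-level ranges (joint counts in 0-28, PGA in 0-10,
#' concentrations non-negative). Rows failing checks are dropped and
#' reported in the `"rejected"` attribute with row numbers and reasons.
#'
#' @param path CSV path with a header row.
#' @param markers Required marker columns; default the 11 component
#'   analytes (CRP is the clinical `crp` column).
#' @param pga_scale `"0-10"` (default) or `"0-100"`; the latter is divided
#'   by 10 on load so the in-memory scale is always 0-10.
#' @return A validated cohort data.frame with attribute `"rejected"`.
#' @export
load_cohort <- function(path, markers = mbda_component_analytes(),
                        pga_scale = c("0-10", "0-100")) {
  pga_scale <- match.arg(pga_scale)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- cohort_required_columns(markers)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("cohort schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (pga_scale == "0-100") df$pga <- df$pga / 10
  validate_cohort(df, markers = markers)
}

#' Validate a cohort data.frame
#'
#' @param df Cohort data.frame (see [cohort]).
#' @param markers Required marker columns.
#' @return `df` with invalid rows removed and a `"rejected"` attribute
#'   (data.frame: row, patient_id, reason).
#' @export
validate_cohort <- function(df, markers = mbda_component_analytes()) {
  need <- cohort_required_columns(markers)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("cohort schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  key <- paste(df$patient_id, df$visit_id, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate patient/visit identifiers")
  rejected <- data.frame(row = integer(), patient_id = character(),
                         reason = character(), stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    reasons <- row_problems(df[i, , drop = FALSE], markers)
    if (length(reasons)) {
      keep[i] <- FALSE
      rejected <- rbind(rejected, data.frame(
        row = i, patient_id = as.character(df$patient_id[i]),
        reason = paste(reasons, collapse = ";"), stringsAsFactors = FALSE))
    }
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write a cohort CSV
#'
#' Values round-trip bit-for-bit for finite decimals (written with 15
#' significant digits).
#'
#' @param cohort Cohort data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  attr(df, "rejected") <- NULL
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE,
                                                scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Matrix of power-transformed marker concentrations for the analytes a
# component model uses; errors name the first missing analyte.
marker_matrix <- function(cohort, analytes, exponent) {
  missing_cols <- setdiff(analytes, names(cohort))
  if (length(missing_cols)) {
    stop("scoring error: missing analyte '", missing_cols[1], "'")
  }
  X <- as.matrix(cohort[, analytes, drop = FALSE])
  storage.mode(X) <- "double"
  if (any(is.na(X))) {
    bad <- analytes[which(colSums(is.na(X)) > 0)[1]]
    stop("scoring error: missing analyte value for '", bad, "'")
  }
  for (a in analytes) X[, a] <- transform_concentration(X[, a], exponent, a)
  X
}
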