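#' Ratio of group medians
#'
#' `median(with) / median(without)`; 1.0 means the measure is unaffected by
#' the condition. Unit-invariant: rescaling both groups leaves the ratio
#' unchanged.
#'
#' @param values_with,values_without Measure values in patients with/without
#'   the condition; both nonempty.
#' @return The ratio, or NA (with a warning) when the denominator median is
#'   not positive.
#' @export
median_ratio <- function(values_with, values_without) {
  if (!length(values_with) || !length(values_without)) {
    stop("both groups must be nonempty")
  }
  den <- stats::median(values_without, na.rm = TRUE)
  if (!is.finite(den) || den <= 0) {
    warning("denominator median not positive; ratio is NA")
    return(NA_real_)
  }
  stats::median(values_with, na.rm = TRUE) / den
}

#' Age/sex-adjusted association of a measure with a condition
#'
#' Multiple linear regression `measure ~ condition + age + sex`; returns the
#' condition coefficient and its p-value. Sex is encoded as a single
#' indicator (female = 1).
#'
#' @param measure Numeric outcome.
#' @param condition Logical/0-1 comorbidity flag; both levels required.
#' @param age Years.
#' @param sex "F"/"M" character, factor, or 0/1 numeric.
#' @param log_transform Regress on `log(measure)` instead (default FALSE;
#'   the untransformed scale is the default, a log option is provided).
#' @return List: coefficient, p_value, n.
#' @export
adjusted_association <- function(measure, condition, age, sex,
                                 log_transform = FALSE) {
  condition <- as.integer(as.logical(condition))
  if (length(unique(condition)) < 2) stop("both condition levels required")
  if (length(measure) < 20) stop("need n >= 20")
  sex01 <- if (is.numeric(sex)) sex else as.integer(sex %in% c("F", "female"))
  y <- if (log_transform) log(measure) else measure
  df <- data.frame(y = y, condition = condition, age = age, sex = sex01)
  fit <- stats::lm(y ~ condition + age + sex, data = df)
  if (any(is.na(stats::coef(fit)))) stop("collinear design")
  sm <- summary(fit)$coefficients
  list(coefficient = sm["condition", "Estimate"],
       p_value = sm["condition", "Pr(>|t|)"], n = nrow(df))
}

#' Benjamini-Hochberg significance flags for a report family
#'
#' Step-up BH across the whole condition x measure family.
#'
#' @param p_values Numeric p-values (NA allowed, excluded).
#' @param q FDR level, default 0.05.
#' @return Logical vector of flags, aligned with `p_values`.
#' @export
family_adjust <- function(p_values, q = 0.05) {
  flags <- rep(NA, length(p_values))
  ok <- !is.na(p_values)
  # reject at adjusted p <= q: equivalent to the literal step-up rule
  flags[ok] <- stats::p.adjust(p_values[ok], method = "BH") <= q
  flags
}

#' Comorbidity confounding report
#'
#' For each comorbidity flag present in at least `prevalence_min` of the
#' cohort, compares each disease-activity measure between patients with and
#' without the condition: ratio of medians, age/sex-adjusted p-value, and
#' BH-adjusted significance across the full condition x measure family.
#'
#' @param cohort Cohort data.frame with `age`, `sex` and `comorbid_*`
#'   columns.
#' @param measures Named list of numeric vectors (e.g. crp, cdai,
#'   das28crp4, mbda), or character vector of cohort column names.
#' @param conditions Comorbidity column names; default every `comorbid_*`
#'   column.
#' @param prevalence_min Minimum prevalence to analyze, default 0.10.
#' @param q FDR level for the family flags, default 0.05.
#' @return data.frame: condition, n_with, fraction_with, measure,
#'   median_ratio, coefficient, p_value, bh_significant.
#' @export
comorbidity_report <- function(cohort, measures,
                               conditions = grep("^comorbid_", names(cohort),
                                                 value = TRUE),
                               prevalence_min = 0.10, q = 0.05) {
  if (is.character(measures)) {
    measures <- stats::setNames(lapply(measures, function(m) cohort[[m]]),
                                measures)
  }
  rows <- list()
  for (cond in conditions) {
    flag <- as.logical(cohort[[cond]])
    frac <- mean(flag)
    if (frac < prevalence_min) next
    for (mn in names(measures)) {
      v <- measures[[mn]]
      assoc <- adjusted_association(v, flag, cohort$age, cohort$sex)
      rows[[length(rows) + 1]] <- data.frame(
        condition = sub("^comorbid_", "", cond),
        n_with = sum(flag), fraction_with = frac, measure = mn,
        median_ratio = median_ratio(v[flag], v[!flag]),
        coefficient = assoc$coefficient, p_value = assoc$p_value,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(condition = character(), n_with = integer(),
                      fraction_with = numeric(), measure = character(),
                      median_ratio = numeric(), coefficient = numeric(),
                      p_value = numeric(), bh_significant = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$bh_significant <- family_adjust(out$p_value, q)
  out
}
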