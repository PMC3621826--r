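#' Default synthetic marker panel parameters
#'
#' Baseline medians (pg/mL), loadings on the latent disease-activity factor
#' and log-scale noise SDs for the 11 component analytes. Values are chosen
#' once to resemble typical serum immunoassay medians and the skewed,
#' moderately informative marginals an RA development cohort shows: acute
#' phase reactants (SAA, IL-6) load strongly with wide dynamic range;
#' adhesion/angiogenesis markers load moderately; leptin (adiposity-driven)
#' loads weakly; EGF loads negatively.
#'
#' @return data.frame: analyte_id, baseline, loading, sigma.
#' @export
default_marker_params <- function() {
  data.frame(
    analyte_id = c("TNFRI", "IL6", "VCAM1", "EGF", "VEGFA", "YKL40",
                   "MMP1", "MMP3", "SAA", "leptin", "resistin"),
    baseline = c(1200, 8, 6e5, 60, 250, 6e4, 6e3, 2.5e4, 2e6, 1e4, 6e3),
    loading = c(0.45, 0.90, 0.30, -0.25, 0.50, 0.60,
                0.50, 0.55, 1.00, 0.15, 0.40),
    sigma = c(0.35, 0.90, 0.30, 0.70, 0.60, 0.70,
              0.80, 0.90, 1.20, 0.80, 0.60),
    stringsAsFactors = FALSE
  )
}

#' Specify a synthetic RA cohort
#'
#' A single latent disease-activity factor drives every observable: marker
#' concentrations are log-normal around `baseline * exp(loading * latent)`;
#' joint counts are beta-binomial over 28 joints with logit-linked mean;
#' PGA is a logit-linked 0-10 value; CRP is log-linked. Enriched designs
#' ("similar numbers of patients in low, moderate and high disease
#' activity") use a latent mixture.
#'
#' @param n Number of patients (> 0).
#' @param visits Visits per patient, default 1.
#' @param latent List: either `mean`/`sd` for a single normal, or `means`,
#'   `sds`, `weights` for a mixture.
#' @param markers Marker parameter table, default
#'   [default_marker_params()].
#' @param tjc,sjc Lists `a`, `b`, `kappa`: beta-binomial over 28 joints
#'   with mean `plogis(a + b*latent)` and precision `kappa`.
#' @param pga List `a`, `b`, `sigma`: `10 * plogis(a + b*latent + noise)`.
#' @param crp List `log_baseline`, `loading`, `sigma`: log-normal CRP in
#'   mg/L.
#' @param female_frac Fraction female.
#' @param comorbidities Named list of lists `prev` (prevalence) and `shift`
#'   (additive latent shift for carriers; 0 = null effect).
#' @param study Study label stored in the cohort.
#' @return List of class `mbda_cohort_spec`.
#' @export
cohort_spec <- function(n, visits = 1,
                        latent = list(mean = 0, sd = 1),
                        markers = default_marker_params(),
                        tjc = list(a = -1.52, b = 1.0, kappa = 10),
                        sjc = list(a = -1.79, b = 1.0, kappa = 10),
                        pga = list(a = -0.45, b = 0.9, sigma = 0.5),
                        crp = list(log_baseline = log(4), loading = 0.9,
                                   sigma = 0.8),
                        female_frac = 0.76,
                        comorbidities = list(),
                        study = "synthetic") {
  if (n <= 0) stop("n must be > 0")
  stopifnot(all(markers$sigma >= 0), pga$sigma >= 0, crp$sigma >= 0)
  prevs <- vapply(comorbidities, function(x) x$prev, numeric(1))
  if (length(prevs) && any(prevs < 0 | prevs > 1)) {
    stop("prevalences must lie in [0, 1]")
  }
  structure(list(n = n, visits = visits, latent = latent, markers = markers,
                 tjc = tjc, sjc = sjc, pga = pga, crp = crp,
                 female_frac = female_frac, comorbidities = comorbidities,
                 study = study),
            class = "mbda_cohort_spec")
}

#' Preset cohort specifications
#'
#' `"studyI-like"`: an early feasibility study, n = 128, high disease
#' activity (median DAS28-CRP near 5.7, TJC ~12, SJC ~16, CRP ~14 mg/L,
#' 82% female). `"training-like"`: an enrichment design, n = 249, latent
#' three-component mixture giving similar numbers in low, moderate and high
#' activity with a wide DAS28-CRP spread. `"inform512-like"`: a
#' representative registry sample, n = 512, moderate activity (median
#' DAS28-CRP near 3.3) with null-effect comorbidity flags at registry
#' prevalences (hypertension 0.44, osteoarthritis 0.34, fracture 0.26,
#' degenerative joint disease 0.22, diabetes 0.14, asthma 0.10).
#'
#' @param name Preset name.
#' @param n Optional override of the preset's sample size.
#' @return `mbda_cohort_spec`.
#' @export
preset_spec <- function(name = c("studyI-like", "training-like",
                                 "inform512-like"), n = NULL) {
  name <- match.arg(name)
  spec <- switch(name,
    "studyI-like" = cohort_spec(
      n = 128, latent = list(mean = 0, sd = 1),
      tjc = list(a = -0.29, b = 0.9, kappa = 12),
      sjc = list(a = 0.29, b = 0.9, kappa = 12),
      pga = list(a = 0, b = 0.8, sigma = 0.5),
      crp = list(log_baseline = log(14), loading = 0.8, sigma = 0.7),
      female_frac = 0.82, study = "studyI-like"),
    "training-like" = cohort_spec(
      n = 249,
      latent = list(means = c(-1.3, 0, 1.3), sds = c(0.55, 0.55, 0.55),
                    weights = c(1, 1, 1) / 3),
      tjc = list(a = -1.52, b = 1.0, kappa = 10),
      sjc = list(a = -1.79, b = 1.0, kappa = 10),
      pga = list(a = -0.45, b = 0.9, sigma = 0.5),
      crp = list(log_baseline = log(3.8), loading = 0.9, sigma = 0.8),
      female_frac = 0.75, study = "training-like"),
    "inform512-like" = cohort_spec(
      n = 512, latent = list(mean = 0, sd = 0.8),
      tjc = list(a = -2.2, b = 1.1, kappa = 8),
      sjc = list(a = -2.2, b = 1.1, kappa = 8),
      pga = list(a = -0.6, b = 0.9, sigma = 0.5),
      crp = list(log_baseline = log(4.3), loading = 0.9, sigma = 0.8),
      female_frac = 0.76,
      comorbidities = list(
        hypertension = list(prev = 0.44, shift = 0),
        osteoarthritis = list(prev = 0.34, shift = 0),
        osteoporotic_fracture = list(prev = 0.26, shift = 0),
        degenerative_joint_disease = list(prev = 0.22, shift = 0),
        diabetes = list(prev = 0.14, shift = 0),
        asthma = list(prev = 0.10, shift = 0)),
      study = "inform512-like"))
  if (!is.null(n)) spec$n <- n
  spec
}

# Beta-binomial draw over `size` trials with mean mu and precision kappa.
rbetabinom <- function(n, size, mu, kappa) {
  mu <- pmin(1 - 1e-9, pmax(1e-9, mu))
  p <- stats::rbeta(n, mu * kappa, (1 - mu) * kappa)
  stats::rbinom(n, size, p)
}

#' Generate a synthetic cohort
#'
#' Deterministic given `seed`. DAS28-CRP is computed from the generated
#' clinical components, not drawn directly, so the composite inherits the
#' latent structure the way a real cohort would.
#'
#' @param spec `mbda_cohort_spec`.
#' @param seed Integer seed.
#' @return Validated cohort data.frame with a `latent` column retained for
#'   diagnostics and a `das28crp4` convenience column.
#' @export
generate_cohort <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "mbda_cohort_spec"))
  set.seed(seed)
  n_rows <- spec$n * spec$visits
  lat <- spec$latent
  patient <- rep(seq_len(spec$n), each = spec$visits)
  base_theta <- if (!is.null(lat$means)) {
    comp <- sample(seq_along(lat$means), spec$n, replace = TRUE,
                   prob = lat$weights)
    stats::rnorm(spec$n, lat$means[comp], lat$sds[comp])
  } else {
    stats::rnorm(spec$n, lat$mean, lat$sd)
  }
  cmb <- spec$comorbidities
  com_flags <- lapply(cmb, function(cc) stats::runif(spec$n) < cc$prev)
  shift <- rep(0, spec$n)
  for (i in seq_along(cmb)) shift <- shift + cmb[[i]]$shift * com_flags[[i]]
  base_theta <- base_theta + shift
  # small within-patient drift across visits
  theta <- base_theta[patient] +
    if (spec$visits > 1) stats::rnorm(n_rows, 0, 0.25) else 0
  mk <- spec$markers
  markers <- vapply(seq_len(nrow(mk)), function(i) {
    mk$baseline[i] * exp(mk$loading[i] * theta +
                           stats::rnorm(n_rows, 0, mk$sigma[i]))
  }, numeric(n_rows))
  colnames(markers) <- mk$analyte_id
  tjc <- rbetabinom(n_rows, 28, stats::plogis(spec$tjc$a + spec$tjc$b * theta),
                    spec$tjc$kappa)
  sjc <- rbetabinom(n_rows, 28, stats::plogis(spec$sjc$a + spec$sjc$b * theta),
                    spec$sjc$kappa)
  pga <- 10 * stats::plogis(spec$pga$a + spec$pga$b * theta +
                              stats::rnorm(n_rows, 0, spec$pga$sigma))
  crp <- exp(spec$crp$log_baseline + spec$crp$loading * theta +
               stats::rnorm(n_rows, 0, spec$crp$sigma))
  age_p <- pmax(18, round(stats::rnorm(spec$n, 59, 13)))
  sex_p <- ifelse(stats::runif(spec$n) < spec$female_frac, "F", "M")
  df <- data.frame(
    patient_id = sprintf("P%04d", patient),
    visit_id = sprintf("V%d", rep(seq_len(spec$visits), spec$n)),
    tjc28 = tjc, sjc28 = sjc, pga = pga, crp = crp,
    esr = pmax(1, crp * 2 + stats::rnorm(n_rows, 0, 5)),
    age = age_p[patient], sex = sex_p[patient],
    stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(markers))
  for (i in seq_along(cmb)) {
    df[[paste0("comorbid_", names(cmb)[i])]] <- com_flags[[i]][patient]
  }
  df$latent <- theta
  df$das28crp4 <- das28_crp4(df$tjc28, df$sjc28, df$crp, df$pga)
  out <- validate_cohort(df)
  attr(out, "study") <- spec$study
  out
}

#' Inject out-of-curve flags into a cohort's marker readings
#'
#' Marks randomly chosen readings as below/above the standard curve, the
#' fixture the QC imputation rule consumes. Deterministic given `seed`.
#'
#' @param cohort Cohort data.frame.
#' @param analytes Marker columns to flag.
#' @param below_rate,above_rate Per-reading flag probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @return Long data.frame: row, analyte_id, value, flag
#'   ("in"/"below"/"above").
#' @export
inject_out_of_curve <- function(cohort, analytes = mbda_component_analytes(),
                                below_rate = 0.02, above_rate = 0.02,
                                seed = 1) {
  if (below_rate < 0 || below_rate > 1 || above_rate < 0 || above_rate > 1) {
    stop("rates must lie in [0, 1]")
  }
  set.seed(seed)
  rows <- lapply(analytes, function(a) {
    v <- cohort[[a]]
    u <- stats::runif(length(v))
    flag <- ifelse(u < below_rate, "below",
            ifelse(u < below_rate + above_rate, "above", "in"))
    data.frame(row = seq_along(v), analyte_id = a, value = v, flag = flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate duplicate-well signal pairs from a cohort
#'
#' Each sample x analyte reading becomes two adjacent-well signals with a
#' target duplicate CV: both wells are the concentration times independent
#' log-normal noise with `sd = cv`. `cv = 0` gives identical wells.
#'
#' @param cohort Cohort data.frame.
#' @param analytes Marker columns.
#' @param cv Target duplicate coefficient of variation (>= 0).
#' @param plate_size Samples per plate for plate_id assignment.
#' @param seed Integer seed.
#' @return data.frame: sample_id, analyte_id, plate_id, signal_a, signal_b.
#' @export
inject_duplicates <- function(cohort, analytes = mbda_component_analytes(),
                              cv = 0.05, plate_size = 40, seed = 1) {
  if (cv < 0) stop("cv must be >= 0")
  set.seed(seed)
  n <- nrow(cohort)
  plate <- sprintf("PL%03d", (seq_len(n) - 1) %/% plate_size + 1)
  rows <- lapply(analytes, function(a) {
    conc <- cohort[[a]]
    noise <- function() if (cv == 0) rep(1, n) else
      exp(stats::rnorm(n, -cv^2 / 2, cv))
    data.frame(sample_id = paste(cohort$patient_id, cohort$visit_id, sep = ":"),
               analyte_id = a, plate_id = plate,
               signal_a = conc * noise(), signal_b = conc * noise(),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
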