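# Independent oracles, kept deliberately naive.

# Brute-force Benjamini-Hochberg step-up: reject H_(1..k*) where k* is the
# largest k with p_(k) <= k/m * q. Returns logical flags in input order.
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ks <- which(p[o] <= seq_len(m) / m * q)
  flags <- rep(FALSE, m)
  if (length(ks)) flags[o[seq_len(max(ks))]] <- TRUE
  flags
}

# Brute-force AUROC: enumerate all positive-negative pairs, ties count 1/2.
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Two-point sample-sd duplicate CV, written out longhand.
cv_oracle <- function(a, b) {
  stats::sd(c(a, b)) / mean(c(a, b))
}

# Power-transformed marker matrix over the component panel (test-local
# re-derivation; independent of the package's internal builder).
marker_matrix_for_test <- function(cohort, exponent = 0.1) {
  X <- as.matrix(cohort[, mbda_component_analytes()])
  storage.mode(X) <- "double"
  X ^ exponent
}

# Minimal valid coefficient set for unit tests: one analyte per component,
# identity shrinkage, DAS28-CRP-analogous combination.
make_test_coeffs <- function(shrinkage = diag(2),
                             components = list(
                               ptjc28 = list(intercept = 1,
                                             coefficients = c(IL6 = 2)),
                               psjc28 = list(intercept = 0.5,
                                             coefficients = c(MMP3 = 1)),
                               ppga = list(intercept = 2,
                                           coefficients = c(SAA = 0.5)))) {
  algorithm_coefficients(
    components = components, shrinkage = shrinkage,
    combination = c(sqrt_iptjc = 0.56, sqrt_isjc = 0.28, log_crp = 0.36,
                    ppga = 0.14, constant = 0.96))
}

# Tiny fully-populated cohort for scoring tests.
make_toy_cohort <- function(n = 3, seed = 42) {
  set.seed(seed)
  df <- data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    visit_id = "V1",
    tjc28 = sample(0:28, n, replace = TRUE),
    sjc28 = sample(0:28, n, replace = TRUE),
    pga = round(runif(n, 0, 10), 2),
    crp = round(exp(rnorm(n, log(5), 1)), 3),
    age = sample(30:80, n, replace = TRUE),
    sex = sample(c("F", "M"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  for (a in mbda_component_analytes()) {
    df[[a]] <- round(exp(rnorm(n, log(1000), 1)), 3)
  }
  df
}

# Write a cohort data.frame to a temp CSV and return the path.
toy_cohort_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
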