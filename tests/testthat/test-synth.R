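test_that("generation is deterministic given the seed", {
  spec <- preset_spec("training-like", n = 50)
  c1 <- generate_cohort(spec, seed = 7)
  c2 <- generate_cohort(spec, seed = 7)
  expect_identical(c1, c2)
  c3 <- generate_cohort(spec, seed = 8)
  expect_false(identical(c1$IL6, c3$IL6))
})

test_that("generated cohorts pass core schema validation", {
  for (preset in c("studyI-like", "training-like", "inform512-like")) {
    cohort <- generate_cohort(preset_spec(preset, n = 60), seed = 2)
    expect_equal(nrow(attr(cohort, "rejected")), 0)
    expect_true(all(cohort$tjc28 >= 0 & cohort$tjc28 <= 28))
    expect_true(all(cohort$pga >= 0 & cohort$pga <= 10))
    expect_true(all(as.matrix(cohort[, mbda_component_analytes()]) >= 0))
  }
})

test_that("zero loadings sever the marker-DAS link", {
  spec <- preset_spec("studyI-like", n = 1000)
  spec$markers$loading <- 0
  cohort <- generate_cohort(spec, seed = 5)
  for (a in mbda_component_analytes()) {
    expect_lt(abs(cor(log(cohort[[a]]), cohort$das28crp4)), 0.1)
  }
})

test_that("studyI-like preset lands in the intended activity range", {
  cohort <- generate_cohort(preset_spec("studyI-like"), seed = 101)
  med <- median(cohort$das28crp4)
  expect_gt(med, 4.7)
  expect_lt(med, 6.5)
})

test_that("increasing a loading increases the marker-DAS correlation", {
  rs <- vapply(c(0.1, 0.5, 1.0), function(lo) {
    spec <- preset_spec("studyI-like", n = 600)
    spec$markers$loading[spec$markers$analyte_id == "YKL40"] <- lo
    cohort <- generate_cohort(spec, seed = 9)
    cor(log(cohort$YKL40), cohort$das28crp4)
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
})

test_that("comorbidity flags appear at the specified prevalences", {
  cohort <- generate_cohort(preset_spec("inform512-like", n = 1000), seed = 12)
  # binomial 99.9% band at n = 1000 (absolute)
  expect_lt(abs(mean(cohort$comorbid_hypertension) - 0.44), 0.06)
  expect_lt(abs(mean(cohort$comorbid_asthma) - 0.10), 0.04)
})

test_that("inject_out_of_curve flags at the stated rates", {
  cohort <- generate_cohort(preset_spec("training-like", n = 100), seed = 3)
  none <- inject_out_of_curve(cohort, below_rate = 0, above_rate = 0, seed = 1)
  expect_true(all(none$flag == "in"))
  some <- inject_out_of_curve(cohort, analytes = mbda_component_analytes(),
                              below_rate = 0.1, above_rate = 0, seed = 1)
  frac <- mean(some$flag == "below")   # 1100 readings, binomial band
  expect_lt(abs(frac - 0.1), 0.03)
  expect_error(inject_out_of_curve(cohort, below_rate = 1.5), "\\[0, 1\\]")
})

test_that("inject_duplicates produces pairs with the target CV", {
  cohort <- generate_cohort(preset_spec("training-like", n = 80), seed = 4)
  exact <- inject_duplicates(cohort, cv = 0, seed = 1)
  expect_equal(exact$signal_a, exact$signal_b)
  noisy <- inject_duplicates(cohort, cv = 0.10, seed = 1)
  cvs <- duplicate_cv_flag(noisy$signal_a, noisy$signal_b)$cv
  # a two-point sd underestimates sigma by c4 = sqrt(2/pi) on average
  expect_lt(abs(mean(cvs, na.rm = TRUE) - 0.10 * sqrt(2 / pi)), 0.01)
  expect_error(inject_duplicates(cohort, cv = -0.1), ">= 0")
})

test_that("multi-visit specs produce the requested layout", {
  spec <- preset_spec("training-like", n = 20)
  spec$visits <- 3
  cohort <- generate_cohort(spec, seed = 6)
  expect_equal(nrow(cohort), 60)
  expect_equal(length(unique(cohort$patient_id)), 20)
  expect_equal(unname(table(cohort$visit_id)), rep(20L, 3),
               ignore_attr = TRUE)
})
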