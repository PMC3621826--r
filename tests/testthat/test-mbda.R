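test_that("predict_components evaluates the configured linear models", {
  # degenerate config: zero coefficients leave only intercepts
  cf0 <- make_test_coeffs(components = list(
    ptjc28 = list(intercept = 3, coefficients = c(IL6 = 0)),
    psjc28 = list(intercept = 3, coefficients = c(MMP3 = 0)),
    ppga = list(intercept = 3, coefficients = c(SAA = 0))))
  cohort <- make_toy_cohort(2)
  cmp <- predict_components(cohort, cf0)
  expect_equal(unlist(cmp[1, ]), c(ptjc28 = 3, psjc28 = 3, ppga = 3))

  # one-marker model w*x^0.1 + b at x = 1024: 2*2 + 1 = 5
  cf1 <- make_test_coeffs()
  cohort$IL6 <- 1024
  expect_equal(predict_components(cohort, cf1)$ptjc28, rep(5, 2))

  # hand arithmetic across all three components
  cohort$MMP3 <- 59049  # 3^10
  cohort$SAA <- 1
  cmp <- predict_components(cohort, cf1)
  expect_equal(cmp$psjc28, rep(0.5 + 3, 2))
  expect_equal(cmp$ppga, rep(2 + 0.5, 2))

  # missing analyte errors name the analyte
  expect_error(predict_components(cohort[, setdiff(names(cohort), "IL6")], cf1),
               "IL6")
})

test_that("curds_whey_improve applies the shrinkage matrix and truncates at 0", {
  cf_id <- make_test_coeffs(shrinkage = diag(2))
  out <- curds_whey_improve(c(3, -2), c(4, 1), cf_id)
  expect_equal(out$iptjc, c(3, 0))  # negative input truncated
  expect_equal(out$isjc, c(4, 1))

  cf_m <- make_test_coeffs(shrinkage = matrix(c(0.2, 0.2, 0.8, 0.8), 2))
  out <- curds_whey_improve(10, 5, cf_m)  # [[0.2, 0.8], [0.2, 0.8]] %*% (10, 5)
  expect_equal(out$iptjc, 6.0)
  expect_equal(out$isjc, 6.0)

  neg <- make_test_coeffs(shrinkage = matrix(c(-1, 0, 0, 1), 2))
  expect_equal(curds_whey_improve(5, 2, neg)$iptjc, 0)
})

test_that("combine_and_scale reproduces the DAS-analogous arithmetic", {
  cf <- make_test_coeffs()
  res <- combine_and_scale(0, 0, 0, 0, cf)
  expect_equal(res$pre_scale, 0.96)
  expect_equal(res$score, 11L)  # round(0.96 * 10.53 + 1)
  expect_equal(res$crp_fraction, 0)

  # upper clamp: pre_scale >= 9.41 implies raw > 100
  big <- combine_and_scale(400, 400, 1e6, 10, cf)
  expect_equal(big$score, 100L)
  expect_error(combine_and_scale(1, 1, -2, 1, cf), "non-negative")
})

test_that("mbda_category and mbda_equivalent_of_das pin the published cutoffs", {
  expect_equal(mbda_equivalent_of_das(2.3), 25L)
  expect_equal(mbda_equivalent_of_das(2.7), 29L)
  expect_equal(mbda_equivalent_of_das(4.1), 44L)
  expect_equal(as.character(mbda_category(c(25, 26, 29, 30, 44, 45))),
               c("remission", "low", "low", "moderate", "moderate", "high"))
  expect_error(mbda_category(0), "range")
  expect_error(mbda_category(101), "range")
})

test_that("category maps agree away from boundaries", {
  cutoffs <- c(2.3, 2.7, 4.1)
  set.seed(11)
  d <- runif(400, 0, 8)
  d <- d[vapply(d, function(x) all(abs(x - cutoffs) > 0.05), logical(1))]
  score <- pmin(100L, pmax(1L, mbda_equivalent_of_das(d)))
  expect_equal(as.character(mbda_category(score)),
               as.character(das28_category(d)))
})

test_that("mbda_score is deterministic and monotone in CRP", {
  cohort <- make_toy_cohort(5)
  cf <- default_coefficients()
  r1 <- mbda_score(cohort, cf)
  r2 <- mbda_score(cohort, cf)
  expect_identical(r1, r2)
  expect_true(all(r1$score == as.integer(r1$score)))
  expect_true(all(r1$score >= 1 & r1$score <= 100))
  expect_true(all(r1$iptjc >= 0 & r1$isjc >= 0))

  up <- cohort
  up$crp <- cohort$crp * 10
  expect_true(all(mbda_score(up, cf)$score >= r1$score))
})

test_that("shipped default coefficients score a synthetic registry cohort sensibly", {
  cohort <- generate_cohort(preset_spec("inform512-like", n = 150), seed = 3)
  res <- mbda_score(cohort)
  expect_true(all(res$score >= 1 & res$score <= 100))
  # the score must track the composite it was built to mirror
  expect_gt(cor(res$score, cohort$das28crp4), 0.6)
})
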