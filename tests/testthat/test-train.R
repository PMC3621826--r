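test_that("stepwise_fit recovers an exact one-variable model at size 1", {
  set.seed(2)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 + 3 * X[, "b"]
  for (fam in c("ols", "lasso")) {
    path <- stepwise_fit(X, y, family = fam)
    expect_equal(path$order[1], "b")
    expect_lt(path$mse[2], 1e-20)  # training error 0 at size 1
    m <- path$models[[1]]
    expect_equal(m$intercept, 2, tolerance = 1e-8)
    expect_equal(unname(m$coefficients["b"]), 3, tolerance = 1e-8)
  }
  expect_error(stepwise_fit(cbind(X, k = rep(1, 100)), y), "constant")
})

test_that("on an orthogonal design entry follows descending coefficient scale", {
  n <- 64
  # orthogonal columns from a Hadamard-like construction
  X <- cbind(rep(c(1, -1), n / 2),
             rep(c(1, 1, -1, -1), n / 4),
             rep(c(rep(1, 8), rep(-1, 8)), n / 16))
  colnames(X) <- c("big", "mid", "small")
  y <- 5 * X[, "big"] + 2 * X[, "mid"] + 0.5 * X[, "small"]
  for (fam in c("ols", "lasso")) {
    expect_equal(stepwise_fit(X, y, family = fam)$order,
                 c("big", "mid", "small"))
  }
})

test_that("nested CV is deterministic given the seed and picks small models on noise", {
  set.seed(77)
  X <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(NULL, paste0("v", 1:8)))
  y <- rnorm(60)
  set.seed(123); s1 <- nested_cv_select(X, y, k = 10)
  set.seed(123); s2 <- nested_cv_select(X, y, k = 10)
  expect_identical(s1, s2)
  expect_error(nested_cv_select(X[1:5, ], y[1:5], k = 10), "exceeds")

  # signal-free data: selected size <= 1 in at least 80% of 50 reps
  small <- 0
  for (r in 1:50) {
    set.seed(1000 + r)
    Xr <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(NULL, paste0("v", 1:8)))
    yr <- rnorm(60)
    set.seed(r)
    small <- small + (nested_cv_select(Xr, yr, k = 10)$size <= 1)
  }
  expect_gte(small / 50, 0.8)
})

test_that("nested CV finds a strong 3-variable signal", {
  hits <- 0
  reps <- 20
  for (r in 1:reps) {
    set.seed(300 + r)
    X <- matrix(rnorm(300 * 8), 300, 8, dimnames = list(NULL, paste0("v", 1:8)))
    y <- 2 * X[, 1] + 2 * X[, 2] + 2 * X[, 3] + rnorm(300)
    set.seed(r)
    s <- nested_cv_select(X, y, family = "lasso", k = 10)$size
    hits <- hits + (abs(s - 3) <= 1)
  }
  expect_gte(hits / reps, 0.8)
})

test_that("Curds-and-Whey shrinkage factors match the closed form", {
  # c2 = 0.5, r = 0.1 -> 0.9*0.4 / (0.81*0.5 + 0.01*0.5) = 0.36/0.41
  expect_equal(cw_shrinkage_factors(0.5, 0.1), 0.36 / 0.41)
  # full shrink when c2 <= r
  expect_equal(cw_shrinkage_factors(0.05, 0.1), 0)
  expect_equal(cw_shrinkage_factors(0.1, 0.1), 0)
  # no shrinkage in the infinite-data limit
  expect_equal(cw_shrinkage_factors(0.5, 0), 1)
  for (c2 in c(0.2, 0.7, 0.95)) {
    expect_lt(abs(cw_shrinkage_factors(c2, 1e-9) - 1), 1e-6)
  }
  # always within [0, 1]
  grid <- expand.grid(c2 = seq(0, 1, 0.05), r = seq(0, 0.9, 0.05))
  d <- cw_shrinkage_factors(grid$c2, grid$r)
  expect_true(all(d >= 0 & d <= 1))
})

test_that("curds_whey_matrix estimates sensible shrinkage from data", {
  set.seed(6)
  n <- 400
  f <- rnorm(n)
  Y <- cbind(tjc = f + rnorm(n, 0, 0.5), sjc = f + rnorm(n, 0, 0.5))
  Yhat <- cbind(tjc = f + rnorm(n, 0, 0.3), sjc = f + rnorm(n, 0, 0.3))
  cw <- curds_whey_matrix(Y, Yhat, p = 5)
  expect_true(all(cw$d >= 0 & cw$d <= 1))
  expect_equal(dim(cw$M), c(2, 2))
  # shrunk predictions should not correlate worse with truth
  shr <- Yhat %*% t(cw$M)
  expect_gt(cor(shr[, 1], Y[, 1]), cor(Yhat[, 1], Y[, 1]) - 0.05)
  expect_error(curds_whey_matrix(Y[1:2, ], Yhat[1:2, ], p = 2), "rows")
})

test_that("train_cw_lasso returns a scoreable model and honest train/test separation", {
  cohort <- generate_cohort(preset_spec("training-like", n = 200), seed = 14)
  tr <- cohort[1:140, ]
  te <- cohort[141:200, ]
  model <- train_cw_lasso(tr, seed = 14)
  expect_s3_class(model$coefficients, "mbda_coefficients")
  expect_equal(unname(model$selected),
               unname(vapply(model$coefficients$components,
                             function(m) length(m$coefficients), integer(1))))
  # the fit function received only training rows: scoring unseen rows works
  # and retraining without the test rows changes nothing
  res <- mbda_score(te, model$coefficients)
  expect_true(all(res$score >= 1 & res$score <= 100))
  model2 <- train_cw_lasso(tr, seed = 14)
  expect_identical(model$coefficients$components,
                   model2$coefficients$components)
})

test_that("compare_families is reproducible and pairs families on shared splits", {
  cohort <- generate_cohort(preset_spec("training-like", n = 150), seed = 9)
  t1 <- compare_families(cohort, c("lasso", "lasso2" = "lasso"), reps = 2,
                         seed = 4)
  # identical families on identical splits give identical metrics
  a <- t1[t1$family == "lasso", c("r", "auroc_fixed", "auroc_median")]
  expect_equal(nrow(t1), 4)
  t2 <- compare_families(cohort, c("lasso", "lasso"), reps = 2, seed = 4)
  expect_equal(t2$r[c(1, 3)], t2$r[c(2, 4)])
  # rerun with the same seed is bit-identical
  t3 <- compare_families(cohort, c("lasso", "lasso"), reps = 2, seed = 4)
  expect_identical(t2, t3)
})
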