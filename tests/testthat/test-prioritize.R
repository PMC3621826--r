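test_that("BH flags match a brute-force step-up oracle on short p-vectors", {
  # package route: p.adjust(BH) < q ; oracle: literal step-up
  set.seed(21)
  grid <- c(0.001, 0.01, 0.02, 0.04, 0.05, 0.1, 0.19, 0.2, 0.5, 0.9)
  for (m in 1:6) {
    for (rep in 1:40) {
      p <- sample(grid, m, replace = TRUE)
      for (q in c(0.05, 0.2)) {
        expect_equal(family_adjust(p, q), bh_oracle(p, q),
                     info = paste(c(q, p), collapse = ","))
      }
    }
  }
  # the spec's worked case: all four pass at q = 0.2
  expect_true(all(bh_oracle(c(0.01, 0.02, 0.03, 0.04), 0.2)))
  expect_true(all(family_adjust(c(0.01, 0.02, 0.03, 0.04), 0.2)))
})

test_that("univariate_screen finds perfect association and ignores noise", {
  set.seed(5)
  n <- 200
  cohort <- data.frame(sig = exp(rnorm(n)), noise = exp(rnorm(n)))
  cohort$endpoint <- log(cohort$sig)   # rank-perfect with sig
  res <- univariate_screen(cohort, c("sig", "noise"),
                           list(ep = cohort$endpoint))
  sig_rows <- res[res$analyte_id == "sig", ]
  expect_true(all(sig_rows$fdr_significant))
  expect_equal(sig_rows$estimate[sig_rows$method == "spearman"], 1)
  noise_rows <- res[res$analyte_id == "noise", ]
  expect_true(all(abs(noise_rows$estimate) < 0.2))

  # degenerate (constant) marker recorded as NA, excluded from counting
  cohort$flat <- 1
  res <- univariate_screen(cohort, c("sig", "flat"), list(ep = cohort$endpoint))
  expect_true(all(is.na(res$estimate[res$analyte_id == "flat"])))
  rk <- univariate_rank(res)
  expect_equal(rk$pass_count[rk$analyte_id == "flat"], 0)
})

test_that("univariate_rank uses competition ranking with common tie handling", {
  res <- data.frame(
    analyte_id = rep(c("A", "B", "C"), each = 6),
    endpoint_id = "e", subgroup_id = "all", method = "pearson",
    fdr_significant = c(rep(TRUE, 5), FALSE,
                        rep(TRUE, 3), rep(FALSE, 3),
                        rep(FALSE, 6)))
  rk <- univariate_rank(res)
  expect_equal(rk$univariate_rank[match(c("A", "B", "C"), rk$analyte_id)],
               c(1L, 2L, 3L))

  # tie at the top: both rank 1, next rank 3
  res$fdr_significant[7:12] <- c(rep(TRUE, 5), FALSE)
  rk <- univariate_rank(res)
  expect_equal(rk$univariate_rank[match(c("A", "B", "C"), rk$analyte_id)],
               c(1L, 1L, 3L))

  # total tie at zero: everyone rank 1
  res$fdr_significant <- FALSE
  expect_true(all(univariate_rank(res)$univariate_rank == 1L))
})

test_that("multivariate priorities record order of entry; scores sum inverse priorities", {
  pri <- data.frame(analyte_id = c("X2", "X1", "X3"),
                    model_id = "m1", priority = 1:3)
  tb <- multivariate_score_and_rank(pri, c("X1", "X2", "X3", "X4"))
  expect_equal(tb$multivariate_score[match(c("X2", "X1", "X3"), tb$analyte_id)],
               c(1, 1 / 2, 1 / 3))
  # never-entered analyte shares the common lowest rank (3 ranked -> 4)
  expect_equal(tb$multivariate_rank[tb$analyte_id == "X4"], 4L)

  # first in two models scores 2.0; 1st and 3rd scores 1 + 1/3
  pri2 <- rbind(pri, data.frame(analyte_id = c("X2", "X3", "X1"),
                                model_id = "m2", priority = 1:3))
  tb2 <- multivariate_score_and_rank(pri2, c("X1", "X2", "X3"))
  expect_equal(tb2$multivariate_score[tb2$analyte_id == "X2"], 2.0)
  expect_equal(tb2$multivariate_score[tb2$analyte_id == "X3"], 1 / 3 + 1 / 2)
})

test_that("stepwise entry order finds the dominant variable first", {
  set.seed(13)
  n <- 150
  X <- matrix(exp(rnorm(n * 3)), n, 3,
              dimnames = list(NULL, c("x1", "x2", "x3")))
  cohort <- as.data.frame(X)
  y <- X[, "x1"] + 0.1 * X[, "x2"]
  pri <- multivariate_priorities(cohort, c("x1", "x2", "x3"), list(y = y),
                                 families = c("ols", "lasso"), seed = 1,
                                 exponent = 1)
  first <- pri[pri$priority == 1, "analyte_id"]
  expect_true(all(first == "x1"))
})

test_that("combined and grand ranks follow the inverse-rank sums", {
  # uni=1, multi=1 -> 2.0 ; uni=2, multi=4 -> 0.75
  tb <- data.frame(analyte_id = c("A", "B"),
                   univariate_rank = c(1, 2), multivariate_rank = c(1, 4))
  out <- combined_and_grand_ranks(list(s1 = tb))
  expect_equal(out$combined_score.s1[match(c("A", "B"), out$analyte_id)],
               c(2.0, 0.75))

  # combined ranks (1,1,1,1) across four studies -> grand score 4.0
  four <- rep(list(data.frame(analyte_id = "A", univariate_rank = 1,
                              multivariate_rank = 1)), 4)
  names(four) <- paste0("s", 1:4)
  expect_equal(combined_and_grand_ranks(four)$grand_score, 4.0)
})

test_that("ranks are invariant to analyte input order", {
  set.seed(31)
  cohort <- generate_cohort(preset_spec("studyI-like", n = 60), seed = 8)
  analytes <- mbda_component_analytes()
  eps <- list(das = cohort$das28crp4)
  t1 <- rank_table(cohort, analytes, eps, families = "lasso", seed = 2)
  t2 <- rank_table(cohort, sample(analytes), eps, families = "lasso", seed = 2)
  m <- match(t1$analyte_id, t2$analyte_id)
  expect_equal(t1$univariate_rank, t2$univariate_rank[m])
  expect_equal(t1$multivariate_rank, t2$multivariate_rank[m])
  expect_equal(t1$combined_rank, t2$combined_rank[m])
})
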