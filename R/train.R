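#' Forward stepwise model path
#'
#' Fits a nested sequence of linear models of sizes 1..`max_size` with the
#' order of variable entry recorded. For `family = "ols"` this is classic
#' greedy forward selection by residual sum of squares. For `"lasso"` and
#' `"enet"` the entry order is read off the glmnet penalty path (the order
#' in which variables first acquire a nonzero coefficient as the penalty
#' relaxes) and coefficients are refit by OLS at each size — one mechanism
#' that reconciles "LASSO" with "forward stepwise selection" and yields the
#' order-of-entry priorities the prioritization stage needs.
#'
#' @param X Numeric matrix of (transformed) predictors with column names.
#' @param y Numeric response.
#' @param family "ols", "lasso" or "enet".
#' @param max_size Largest model size; trimmed with a warning when the path
#'   or the design rank supports fewer.
#' @param alpha Elastic-net mixing parameter for `"enet"`, default 0.5.
#' @return List (class `mbda_steppath`): `order` (analytes by entry),
#'   `models` (per size: intercept + named coefficients), `mse` (training
#'   MSE per size, size 0 first).
#' @export
stepwise_fit <- function(X, y, family = c("lasso", "ols", "enet"),
                         max_size = ncol(X), alpha = 0.5) {
  family <- match.arg(family)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (any(apply(X, 2, stats::sd) == 0)) stop("constant predictor column")
  n <- nrow(X)
  rank_cap <- min(max_size, ncol(X), n - 2)
  if (rank_cap < max_size) {
    warning("max_size reduced to ", rank_cap, " (design rank/size)")
    max_size <- rank_cap
  }
  entry <- character(0)
  if (family == "ols") {
    remaining <- colnames(X)
    while (length(entry) < max_size && length(remaining)) {
      rss <- vapply(remaining, function(v) {
        fit <- stats::lm.fit(cbind(1, X[, c(entry, v), drop = FALSE]), y)
        sum(fit$residuals^2)
      }, numeric(1))
      entry <- c(entry, remaining[which.min(rss)])
      remaining <- setdiff(remaining, entry)
    }
  } else {
    a <- if (family == "lasso") 1 else alpha
    fit <- glmnet::glmnet(X, y, alpha = a, nlambda = 200,
                          lambda.min.ratio = 1e-4)
    beta <- as.matrix(fit$beta)
    first_nz <- apply(beta != 0, 1, function(r) if (any(r)) which(r)[1] else NA)
    entered <- names(sort(first_nz[!is.na(first_nz)]))
    entry <- utils::head(entered, max_size)
  }
  sizes <- seq_along(entry)
  models <- lapply(sizes, function(k) {
    vars <- entry[seq_len(k)]
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X[, vars, drop = FALSE]), y)
    cf <- fit$coefficients
    list(intercept = unname(cf[1]),
         coefficients = stats::setNames(cf[-1], vars))
  })
  mse0 <- mean((y - mean(y))^2)
  mse <- c(mse0, vapply(sizes, function(k) {
    m <- models[[k]]
    pred <- m$intercept + X[, names(m$coefficients), drop = FALSE] %*%
      m$coefficients
    mean((y - pred)^2)
  }, numeric(1)))
  structure(list(order = entry, models = models, mse = mse,
                 family = family), class = "mbda_steppath")
}

# Predict from one size of a step path (size 0 = intercept-only mean).
predict_steppath <- function(path, X, size, y_train_mean) {
  if (size == 0) return(rep(y_train_mean, nrow(X)))
  m <- path$models[[size]]
  as.numeric(m$intercept +
    as.matrix(X[, names(m$coefficients), drop = FALSE]) %*% m$coefficients)
}

# Fold assignment stratified by outcome tertile; deterministic given the
# RNG state at call time.
stratified_folds <- function(y, k) {
  n <- length(y)
  tert <- cut(rank(y, ties.method = "first"), breaks = 3, labels = FALSE)
  fold <- integer(n)
  for (g in unique(tert)) {
    idx <- which(tert == g)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Nested k-fold cross-validation for model size
#'
#' Within a training set, samples are divided into `k` groups stratified by
#' outcome tertile; models of every size are built on k-1 groups and scored
#' on the held-out group. Size 0 (intercept only) competes too. Mean squared
#' error is the default loss; held-out Pearson correlation is also reported.
#' With `rule = "1se"` (default) the selected size is the smallest whose
#' mean held-out loss lies within one standard error of the best — the
#' standard parsimony correction for the overselection the plain minimum
#' exhibits; `rule = "min"` takes the literal best mean (ties toward the
#' smaller model).
#'
#' @inheritParams stepwise_fit
#' @param k Number of folds, default 10; must not exceed `n`.
#' @param loss "mse" (default) or "cor" (negative Pearson r).
#' @param rule Size selection rule, "1se" (default) or "min".
#' @return List: `size` (selected), `cv_mse`, `cv_cor` (means per size,
#'   index 1 = size 0), `cv_se` (fold standard errors of the loss),
#'   `folds`.
#' @export
nested_cv_select <- function(X, y, family = "lasso", k = 10,
                             max_size = ncol(X), loss = c("mse", "cor"),
                             rule = c("1se", "min"), alpha = 0.5) {
  loss <- match.arg(loss)
  rule <- match.arg(rule)
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) stop("k exceeds the number of samples")
  fold <- stratified_folds(y, k)
  sizes <- 0:max_size
  se <- matrix(NA_real_, k, length(sizes))
  co <- matrix(NA_real_, k, length(sizes))
  for (f in seq_len(k)) {
    tr <- fold != f
    path <- stepwise_fit(X[tr, , drop = FALSE], y[tr], family = family,
                         max_size = max_size, alpha = alpha)
    for (j in seq_along(sizes)) {
      s <- min(sizes[j], length(path$order))
      pred <- predict_steppath(path, X[!tr, , drop = FALSE], s, mean(y[tr]))
      se[f, j] <- mean((y[!tr] - pred)^2)
      co[f, j] <- if (stats::sd(pred) > 0 && stats::sd(y[!tr]) > 0)
        stats::cor(pred, y[!tr]) else 0
    }
  }
  cv_mse <- colMeans(se)
  cv_cor <- colMeans(co)
  crit_mat <- if (loss == "mse") se else -co
  crit <- colMeans(crit_mat)
  cv_se <- apply(crit_mat, 2, stats::sd) / sqrt(k)
  j0 <- which.min(crit)
  size <- if (rule == "min") sizes[j0]
          else sizes[which(crit <= crit[j0] + cv_se[j0])[1]]
  list(size = size, cv_mse = cv_mse, cv_cor = cv_cor, cv_se = cv_se,
       sizes = sizes, folds = fold)
}

#' Curds-and-Whey shrinkage matrix (GCV form)
#'
#' Estimates the Breiman-Friedman shrinkage matrix from true responses `Y`
#' and their per-response predictions `Yhat`. In canonical coordinates the
#' shrinkage factors are
#' `d_i = (1 - r) (c_i^2 - r) / ((1 - r)^2 c_i^2 + r^2 (1 - c_i^2))`,
#' truncated to `[0, 1]`, with `r = p/n` and `c_i^2` the squared canonical
#' correlations between `Y` and `Yhat`; the matrix is assembled back in
#' original coordinates as `M = T^-1 D T` where `T` maps `Y` to canonical
#' coordinates. As `r -> 0` every `d_i -> 1` (no shrinkage in the
#' infinite-data limit); `c_i^2 <= r` shrinks fully to 0.
#'
#' @param Y Matrix of true responses (n x q, q >= 2).
#' @param Yhat Matrix of predictions, same shape.
#' @param p Number of predictors used to build `Yhat` (sets `r = p/n`).
#' @return List (class `mbda_cw`): `M` (q x q), `d`, `c2`, `r`, `T`.
#' @export
curds_whey_matrix <- function(Y, Yhat, p) {
  Y <- as.matrix(Y); Yhat <- as.matrix(Yhat)
  stopifnot(ncol(Y) >= 2, all(dim(Y) == dim(Yhat)))
  n <- nrow(Y)
  if (n <= ncol(Y)) stop("need more rows than response columns")
  r <- p / n
  cc <- tryCatch(stats::cancor(Yhat, Y),
                 error = function(e) {
                   warning("singular canonical problem; ridge epsilon 1e-8 applied")
                   eps <- 1e-8
                   stats::cancor(Yhat + matrix(stats::rnorm(length(Yhat), 0, eps),
                                               nrow(Yhat)), Y)
                 })
  c2 <- cc$cor^2
  d <- cw_shrinkage_factors(c2, r)
  # T: rows transform centered Y into canonical coordinates
  Tm <- t(cc$ycoef[, seq_along(d), drop = FALSE])
  M <- solve(Tm) %*% diag(d, nrow = length(d)) %*% Tm
  dimnames(M) <- list(colnames(Y), colnames(Y))
  structure(list(M = M, d = d, c2 = c2, r = r, T = Tm), class = "mbda_cw")
}

#' Closed-form Curds-and-Whey shrinkage factors
#'
#' @param c2 Squared canonical correlation(s), in `[0, 1]`.
#' @param r Ratio `p/n`.
#' @return Shrinkage factor(s) in `[0, 1]`.
#' @export
cw_shrinkage_factors <- function(c2, r) {
  d <- (1 - r) * (c2 - r) / ((1 - r)^2 * c2 + r^2 * (1 - c2))
  d[!is.finite(d)] <- 0  # c2 = r = 0: no correlation, shrink fully
  pmin(1, pmax(0, d))
}

#' Train a full MBDA-style model on a cohort
#'
#' For each DAS28-CRP component except CRP (TJC28, SJC28, PGA), fits a
#' LASSO forward-stepwise path on power-transformed marker concentrations
#' with the model size chosen by nested k-fold cross-validation; then
#' estimates the Curds-and-Whey shrinkage matrix over the two joint-count
#' predictions (predicted PGA and CRP are excluded from the shrinkage).
#'
#' @param cohort Cohort data.frame carrying the 11 component analytes plus
#'   tjc28, sjc28, pga, crp.
#' @param family "lasso" (default), "ols" or "enet"; "cw-lasso"/"cw-ols"
#'   aliases select the base family (shrinkage is always estimated).
#' @param seed Integer seed controlling fold assignment.
#' @param k Folds for nested CV, default 10.
#' @param exponent Concentration transform exponent, default 0.1.
#' @param combination Combination weights for the emitted coefficient set;
#'   defaults to the DAS28-CRP(4) weights (0.14 on the 0-10 PGA scale).
#' @param analytes Candidate predictors, default the 11 component analytes.
#' @return List (class `mbda_cw_model`): `coefficients`
#'   (`mbda_coefficients`, directly usable by [mbda_score()]), `selected`
#'   (sizes per component), `cv` (curves), `cw` (shrinkage detail).
#' @export
train_cw_lasso <- function(cohort, family = "lasso", seed = 1, k = 10,
                           exponent = 0.1,
                           combination = c(sqrt_iptjc = 0.56,
                                           sqrt_isjc = 0.28,
                                           log_crp = 0.36, ppga = 0.14,
                                           constant = 0.96),
                           analytes = mbda_component_analytes()) {
  base_family <- sub("^cw-", "", family)
  X <- marker_matrix(cohort, analytes, exponent)
  targets <- list(ptjc28 = cohort$tjc28, psjc28 = cohort$sjc28,
                  ppga = cohort$pga)
  components <- list(); selected <- integer(0); cv <- list()
  set.seed(seed)
  for (cmp in names(targets)) {
    y <- targets[[cmp]]
    sel <- nested_cv_select(X, y, family = base_family, k = k)
    path <- stepwise_fit(X, y, family = base_family)
    s <- min(sel$size, length(path$order))
    components[[cmp]] <- if (s == 0) {
      list(intercept = mean(y), coefficients = stats::setNames(numeric(0),
                                                               character(0)))
    } else path$models[[s]]
    selected[cmp] <- s
    cv[[cmp]] <- sel
  }
  pred <- vapply(c("ptjc28", "psjc28"), function(cmp) {
    m <- components[[cmp]]
    if (length(m$coefficients) == 0) rep(m$intercept, nrow(X))
    else as.numeric(m$intercept + X[, names(m$coefficients), drop = FALSE] %*%
                      m$coefficients)
  }, numeric(nrow(X)))
  Y <- cbind(tjc = cohort$tjc28, sjc = cohort$sjc28)
  colnames(pred) <- c("tjc", "sjc")
  p_used <- length(unique(c(names(components$ptjc28$coefficients),
                            names(components$psjc28$coefficients))))
  cw <- if (stats::sd(pred[, 1]) > 0 && stats::sd(pred[, 2]) > 0) {
    curds_whey_matrix(Y, pred, p = max(1, p_used))
  } else {
    structure(list(M = diag(2), d = c(1, 1), c2 = c(NA, NA),
                   r = p_used / nrow(X)), class = "mbda_cw")
  }
  coeffs <- algorithm_coefficients(
    components = components, shrinkage = cw$M, combination = combination,
    exponent = exponent,
    metadata = list(family = paste0("cw-", base_family), seed = seed,
                    k = k, n = nrow(cohort),
                    selected_sizes = as.list(selected),
                    note = "trained on data supplied at run time"))
  structure(list(coefficients = coeffs, selected = selected, cv = cv,
                 cw = cw), class = "mbda_cw_model")
}

#' Compare model families by repeated 70/30 cross-validation
#'
#' Each repetition draws one random 70/30 train/test split shared by all
#' families (paired comparison); each family trains on the 70% and is
#' evaluated on the held-out 30% by Pearson correlation to DAS28-CRP and
#' AUROC at the 2.67 cutoff and at the study-median cutoff. Plain families
#' ("ols", "lasso", "enet") regress DAS28-CRP directly on transformed
#' markers (size by nested CV); "cw-ols"/"cw-lasso" train component models
#' and score through the full pipeline.
#'
#' @param cohort Cohort data.frame.
#' @param families Character vector of families to compare.
#' @param reps Number of 70/30 repetitions.
#' @param seed Integer seed.
#' @param split Training fraction, default 0.7.
#' @param k Folds for the inner size selection (default 10).
#' @return data.frame: family, rep, r, auroc_fixed, auroc_median.
#' @export
compare_families <- function(cohort, families = c("lasso", "cw-lasso"),
                             reps = 10, seed = 1, split = 0.7, k = 10) {
  das <- das28_crp4(cohort$tjc28, cohort$sjc28, cohort$crp, cohort$pga)
  med <- stats::median(das)
  analytes <- mbda_component_analytes()
  X <- marker_matrix(cohort, analytes, 0.1)
  n <- nrow(cohort)
  out <- list()
  for (rep_i in seq_len(reps)) {
    set.seed(seed + 7919L * rep_i)
    tr <- sample(n, floor(split * n))
    te <- setdiff(seq_len(n), tr)
    for (fam in families) {
      pred <- if (startsWith(fam, "cw-")) {
        model <- train_cw_lasso(cohort[tr, , drop = FALSE], family = fam,
                                seed = seed + rep_i, k = k)
        mbda_score(cohort[te, , drop = FALSE], model$coefficients)$pre_scale
      } else {
        set.seed(seed + rep_i)
        sel <- nested_cv_select(X[tr, , drop = FALSE], das[tr], family = fam,
                                k = k)
        path <- stepwise_fit(X[tr, , drop = FALSE], das[tr], family = fam)
        s <- min(sel$size, length(path$order))
        predict_steppath(path, X[te, , drop = FALSE], s, mean(das[tr]))
      }
      lab_fixed <- as.integer(das[te] > 2.67)
      lab_med <- as.integer(das[te] > med)
      out[[length(out) + 1]] <- data.frame(
        family = fam, rep = rep_i,
        r = if (stats::sd(pred) > 0) stats::cor(pred, das[te]) else 0,
        auroc_fixed = if (length(unique(lab_fixed)) == 2)
          auroc(pred, lab_fixed) else NA_real_,
        auroc_median = if (length(unique(lab_med)) == 2)
          auroc(pred, lab_med) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
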