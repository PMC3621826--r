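# Competition ("1224") ranking on descending score: rank 1 is maximal,
# ties share the smallest rank, the next distinct score skips.
competition_rank <- function(score) {
  as.integer(rank(-score, ties.method = "min"))
}

#' Univariate biomarker screen
#'
#' Pearson and Spearman correlations of each analyte with each clinical
#' endpoint, in the whole cohort and in subgroups, with Benjamini-Hochberg
#' correction applied within each endpoint x subgroup x correlation-type
#' family; a cell is significant when its adjusted p-value is below `fdr_q`
#' (default FDR < 20%). Degenerate (constant) variables yield NA and are
#' excluded from downstream counting.
#'
#' @param cohort Cohort data.frame.
#' @param analytes Marker columns to screen.
#' @param endpoints Named list of numeric vectors (one per clinical
#'   measure), or character vector of cohort column names.
#' @param subgroups Optional named list of logical vectors; the full cohort
#'   ("all") is always screened.
#' @param fdr_q FDR threshold, default 0.20.
#' @param min_n Minimum complete observations per cell, default 3.
#' @return data.frame: analyte_id, endpoint_id, subgroup_id, method,
#'   estimate, p_value, p_adjusted, fdr_significant.
#' @export
univariate_screen <- function(cohort, analytes, endpoints,
                              subgroups = NULL, fdr_q = 0.20, min_n = 3) {
  if (is.character(endpoints)) {
    endpoints <- stats::setNames(lapply(endpoints, function(e) cohort[[e]]),
                                 endpoints)
  }
  groups <- c(list(all = rep(TRUE, nrow(cohort))), subgroups)
  rows <- list()
  for (ep in names(endpoints)) {
    for (sg in names(groups)) {
      idx <- groups[[sg]]
      yv <- endpoints[[ep]][idx]
      for (method in c("pearson", "spearman")) {
        res <- lapply(analytes, function(a) {
          xv <- cohort[[a]][idx]
          ok <- stats::complete.cases(xv, yv)
          x <- xv[ok]; y <- yv[ok]
          if (length(x) < min_n || stats::sd(x) == 0 || stats::sd(y) == 0) {
            return(c(NA_real_, NA_real_))
          }
          exact <- method == "spearman" && length(x) < 10
          ct <- suppressWarnings(
            stats::cor.test(x, y, method = method, exact = exact))
          c(unname(ct$estimate), ct$p.value)
        })
        est <- vapply(res, `[`, numeric(1), 1)
        p <- vapply(res, `[`, numeric(1), 2)
        p_adj <- rep(NA_real_, length(p))
        ok <- !is.na(p)
        p_adj[ok] <- stats::p.adjust(p[ok], method = "BH")
        rows[[length(rows) + 1]] <- data.frame(
          analyte_id = analytes, endpoint_id = ep, subgroup_id = sg,
          method = method, estimate = est, p_value = p, p_adjusted = p_adj,
          fdr_significant = !is.na(p_adj) & p_adj <= fdr_q,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Univariate rank from screen results
#'
#' `pass_count` is the number of (endpoint, subgroup, correlation-type)
#' cells in which the analyte passed the FDR criterion; analytes are ranked
#' by descending pass count with competition ranking.
#'
#' @param results Output of [univariate_screen()].
#' @param count_methods_separately Count Pearson and Spearman cells
#'   separately (default TRUE); if FALSE a cell counts once if either
#'   passes.
#' @return data.frame: analyte_id, pass_count, univariate_rank.
#' @export
univariate_rank <- function(results, count_methods_separately = TRUE) {
  if (!count_methods_separately) {
    agg0 <- stats::aggregate(
      fdr_significant ~ analyte_id + endpoint_id + subgroup_id,
      data = results, FUN = any)
    results <- agg0
  }
  agg <- stats::aggregate(fdr_significant ~ analyte_id, data = results,
                          FUN = function(x) sum(x, na.rm = TRUE))
  names(agg)[2] <- "pass_count"
  agg$univariate_rank <- competition_rank(agg$pass_count)
  agg[order(agg$univariate_rank, agg$analyte_id), ]
}

#' Order-of-entry priorities from multivariate models
#'
#' For each endpoint and model family a forward-stepwise model is fitted;
#' the first analyte entering a model gets priority 1, the second 2, etc.
#' Analytes never entering a model get no priority row.
#'
#' @param cohort Cohort data.frame.
#' @param analytes Candidate marker columns.
#' @param endpoints Named list of numeric endpoint vectors (or column
#'   names).
#' @param families Model families, default `c("ols", "lasso", "enet")`.
#' @param max_size Cap on model size per fit (nested CV selects the used
#'   size), default all analytes.
#' @param k Folds for nested CV size selection, default 10.
#' @param seed Integer seed for fold assignment.
#' @param exponent Concentration transform exponent, default 0.1.
#' @return data.frame: analyte_id, model_id, priority.
#' @export
multivariate_priorities <- function(cohort, analytes, endpoints,
                                    families = c("ols", "lasso", "enet"),
                                    max_size = length(analytes), k = 10,
                                    seed = 1, exponent = 0.1) {
  if (is.character(endpoints)) {
    endpoints <- stats::setNames(lapply(endpoints, function(e) cohort[[e]]),
                                 endpoints)
  }
  X <- marker_matrix(cohort, analytes, exponent)
  rows <- list()
  for (ep in names(endpoints)) {
    y <- endpoints[[ep]]
    for (fam in families) {
      model_id <- paste(ep, fam, sep = ":")
      fit <- tryCatch({
        set.seed(seed)
        sel <- nested_cv_select(X, y, family = fam, k = min(k, nrow(X)),
                                max_size = max_size)
        path <- stepwise_fit(X, y, family = fam, max_size = max_size)
        utils::head(path$order, min(sel$size, length(path$order)))
      }, error = function(e) {
        message("model skipped (", model_id, "): ", conditionMessage(e))
        NULL
      })
      if (is.null(fit) || !length(fit)) next
      rows[[length(rows) + 1]] <- data.frame(
        analyte_id = fit, model_id = model_id,
        priority = seq_along(fit), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(analyte_id = character(), model_id = character(),
                      priority = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Multivariate score and rank from priorities
#'
#' Score per analyte is the sum of inverse priorities across all models;
#' analytes are ranked by descending score (competition ranking). Analytes
#' never included in any model share a common lowest rank, one past the
#' number of ranked analytes.
#'
#' @param priorities Output of [multivariate_priorities()].
#' @param analytes Full analyte set (so never-entered analytes appear).
#' @return data.frame: analyte_id, multivariate_score, multivariate_rank.
#' @export
multivariate_score_and_rank <- function(priorities, analytes) {
  score <- stats::setNames(rep(0, length(analytes)), analytes)
  if (nrow(priorities)) {
    agg <- stats::aggregate(priority ~ analyte_id, data = priorities,
                            FUN = function(p) sum(1 / p))
    score[agg$analyte_id] <- agg$priority
  }
  entered <- score > 0
  rank <- rep(NA_integer_, length(analytes))
  rank[entered] <- competition_rank(score[entered])
  rank[!entered] <- sum(entered) + 1L
  out <- data.frame(analyte_id = analytes, multivariate_score = unname(score),
                    multivariate_rank = rank, stringsAsFactors = FALSE)
  out[order(out$multivariate_rank, out$analyte_id), ]
}

#' Combined and grand ranks across studies
#'
#' Within each study, `combined_score = 1/univariate_rank +
#' 1/multivariate_rank`, ranked descending. Across studies,
#' `grand_score = sum(1/combined_rank)` (an analyte absent from a study
#' contributes 0 there), and the grand rank sorts descending grand score.
#'
#' @param study_tables Named list of per-study data.frames, each with
#'   columns analyte_id, univariate_rank, multivariate_rank.
#' @return data.frame: analyte_id, per-study combined ranks
#'   (`combined_rank.<study>`), grand_score, grand_rank.
#' @export
combined_and_grand_ranks <- function(study_tables) {
  stopifnot(length(study_tables) >= 1)
  if (is.null(names(study_tables)) || any(names(study_tables) == "")) {
    names(study_tables) <- paste0("study", seq_along(study_tables))
  }
  per_study <- lapply(names(study_tables), function(st) {
    tb <- study_tables[[st]]
    tb$combined_score <- 1 / tb$univariate_rank + 1 / tb$multivariate_rank
    tb$combined_rank <- competition_rank(tb$combined_score)
    stats::setNames(
      tb[, c("analyte_id", "combined_score", "combined_rank")],
      c("analyte_id", paste0("combined_score.", st),
        paste0("combined_rank.", st)))
  })
  merged <- Reduce(function(a, b) merge(a, b, by = "analyte_id", all = TRUE),
                   per_study)
  rank_cols <- grep("^combined_rank\\.", names(merged), value = TRUE)
  inv <- as.matrix(1 / merged[, rank_cols, drop = FALSE])
  inv[is.na(inv)] <- 0
  merged$grand_score <- rowSums(inv)
  merged$grand_rank <- competition_rank(merged$grand_score)
  merged[order(merged$grand_rank, merged$analyte_id), ]
}

#' Full per-study rank table
#'
#' Convenience wrapper running the univariate screen, the multivariate
#' priorities and both ranks for one study.
#'
#' @inheritParams multivariate_priorities
#' @param subgroups Passed to [univariate_screen()].
#' @param fdr_q FDR threshold, default 0.20.
#' @return data.frame with pass_count, univariate_rank, multivariate_score,
#'   multivariate_rank, combined_score, combined_rank per analyte.
#' @export
rank_table <- function(cohort, analytes, endpoints, subgroups = NULL,
                       families = c("ols", "lasso", "enet"), fdr_q = 0.20,
                       k = 10, seed = 1) {
  uni <- univariate_rank(
    univariate_screen(cohort, analytes, endpoints, subgroups, fdr_q))
  pri <- multivariate_priorities(cohort, analytes, endpoints, families,
                                 k = k, seed = seed)
  multi <- multivariate_score_and_rank(pri, analytes)
  tb <- merge(uni, multi, by = "analyte_id", all = TRUE)
  tb$combined_score <- 1 / tb$univariate_rank + 1 / tb$multivariate_rank
  tb$combined_rank <- competition_rank(tb$combined_score)
  tb[order(tb$combined_rank, tb$analyte_id), ]
}
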