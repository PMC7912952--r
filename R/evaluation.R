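#' Scored subjects for ROC analysis
#'
#' Bundles per-subject labels and continuous scores, oriented so that larger
#' means more abnormal. For the Z arm the continuous statistic is the
#' (per-level or max-over-levels) Z-score itself; for the Q arm the negated
#' Q-score is used, since small percentiles indicate abnormalcy. Above-grid
#' Q-scores are mapped to one grid step beyond the largest grid percentile
#' before negation so every score is finite.
#'
#' @param subject_id Identifiers.
#' @param label 0 = healthy, 1 = patient.
#' @param score Numeric, larger = more abnormal.
#' @return Data frame of class `scored_subjects`.
#' @export
scored_subjects <- function(subject_id, label, score) {
  if (!all(label %in% c(0, 1)))
    stop("scored_subjects: 'label' must be 0 (healthy) or 1 (patient)",
         call. = FALSE)
  if (any(!is.finite(score)))
    stop("scored_subjects: scores must be finite", call. = FALSE)
  structure(data.frame(subject_id = as.character(subject_id),
                       label = as.integer(label), score = as.numeric(score),
                       stringsAsFactors = FALSE),
            class = c("scored_subjects", "data.frame"))
}

# Orientation helper for the Q arm: finite, larger = more abnormal.
q_to_abnormalcy <- function(q, grid = nu_grid()) {
  cap <- 100 * max(grid$values) + 1
  -pmin(q, cap)
}

#' Stratified k-fold cross-validated scoring
#'
#' Partitions healthy subjects and patients each into `k` folds (stratified,
#' so class proportions are preserved per fold). For every fold, the scorer
#' is trained on the healthy subjects of the other k-1 folds only — patients
#' never enter training — and then scores the held-out fold's healthy and
#' patient subjects. Each subject is scored exactly once, by the model of
#' the fold it was assigned to; the pooled out-of-fold scores are returned.
#'
#' @param healthy,patients `aorta_cohort`s (labels 0 and 1 respectively).
#' @param scorer_factory Function taking a training cohort and returning a
#'   function that maps subject rows to numeric scores (larger = more
#'   abnormal). See [z_scorer_factory()] and [q_scorer_factory()].
#' @param k Number of folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @return A [scored_subjects()] data frame with an extra `fold` column.
#' @export
cv_scores <- function(healthy, patients, scorer_factory, k = 10, seed = 1) {
  if (k < 2) stop("cv_scores: k must be >= 2", call. = FALSE)
  healthy <- as.data.frame(healthy); patients <- as.data.frame(patients)
  if (nrow(healthy) < k || nrow(patients) < k)
    stop("cv_scores: each class needs at least k members", call. = FALSE)
  set.seed(seed)
  fold_h <- sample(rep_len(seq_len(k), nrow(healthy)))
  fold_p <- sample(rep_len(seq_len(k), nrow(patients)))
  out <- vector("list", k)
  for (j in seq_len(k)) {
    train <- healthy[fold_h != j, , drop = FALSE]
    scorer <- scorer_factory(train)
    test_h <- healthy[fold_h == j, , drop = FALSE]
    test_p <- patients[fold_p == j, , drop = FALSE]
    out[[j]] <- data.frame(
      subject_id = c(test_h$subject_id, test_p$subject_id),
      label = rep(c(0L, 1L), c(nrow(test_h), nrow(test_p))),
      score = c(scorer(test_h), scorer(test_p)),
      fold = j, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  s <- scored_subjects(res$subject_id, res$label, res$score)
  s$fold <- res$fold
  s
}

#' Scorer factories for the two arms
#'
#' `z_scorer_factory(level)` trains the four linear diameter models on the
#' healthy training cohort and scores subjects by the Z-score at `level`, or
#' by the maximum Z over measured levels when `level = NULL` (the global Z
#' statistic). `q_scorer_factory(scope, level)` trains a Q-score ensemble and
#' scores by negated Q (larger = more abnormal).
#'
#' @param level Aortic level, or `NULL` for the global max-Z.
#' @param scope,grid,policy,gamma,adults_only Passed to
#'   [fit_qscore_ensemble()] / [fit_linear_model()].
#' @return A function suitable as `scorer_factory` in [cv_scores()].
#' @export
z_scorer_factory <- function(level = NULL, adults_only = FALSE,
                             policy = age_policy()) {
  function(train) {
    train <- as_aorta_cohort(train)
    if (is.null(level)) {
      models <- fit_linear_models(train, adults_only = adults_only,
                                  policy = policy)
      function(records) {
        records <- as.data.frame(records)
        zs <- sapply(AORTIC_LEVELS, function(lv) {
          obs <- records[[diameter_col(lv)]]
          z <- rep(NA_real_, nrow(records))
          ok <- !is.na(obs)
          if (any(ok))
            z[ok] <- z_score(models[[lv]], records[ok, , drop = FALSE],
                             obs[ok])
          z
        })
        zs <- matrix(zs, nrow = nrow(records))
        apply(zs, 1, max, na.rm = TRUE)
      }
    } else {
      model <- fit_linear_model(train, level, adults_only = adults_only,
                                policy = policy)
      function(records) {
        records <- as.data.frame(records)
        z_score(model, records, records[[diameter_col(level)]])
      }
    }
  }
}

#' @rdname z_scorer_factory
#' @export
q_scorer_factory <- function(scope = "global", level = NULL,
                             grid = nu_grid(), policy = age_policy(),
                             gamma = NULL, adults_only = FALSE) {
  function(train) {
    ensemble <- fit_qscore_ensemble(as_aorta_cohort(train), scope = scope,
                                    level = level, grid = grid,
                                    policy = policy, gamma = gamma,
                                    adults_only = adults_only)
    function(records) q_to_abnormalcy(q_score(ensemble, records), grid)
  }
}

#' ROC curve and AUC
#'
#' Builds the ROC curve by threshold sweep (via pROC) and reports the AUC,
#' which equals the Mann-Whitney probability that a random patient scores
#' higher than a random healthy subject, ties counted one half. Also reports
#' the operating point maximizing sensitivity + specificity (Youden), ties
#' broken toward higher specificity.
#'
#' @param scored A [scored_subjects()] data frame.
#' @param ci If `TRUE`, attach a stratified bootstrap percentile CI
#'   (see [bootstrap_auc_ci()]).
#' @param B,level,seed Bootstrap parameters when `ci = TRUE`.
#' @return Object of class `roc_result`: `auc`, `curve` (fpr, tpr),
#'   `best_cutoff`, `sensitivity`, `specificity`, optional `ci_low`/`ci_high`,
#'   and the underlying `pROC::roc` object in `roc`.
#' @export
roc_auc <- function(scored, ci = FALSE, B = 2000, level = 0.95, seed = 1) {
  if (length(unique(scored$label)) < 2L)
    stop("roc_auc: need both healthy and patient labels", call. = FALSE)
  r <- pROC::roc(response = scored$label, predictor = scored$score,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  curve <- data.frame(fpr = rev(1 - r$specificities),
                      tpr = rev(r$sensitivities))
  bc <- best_cutoff_from_scores(scored$label, scored$score)
  out <- list(auc = as.numeric(pROC::auc(r)), curve = curve,
              best_cutoff = bc$cutoff, sensitivity = bc$sensitivity,
              specificity = bc$specificity,
              n_healthy = sum(scored$label == 0),
              n_patients = sum(scored$label == 1), roc = r)
  if (ci) {
    interval <- bootstrap_auc_ci(scored, B = B, level = level, seed = seed)
    out$ci_low <- interval[1]; out$ci_high <- interval[2]
  }
  structure(out, class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f", x$auc))
  if (!is.null(x$ci_low))
    cat(sprintf(" [95%% CI %.3f-%.3f]", x$ci_low, x$ci_high))
  cat(sprintf("  (healthy n=%d, patients n=%d)\n", x$n_healthy, x$n_patients))
  cat(sprintf("Best cutoff %.3f: sensitivity %.3f, specificity %.3f\n",
              x$best_cutoff, x$sensitivity, x$specificity))
  invisible(x)
}

# Exhaustive threshold scan: classify abnormal when score >= cutoff,
# maximize sensitivity + specificity; ties -> higher specificity (i.e. the
# larger cutoff among tied optima).
best_cutoff_from_scores <- function(label, score) {
  thresholds <- sort(unique(score))
  # midpoints between consecutive observed scores, plus outer sentinels
  cand <- c(min(score) - 1,
            if (length(thresholds) > 1)
              (thresholds[-1] + thresholds[-length(thresholds)]) / 2,
            max(score) + 1)
  sens <- vapply(cand, function(t) mean(score[label == 1] >= t), 0)
  spec <- vapply(cand, function(t) mean(score[label == 0] < t), 0)
  j <- sens + spec
  best <- which(j == max(j))
  pick <- best[which.max(spec[best])]
  list(cutoff = cand[pick], sensitivity = sens[pick], specificity = spec[pick])
}

#' Best cutoff of an ROC result
#'
#' @param roc A [roc_auc()] result.
#' @return List with `cutoff`, `sensitivity`, `specificity`.
#' @export
best_cutoff <- function(roc) {
  list(cutoff = roc$best_cutoff, sensitivity = roc$sensitivity,
       specificity = roc$specificity)
}

#' Stratified bootstrap percentile CI for the AUC
#'
#' Resamples healthy subjects and patients separately with replacement `B`
#' times and returns the percentile interval of the bootstrap AUCs.
#'
#' @param scored A [scored_subjects()] data frame.
#' @param B Number of bootstrap replicates (>= 200).
#' @param level Confidence level.
#' @param seed RNG seed.
#' @return Length-2 numeric vector (low, high).
#' @export
bootstrap_auc_ci <- function(scored, B = 2000, level = 0.95, seed = 1) {
  if (B < 200) stop("bootstrap_auc_ci: B must be >= 200", call. = FALSE)
  set.seed(seed)
  idx0 <- which(scored$label == 0); idx1 <- which(scored$label == 1)
  s <- scored$score
  aucs <- vapply(seq_len(B), function(b) {
    auc_mw(s[sample(idx0, replace = TRUE)], s[sample(idx1, replace = TRUE)])
  }, numeric(1))
  alpha <- (1 - level) / 2
  unname(stats::quantile(aucs, c(alpha, 1 - alpha), type = 7))
}

# Mann-Whitney AUC from the rank-sum, ties counted one half.
auc_mw <- function(score0, score1) {
  n0 <- length(score0); n1 <- length(score1)
  r <- rank(c(score1, score0), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score sets on the same subjects using DeLong's
#' nonparametric method: per-subject placement values give structural
#' components whose empirical covariance yields the variance of the paired
#' AUC difference; a two-sided normal p-value is reported. Identical score
#' vectors give difference 0 and p = 1.
#'
#' @param scored_a,scored_b [scored_subjects()] for the two arms; must hold
#'   the same subjects with the same labels, in the same order.
#' @return Object of class `delong_result`: `auc_a`, `auc_b`, `difference`,
#'   `variance`, `p_value`.
#' @export
delong_test <- function(scored_a, scored_b) {
  if (nrow(scored_a) != nrow(scored_b) ||
      !identical(scored_a$subject_id, scored_b$subject_id) ||
      !identical(scored_a$label, scored_b$label))
    stop("delong_test: inputs must be paired (same subjects, same labels)",
         call. = FALSE)
  comp <- function(scored) {
    s1 <- scored$score[scored$label == 1]
    s0 <- scored$score[scored$label == 0]
    # placement of each patient among healthy scores and vice versa
    v10 <- vapply(s1, function(x) mean((x > s0) + 0.5 * (x == s0)), 0)
    v01 <- vapply(s0, function(y) mean((s1 > y) + 0.5 * (s1 == y)), 0)
    list(auc = mean(v10), v10 = v10, v01 = v01)
  }
  a <- comp(scored_a); b <- comp(scored_b)
  m <- length(a$v10); n <- length(a$v01)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- a$auc - b$auc
  p <- if (var_diff <= 0) {
    if (abs(diff) < .Machine$double.eps^0.5) 1 else 0
  } else {
    2 * stats::pnorm(-abs(diff) / sqrt(var_diff))
  }
  structure(list(auc_a = a$auc, auc_b = b$auc, difference = diff,
                 variance = var_diff, p_value = p),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf(
    "DeLong test: AUC_a = %.3f, AUC_b = %.3f, diff = %+.3f (var %.2e), p = %.4g\n",
    x$auc_a, x$auc_b, x$difference, x$variance, x$p_value))
  invisible(x)
}

#' Prevalence as a percentage
#'
#' `100 * n_abnormal / n_total`, reported to one decimal (e.g. 243 of 351
#' gives 69.2).
#'
#' @param n_abnormal,n_total Counts, `0 <= n_abnormal <= n_total`,
#'   `n_total > 0`.
#' @return Percentage rounded to one decimal.
#' @export
prevalence_percent <- function(n_abnormal, n_total) {
  if (any(n_total <= 0))
    stop("prevalence_percent: 'n_total' must be > 0", call. = FALSE)
  if (any(n_abnormal < 0) || any(n_abnormal > n_total))
    stop("prevalence_percent: need 0 <= n_abnormal <= n_total", call. = FALSE)
  round(100 * n_abnormal / n_total, 1)
}

#' Z/Q discordance table
#'
#' Cross-tabulates, over paired subject reports, the global Z call (any
#' level with Z > 2) against the global Q call (global Q-score <= 4%).
#'
#' @param z_reports List of [z_report()] objects.
#' @param q_reports List of [q_report()] objects for the same subjects, in
#'   the same order.
#' @return 2x2 integer table, rows = Z abnormal (FALSE/TRUE), columns = Q
#'   abnormal (FALSE/TRUE).
#' @export
discordance_table <- function(z_reports, q_reports) {
  if (length(z_reports) != length(q_reports))
    stop("discordance_table: inputs must be paired", call. = FALSE)
  z_flag <- vapply(z_reports, function(r) isTRUE(r$global_abnormal), logical(1))
  q_flag <- vapply(q_reports, function(r) {
    if (is.na(r$global_q)) stop("discordance_table: global Q unavailable",
                                call. = FALSE)
    r$global_q <= 4
  }, logical(1))
  table(z_abnormal = factor(z_flag, c(FALSE, TRUE)),
        q_abnormal = factor(q_flag, c(FALSE, TRUE)))
}
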