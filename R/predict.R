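## Prediction of the chronic memory outcome: stepwise logistic model
## selection, ROC/AUC, and paired bootstrap AUC comparison.

#' Stepwise logistic regression
#'
#' Bidirectional stepwise selection by AIC, starting from the intercept-only
#' model, over a candidate set of predictors. The selection path is
#' deterministic and logged.
#'
#' @param data Data frame holding outcome and candidates.
#' @param outcome Name of the binary outcome column (0/1 or logical; both
#'   classes must be present).
#' @param candidates Character vector of candidate predictor columns.
#' @param direction Passed to [stats::step()] (default `"both"`).
#' @return An object of class `glym_stepwise`: list with the fitted `glm`,
#'   `selected` (character vector), the coefficient table (estimate, SE, z,
#'   p), and the AIC path.
#' @export
stepwise_logistic <- function(data, outcome, candidates, direction = "both") {
  assert_that(all(c(outcome, candidates) %in% names(data)),
              "missing columns in data")
  y <- data[[outcome]]
  assert_that(length(unique(y[!is.na(y)])) == 2,
              "outcome must contain both classes")
  dat <- data[, c(outcome, candidates), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  null_fml <- stats::as.formula(paste(outcome, "~ 1"))
  full_fml <- stats::as.formula(paste(outcome, "~", paste(candidates, collapse = " + ")))
  base <- stats::glm(null_fml, family = stats::binomial(), data = dat)
  sel <- stats::step(base, scope = list(lower = null_fml, upper = full_fml),
                     direction = direction, trace = 0)
  if (!sel$converged || any(abs(stats::coef(sel)[-1]) > 15, na.rm = TRUE)) {
    stop_glym("logistic fit unstable (possible complete separation); consider penalised estimation")
  }
  sm <- summary(sel)$coefficients
  coef_table <- data.frame(term = rownames(sm), estimate = sm[, 1],
                           se = sm[, 2], z = sm[, 3], p = sm[, 4],
                           row.names = NULL)
  selected <- setdiff(attr(stats::terms(sel), "term.labels"), "1")
  structure(list(fit = sel, selected = selected, coef_table = coef_table,
                 aic = stats::AIC(sel), n = nrow(dat),
                 anova_path = sel$anova),
            class = "glym_stepwise")
}

#' @export
print.glym_stepwise <- function(x, ...) {
  cat(sprintf("<glym_stepwise> %d obs, AIC %.2f, selected: %s\n", x$n, x$aic,
              if (length(x$selected)) paste(x$selected, collapse = ", ")
              else "(intercept only)"))
  print(x$coef_table, digits = 4)
  invisible(x)
}

#' ROC curve and AUC
#'
#' The AUC is the tie-corrected pairwise concordance probability
#' `P(score_pos > score_neg) + P(tie)/2`, computed from the Mann-Whitney
#' rank-sum identity; the curve enumerates every distinct score threshold.
#'
#' @param scores Numeric predictor values (higher = more positive).
#' @param labels Binary labels (0/1 or logical); both classes required.
#' @return An object of class `glym_roc`: list with `auc`, `thresholds`,
#'   `sensitivity`, `one_minus_specificity`.
#' @export
auc_only <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- length(labels) - n1
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  assert_that(length(scores) == length(labels), "scores/labels length mismatch")
  assert_that(all(labels %in% 0:1), "labels must be binary")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  assert_that(n1 > 0 && n0 > 0, "both classes must be present")
  auc <- auc_only(scores, labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(scores[labels == 1] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[labels == 0] >= t), numeric(1))
  structure(list(auc = auc, thresholds = thr, sensitivity = sens,
                 one_minus_specificity = fpr),
            class = "glym_roc")
}

#' @export
print.glym_roc <- function(x, ...) {
  cat(sprintf("<glym_roc> AUC = %.4f (%d thresholds)\n", x$auc,
              length(x$thresholds)))
  invisible(x)
}

#' Paired bootstrap comparison of two AUCs
#'
#' Both models are scored on the same subjects; subjects are resampled with
#' replacement, the AUC difference is recomputed per resample, and the
#' two-sided p-value is the normal tail probability of the observed
#' difference against the bootstrap standard error. Resamples containing a
#' single class are redrawn (and counted).
#'
#' @param scores_a,scores_b Model scores on the same subjects.
#' @param labels Binary labels.
#' @param n_boot Number of bootstrap resamples (>= 200; default 2000).
#' @param seed RNG seed (mandatory: the comparison must be reproducible).
#' @return A `glym_test` with `estimate` = AUC(b) - AUC(a), extra fields
#'   `auc_a`, `auc_b`, `boot_se`, `n_redrawn`.
#' @export
compare_auc_bootstrap <- function(scores_a, scores_b, labels, n_boot = 2000,
                                  seed) {
  assert_that(!missing(seed), "seed is mandatory for the bootstrap comparison")
  assert_that(n_boot >= 200, "n_boot must be >= 200")
  labels <- as.integer(as.logical(labels))
  n <- length(labels)
  assert_that(length(scores_a) == n && length(scores_b) == n,
              "scores and labels must cover the same subjects")
  auc_a <- roc_auc(scores_a, labels)$auc
  auc_b <- roc_auc(scores_b, labels)$auc
  d_obs <- auc_b - auc_a
  with_seed(seed, {
    d_boot <- numeric(n_boot)
    n_redrawn <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2) break
        n_redrawn <- n_redrawn + 1L
      }
      d_boot[b] <- auc_only(scores_b[idx], labels[idx]) -
                   auc_only(scores_a[idx], labels[idx])
    }
    se <- stats::sd(d_boot)
    p <- if (se == 0) 1 else 2 * stats::pnorm(-abs(d_obs) / se)
    new_test("auc_bootstrap", statistic = if (se == 0) 0 else d_obs / se,
             p_value = p, estimate = d_obs,
             extra = list(auc_a = auc_a, auc_b = auc_b, boot_se = se,
                          n_boot = n_boot, n_redrawn = n_redrawn))
  })
}
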