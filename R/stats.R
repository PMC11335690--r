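## Statistical battery: score derivations, group tests, associations,
## longitudinal models, FDR. Standard tests are delegated to the stats /
## lme4 machinery; every wrapper returns a uniform `glym_test` record.

new_test <- function(method, statistic = NA_real_, df = NA_real_,
                     p_value = NA_real_, estimate = NA_real_,
                     conf_int = c(NA_real_, NA_real_), extra = list()) {
  structure(c(list(method = method, statistic = statistic, df = df,
                   p_value = p_value, estimate = estimate,
                   conf_int = conf_int), extra),
            class = "glym_test")
}

#' @export
print.glym_test <- function(x, ...) {
  cat(sprintf("<glym_test> %s\n", x$method))
  cat(sprintf("  statistic %.4g, df %.4g, p = %.4g, estimate %.4g\n",
              x$statistic, x$df, x$p_value, x$estimate))
  invisible(x)
}

#' Symptom-score summaries from questionnaire items
#'
#' RPQ: 22 items on a 0-4 ordinal scale; the total is the plain sum (range
#' 0-88), a symptom counts as present when rated at least mild (>= 2), and
#' the memory-problem flag is the memory item's presence flag. PSQI: seven
#' component scores 0-3 summed to the global score 0-21.
#'
#' @param rpq_items Numeric vector of 22 ratings in 0-4, or a matrix with 22
#'   columns (one row per record).
#' @param psqi_components Optional vector of 7 component scores 0-3 (or
#'   matrix with 7 columns).
#' @param zero_mild_ratings If `TRUE`, ratings of 1 ("no more of a problem")
#'   are zeroed before summing the total (a common alternative convention;
#'   off by default so the total spans 0-88).
#' @return List with `rpq_total`, `n_symptoms`, `symptomatic` (logical item
#'   flags), `memory_problem`, and `psqi_global` (NULL if components
#'   missing).
#' @export
derive_symptom_summaries <- function(rpq_items, psqi_components = NULL,
                                     zero_mild_ratings = FALSE) {
  m <- if (is.matrix(rpq_items)) rpq_items else matrix(rpq_items, nrow = 1)
  assert_that(ncol(m) == RPQ_N_ITEMS, "expected %d RPQ items, got %d",
              RPQ_N_ITEMS, ncol(m))
  assert_that(all(m %in% 0:4), "RPQ ratings must be integers in 0-4")
  scored <- if (zero_mild_ratings) m * (m >= 2) else m
  psqi_global <- NULL
  if (!is.null(psqi_components)) {
    p <- if (is.matrix(psqi_components)) psqi_components else matrix(psqi_components, nrow = 1)
    assert_that(ncol(p) == PSQI_N_COMPONENTS, "expected %d PSQI components, got %d",
                PSQI_N_COMPONENTS, ncol(p))
    assert_that(all(p %in% 0:3), "PSQI component scores must be integers in 0-3")
    psqi_global <- rowSums(p)
  }
  res <- list(rpq_total = rowSums(scored),
              n_symptoms = rowSums(m >= 2),
              symptomatic = m >= 2,
              memory_problem = m[, RPQ_MEMORY_ITEM] >= 2,
              psqi_global = psqi_global)
  if (nrow(m) == 1) {
    res$rpq_total <- res$rpq_total[1]
    res$n_symptoms <- res$n_symptoms[1]
    res$symptomatic <- as.vector(res$symptomatic)
    res$memory_problem <- res$memory_problem[1]
    if (!is.null(psqi_global)) res$psqi_global <- psqi_global[1]
  }
  res
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom,
#' two-sided.
#'
#' @param x,y Numeric samples, each with n >= 2 and positive variance.
#' @return A `glym_test` (estimate = mean difference).
#' @export
welch_t_test <- function(x, y) {
  assert_that(length(x) >= 2 && length(y) >= 2, "each sample needs n >= 2")
  assert_that(stats::var(x) > 0 || stats::var(y) > 0,
              "both samples are constant")
  tt <- stats::t.test(x, y, var.equal = FALSE)
  new_test("welch_t", statistic = unname(tt$statistic), df = unname(tt$parameter),
           p_value = tt$p.value, estimate = unname(diff(rev(tt$estimate))),
           conf_int = as.numeric(tt$conf.int))
}

#' Pearson chi-squared test on a contingency table
#'
#' No continuity correction; `df = (r - 1)(k - 1)`.
#'
#' @param table Matrix of nonnegative counts without zero marginals.
#' @return A `glym_test`.
#' @export
chi_squared_test <- function(table) {
  table <- as.matrix(table)
  assert_that(all(table >= 0) && all(table == round(table)),
              "counts must be nonnegative integers")
  assert_that(all(rowSums(table) > 0) && all(colSums(table) > 0),
              "zero marginal row or column")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  new_test("chi_squared", statistic = unname(ct$statistic),
           df = unname(ct$parameter), p_value = ct$p.value)
}

#' Pearson correlation test
#'
#' @param x,y Numeric vectors, n >= 3, nonzero variance.
#' @return A `glym_test` (estimate = r; p from the t-transform on n - 2 df).
#' @export
pearson_correlation <- function(x, y) {
  assert_that(length(x) == length(y), "x and y lengths differ")
  assert_that(length(x) >= 3, "need n >= 3")
  assert_that(stats::var(x) > 0 && stats::var(y) > 0,
              "zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson")
  new_test("pearson", statistic = unname(ct$statistic), df = unname(ct$parameter),
           p_value = ct$p.value, estimate = unname(ct$estimate),
           conf_int = as.numeric(ct$conf.int))
}

#' Covariate-adjusted association between an outcome and a marker
#'
#' Ordinary least squares of `outcome ~ marker + covariates`; reports the
#' marker coefficient, its t-test, and the partial correlation of outcome
#' and marker given the covariates (the signed root of the marker's partial
#' R^2, identical to the correlation of the two residual vectors).
#'
#' @param outcome,marker Numeric vectors.
#' @param covariates Data frame (or named list) of covariates, e.g. age and
#'   sex. May be `NULL` for a simple regression.
#' @return A `glym_test` with `estimate` = marker slope and extra field
#'   `partial_r`.
#' @export
adjusted_association <- function(outcome, marker, covariates = NULL) {
  n <- length(outcome)
  assert_that(length(marker) == n, "outcome and marker lengths differ")
  dat <- data.frame(.y = outcome, .m = marker)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    assert_that(nrow(covariates) == n, "covariate rows do not match")
    dat <- cbind(dat, covariates)
  }
  p <- ncol(dat) - 1
  assert_that(n > p + 2, "too few observations for %d predictors", p)
  fit <- stats::lm(.y ~ ., data = dat)
  assert_that(!any(is.na(stats::coef(fit))), "rank-deficient design")
  sm <- summary(fit)$coefficients
  row <- sm[".m", ]
  tval <- row[["t value"]]
  df_res <- fit$df.residual
  partial_r <- sign(tval) * sqrt(tval^2 / (tval^2 + df_res))
  new_test("adjusted_association", statistic = tval, df = df_res,
           p_value = row[["Pr(>|t|)"]], estimate = row[["Estimate"]],
           extra = list(partial_r = partial_r, se = row[["Std. Error"]],
                        fit = fit))
}

#' Linear mixed model for the visit effect
#'
#' REML fit of `outcome ~ visit + age + sex + (1 | subject)` on the
#' longitudinal (mTBI) rows of a cohort table, with Wald tests for the
#' fixed effects. Boundary fits (zero random-intercept variance) are
#' reported, not errored.
#'
#' @param cohort A cohort data frame with both mTBI visits.
#' @param outcome Column name of the modelled marker (e.g. `"bg_epvs"`).
#' @param covariates Character vector of covariate columns (default age and
#'   sex).
#' @return A `glym_test` for the visit effect, with the full `lme4` fit and
#'   the fixed-effect table in the extra fields.
#' @export
fit_lmm_visit <- function(cohort, outcome, covariates = c("age", "sex")) {
  tab <- cohort[cohort$visit %in% c("14Day", "6-12Mon"), ]
  assert_that(nrow(tab) > 0, "no longitudinal visits in cohort")
  assert_that(length(unique(tab$subject_id)) >= 2, "need >= 2 subjects")
  tab$visit <- factor(tab$visit, levels = c("14Day", "6-12Mon"))
  fml <- stats::as.formula(paste(outcome, "~ visit",
                                 if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else "",
                                 "+ (1 | subject_id)"))
  fit <- suppressMessages(lme4::lmer(fml, data = tab, REML = TRUE))
  fe <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- fe / se
  p <- 2 * stats::pnorm(-abs(z))
  i <- grep("^visit", names(fe))[1]
  new_test("lmm_visit", statistic = z[[i]], df = NA_real_, p_value = p[[i]],
           estimate = fe[[i]],
           extra = list(fixed_effects = data.frame(term = names(fe),
                                                   estimate = unname(fe),
                                                   se = unname(se),
                                                   z = unname(z),
                                                   p = unname(p)),
                        tau = vc$sdcor[vc$grp == "subject_id"],
                        sigma = vc$sdcor[vc$grp == "Residual"],
                        converged = length(fit@optinfo$conv$lme4) == 0,
                        fit = fit))
}

#' Longitudinal ratio-change correlation
#'
#' For every mTBI subject with both visits and a nonzero 14Day value, forms
#' the ratio `value(6-12Mon) / value(14Day)` of a marker and a score, then
#' Pearson-correlates the two ratio series. Subjects lacking either visit
#' or with a zero baseline are excluded and counted.
#'
#' @param cohort A cohort data frame.
#' @param marker,score Column names (e.g. `"alps_index"`, `"psqi"`).
#' @return A `glym_test` (estimate = r) with extra fields `n_pairs`,
#'   `n_excluded` and the per-subject ratio table.
#' @export
ratio_change_correlation <- function(cohort, marker, score) {
  v1 <- cohort[cohort$visit == "14Day", ]
  v2 <- cohort[cohort$visit == "6-12Mon", ]
  common <- intersect(v1$subject_id, v2$subject_id)
  n_excluded <- length(unique(cohort$subject_id[cohort$group == "mTBI"])) -
    length(common)
  i1 <- match(common, v1$subject_id); i2 <- match(common, v2$subject_id)
  base_m <- v1[[marker]][i1]; base_s <- v1[[score]][i1]
  ok <- is.finite(base_m) & base_m != 0 & is.finite(base_s) & base_s != 0
  if (any(!ok)) {
    warning(sprintf("excluded %d subject(s) with zero/missing baseline", sum(!ok)),
            call. = FALSE)
    n_excluded <- n_excluded + sum(!ok)
  }
  rm_ <- v2[[marker]][i2][ok] / base_m[ok]
  rs_ <- v2[[score]][i2][ok] / base_s[ok]
  assert_that(length(rm_) >= 3, "fewer than 3 complete visit pairs")
  assert_that(stats::var(rm_) > 0 && stats::var(rs_) > 0,
              "ratio series constant; correlation undefined")
  res <- pearson_correlation(rm_, rs_)
  res$method <- "ratio_change_correlation"
  res$n_pairs <- length(rm_)
  res$n_excluded <- n_excluded
  res$ratios <- data.frame(subject_id = common[ok], marker_ratio = rm_,
                           score_ratio = rs_)
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: `adj_(i) = min_(j >= i) m p_(j) / j`, capped
#' at 1. Delegates to [stats::p.adjust()].
#'
#' @param p_values Numeric vector in `[0, 1]` (NA allowed, propagated).
#' @return Adjusted p-values in the original order.
#' @export
fdr_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  assert_that(all(p_values[ok] >= 0 & p_values[ok] <= 1),
              "p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
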