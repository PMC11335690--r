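test_that("symptom summaries follow the rating rules", {
  zero <- derive_symptom_summaries(rep(0, 22))
  expect_equal(zero$rpq_total, 0)
  expect_equal(zero$n_symptoms, 0)

  full <- derive_symptom_summaries(rep(4, 22))
  expect_equal(full$rpq_total, 88)
  expect_equal(full$n_symptoms, 22)
  expect_true(full$memory_problem)

  items <- c(2, 1, rep(0, 20))
  s <- derive_symptom_summaries(items)
  expect_equal(s$rpq_total, 3)
  expect_equal(s$n_symptoms, 1)
  expect_identical(s$symptomatic, items >= 2)
  expect_false(s$memory_problem)

  ## alternative convention: ratings of 1 are zeroed in the total
  s2 <- derive_symptom_summaries(items, zero_mild_ratings = TRUE)
  expect_equal(s2$rpq_total, 2)
  expect_equal(s2$n_symptoms, 1)

  psqi <- derive_symptom_summaries(rep(0, 22), psqi_components = rep(3, 7))
  expect_equal(psqi$psqi_global, 21)

  expect_error(derive_symptom_summaries(rep(0, 21)), "22")
  expect_error(derive_symptom_summaries(c(5, rep(0, 21))), "0-4")
})

test_that("welch test matches the directly evaluated formula", {
  x <- c(1, 2, 3)
  r0 <- welch_t_test(x, x)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  set.seed(10)
  for (i in 1:20) {
    x <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    got <- welch_t_test(x, y)
    want <- oracle_welch(x, y)
    expect_equal(got$statistic, want$t, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
  }
  expect_error(welch_t_test(1, c(1, 2)), "n >= 2")
})

test_that("chi-squared test is Pearson without continuity correction", {
  even <- chi_squared_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)

  t2 <- chi_squared_test(matrix(c(20, 10, 10, 20), 2))
  expect_equal(t2$statistic, 100 / 15, tolerance = 1e-12)
  expect_equal(t2$df, 1)

  t3 <- chi_squared_test(matrix(c(5, 5, 6, 6, 7, 7), 2))
  expect_equal(t3$df, 2)

  set.seed(3)
  for (i in 1:10) {
    tab <- matrix(rpois(6, 20) + 1, 2)
    got <- chi_squared_test(tab)
    want <- oracle_chisq(tab)
    expect_equal(got$statistic, want$stat, tolerance = 1e-10)
    expect_equal(got$df, want$df)
  }
  expect_error(chi_squared_test(matrix(c(0, 0, 5, 5), 2)), "marginal")
})

test_that("pearson correlation handles exact and sampled cases", {
  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 1)$estimate, 1)
  expect_equal(pearson_correlation(x, -x)$estimate, -1)

  set.seed(12)
  for (i in 1:10) {
    x <- rnorm(25); y <- 0.4 * x + rnorm(25)
    got <- pearson_correlation(x, y)
    want <- oracle_pearson(x, y)
    expect_equal(got$estimate, want$r, tolerance = 1e-12)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
  }
  expect_error(pearson_correlation(rep(1, 5), rnorm(5)), "variance")
})

test_that("pearson p agrees with a permutation oracle", {
  set.seed(42)
  x <- rnorm(20); y <- 0.45 * x + rnorm(20)
  got <- pearson_correlation(x, y)
  n_perm <- 1e5
  r_obs <- abs(oracle_pearson(x, y)$r)
  xc <- x - mean(x)
  perm <- replicate(n_perm, {
    yp <- sample(y)
    abs(sum(xc * (yp - mean(yp))))
  })
  scale <- sqrt(sum(xc^2) * sum((y - mean(y))^2))
  p_perm <- mean(perm / scale >= r_obs)
  mc_err <- sqrt(p_perm * (1 - p_perm) / n_perm)
  expect_lt(abs(got$p_value - p_perm), max(2 * mc_err, 0.004))
})

test_that("adjusted association reduces to simple regression when orthogonal", {
  set.seed(30)
  n <- 200
  marker <- rnorm(n)
  cov1 <- resid(lm(rnorm(n) ~ marker))   # orthogonal to marker and intercept
  y <- 0.7 * marker + 0.5 * cov1 + rnorm(n)
  adj <- adjusted_association(y, marker, data.frame(c1 = cov1))
  simple <- coef(lm(y ~ marker))[["marker"]]
  expect_equal(adj$estimate, simple, tolerance = 1e-10)

  expect_error(adjusted_association(y, marker, data.frame(m2 = marker)),
               "rank")

  ## partial correlation equals the residual-residual correlation
  cov2 <- rnorm(n)
  y2 <- 0.3 * marker + 0.8 * cov2 + rnorm(n)
  adj2 <- adjusted_association(y2, marker, data.frame(c2 = cov2))
  ry <- resid(lm(y2 ~ cov2)); rm_ <- resid(lm(marker ~ cov2))
  expect_equal(adj2$partial_r, cor(ry, rm_), tolerance = 1e-10)
})

test_that("mixed model reduces to OLS at zero random-effect variance", {
  set.seed(44)
  spec <- cohort_gen_spec(n_control = 0, n_mtbi = 60, tau = 0,
                          bg = c(intercept = 0.5, visit = 0.15, sigma = 0.1),
                          seed = 44)
  tab <- make_synthetic_cohort(spec)
  fit <- fit_lmm_visit(tab, "bg_epvs")
  long <- tab[tab$visit %in% c("14Day", "6-12Mon"), ]
  long$visit <- factor(long$visit, levels = c("14Day", "6-12Mon"))
  ols <- lm(bg_epvs ~ visit + age + sex, data = long)
  expect_equal(fit$estimate, coef(ols)[["visit6-12Mon"]], tolerance = 1e-6)
})

test_that("balanced paired data recover the mean within-subject difference", {
  set.seed(45)
  n <- 40
  base <- rnorm(n, 10)
  d <- rnorm(n, 0.8, 0.3)
  tab <- data.frame(
    subject_id = rep(sprintf("P%02d", 1:n), each = 2),
    visit = rep(c("14Day", "6-12Mon"), n),
    y = as.vector(rbind(base, base + d)))
  fit <- fit_lmm_visit(tab, "y", covariates = character(0))
  expect_equal(fit$estimate, mean(d), tolerance = 1e-8)
})

test_that("ratio-change correlation excludes incomplete pairs and logs them", {
  tab <- make_synthetic_cohort(cohort_gen_spec(n_control = 0, n_mtbi = 10,
                                               seed = 77))
  drop_subj <- unique(tab$subject_id)[1]
  tab2 <- tab[!(tab$subject_id == drop_subj & tab$visit == "6-12Mon"), ]
  r <- ratio_change_correlation(tab2, "alps_index", "psqi")
  expect_equal(r$n_pairs, 9)
  expect_equal(r$n_excluded, 1)

  ## constant ratios are degenerate
  tab3 <- tab
  tab3$alps_index <- 1.5
  expect_error(ratio_change_correlation(tab3, "alps_index", "psqi"),
               "constant")
})

test_that("BH adjustment matches the brute-force tail definition", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  set.seed(50)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(fdr_adjust(p), oracle_bh(p), tolerance = 1e-14)
  }
  ## idempotent and permutation-equivariant
  p <- runif(20)
  a1 <- fdr_adjust(p)
  expect_equal(fdr_adjust(a1), a1)
  o <- sample(20)
  expect_equal(fdr_adjust(p[o]), a1[o])
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_true(all(fdr_adjust(p) >= p))
})
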