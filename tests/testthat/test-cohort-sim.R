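test_that("cohort generation is deterministic and structurally valid", {
  spec <- cohort_gen_spec(n_control = 8, n_mtbi = 8, seed = 2)
  a <- make_synthetic_cohort(spec)
  b <- make_synthetic_cohort(spec)
  expect_identical(a, b)

  expect_s3_class(a, "glym_cohort")
  expect_equal(sum(a$visit == "control"), 8)
  expect_equal(sum(a$visit == "14Day"), 8)
  expect_equal(sum(a$visit == "6-12Mon"), 8)

  ## memory flag is exactly the memory item's >= 2 indicator
  items <- as.matrix(a[, sprintf("rpq_%02d", 1:22)])
  expect_identical(a$memory_problem, as.integer(items[, 9] >= 2))
  expect_identical(a$n_symptoms, unname(rowSums(items >= 2)))
  expect_identical(a$rpq_total, unname(rowSums(items)))
})

test_that("a null age slope produces no age correlation", {
  spec <- cohort_gen_spec(n_control = 10000, n_mtbi = 0,
                          gamma = c(intercept = -1, age = 0, mtbi = 0),
                          seed = 61)
  tab <- make_synthetic_cohort(spec)
  expect_lt(abs(cor(tab$age, tab$wm_epvs)), 0.03)
})

test_that("the ratio correlation is generated at its target", {
  spec <- cohort_gen_spec(n_control = 0, n_mtbi = 10000, seed = 62)
  tab <- make_synthetic_cohort(spec)
  r <- ratio_change_correlation(tab, "alps_index", "psqi")
  expect_lt(abs(r$estimate - (-0.42)), 0.05)
})

test_that("null marker effects give no AUC gain over education alone", {
  spec <- cohort_gen_spec(n_control = 0, n_mtbi = 10000,
                          delta = c(intercept = 0.3, education = -0.25,
                                    ct_or_mri = 0, wm_epvs = 0, alps = 0),
                          seed = 63)
  tab <- make_synthetic_cohort(spec)
  v1 <- tab[tab$visit == "14Day", ]
  m_edu <- glm(memory_problem ~ education, family = binomial, data = v1)
  m_full <- glm(memory_problem ~ education + wm_epvs + alps_index,
                family = binomial, data = v1)
  a_edu <- roc_auc(predict(m_edu), v1$memory_problem)$auc
  a_full <- roc_auc(predict(m_full), v1$memory_problem)$auc
  expect_lt(abs(a_full - a_edu), 0.02)
})

test_that("marginal calibration sits near the intended control targets", {
  tab <- make_synthetic_cohort(cohort_gen_spec(n_control = 5000, n_mtbi = 0,
                                               seed = 64))
  expect_equal(mean(tab$wm_epvs), 0.40, tolerance = 0.05)
  expect_equal(sd(tab$wm_epvs), 0.18, tolerance = 0.1)
  expect_equal(mean(tab$alps_index), 1.51, tolerance = 0.02)
  expect_equal(sd(tab$alps_index), 0.12, tolerance = 0.1)
})
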