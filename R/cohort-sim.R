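#' Generative specification for a synthetic two-visit cohort
#'
#' Encodes the effect structure the statistical battery is designed to
#' detect: an age-increasing log white-matter ePVS burden, an age-decreasing
#' ALPS index, a symptom count linked to WM ePVS through a Poisson log-link,
#' a memory-problem outcome with a logistic link on education and the two
#' glymphatic markers, a basal-ganglia burden with a subject random intercept
#' and a visit effect, and a negative correlation between the longitudinal
#' ALPS ratio and PSQI ratio. Marginal means and spreads of the defaults are
#' calibrated to plausible control-population values (WM ePVS ~0.40 +/-
#' 0.18 %, ALPS ~1.51 +/- 0.12, age 18-60); they are generator defaults, not
#' estimates of any particular dataset.
#'
#' @param n_control,n_mtbi Subjects per group. Controls contribute one
#'   visit (`"control"`), mTBI subjects two (`"14Day"`, `"6-12Mon"`).
#' @param age_range Uniform age range in years.
#' @param gamma Coefficients of `log(WM ePVS %)`: intercept, age slope
#'   (per year), mTBI group shift.
#' @param sigma_log_wm Residual sd of log WM ePVS.
#' @param beta Coefficients of the ALPS index: intercept, age slope.
#' @param sigma_alps Residual sd of ALPS.
#' @param eta Symptom-count coefficients (Poisson, log link on the count of
#'   non-memory symptomatic items): intercept, WM-ePVS slope (per percent),
#'   mTBI group shift.
#' @param delta Memory-problem logit coefficients: intercept, education
#'   (years), CT-or-MRI-positive flag, WM ePVS (percent), ALPS.
#' @param bg Basal-ganglia burden model: intercept, visit effect (shift at
#'   the follow-up visit, percent), residual sd.
#' @param tau Subject random-intercept sd of the BG burden.
#' @param rho_ratio Correlation between the ALPS ratio and the PSQI ratio
#'   (6-12Mon / 14Day).
#' @param sd_alps_ratio,sd_psqi_ratio Spreads of the two ratios around 1.
#' @param seed RNG seed; the cohort is a pure function of the spec.
#' @return An object of class `cohort_gen_spec`.
#' @export
cohort_gen_spec <- function(n_control = 37, n_mtbi = 44,
                            age_range = c(18, 60),
                            gamma = c(intercept = -1.905, age = 0.023,
                                      mtbi = -0.134),
                            sigma_log_wm = 0.326,
                            beta = c(intercept = 1.653, age = -0.00366),
                            sigma_alps = 0.111,
                            eta = c(intercept = 0.714, wm_epvs = 1.2,
                                    mtbi = 0.826),
                            delta = c(intercept = -10.416, education = -0.2367,
                                      ct_or_mri = -1.6464, wm_epvs = 3.5513,
                                      alps = 9.3073),
                            bg = c(intercept = 0.50, visit = 0.10, sigma = 0.10),
                            tau = 0.15,
                            rho_ratio = -0.42,
                            sd_alps_ratio = 0.06, sd_psqi_ratio = 0.30,
                            seed = 1L) {
  assert_that(n_control >= 0 && n_mtbi >= 0, "cohort sizes must be >= 0")
  assert_that(abs(rho_ratio) <= 1, "|rho_ratio| must be <= 1")
  assert_that(sigma_log_wm >= 0 && sigma_alps >= 0 && tau >= 0 &&
                sd_alps_ratio >= 0 && sd_psqi_ratio >= 0 && bg[["sigma"]] >= 0,
              "all sds must be >= 0")
  assert_that(age_range[1] < age_range[2], "age range must be increasing")
  structure(list(n_control = as.integer(n_control), n_mtbi = as.integer(n_mtbi),
                 age_range = age_range, gamma = gamma,
                 sigma_log_wm = sigma_log_wm, beta = beta,
                 sigma_alps = sigma_alps, eta = eta, delta = delta, bg = bg,
                 tau = tau, rho_ratio = rho_ratio,
                 sd_alps_ratio = sd_alps_ratio, sd_psqi_ratio = sd_psqi_ratio,
                 seed = seed),
            class = "cohort_gen_spec")
}

## RPQ item ratings consistent with a target symptomatic count and memory
## flag: `n_other` non-memory items get ratings 2-4, the memory item gets
## >= 2 iff `memory`, remaining items get 0 or 1.
rpq_items_from_counts <- function(n_other, memory) {
  items <- sample(c(0L, 1L), RPQ_N_ITEMS, replace = TRUE, prob = c(0.7, 0.3))
  pool <- setdiff(seq_len(RPQ_N_ITEMS), RPQ_MEMORY_ITEM)
  n_other <- min(n_other, length(pool))
  if (n_other > 0) {
    on <- sample(pool, n_other)
    items[on] <- sample(2:4, n_other, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  }
  items[RPQ_MEMORY_ITEM] <- if (memory) {
    sample(2:4, 1, prob = c(0.5, 0.3, 0.2))
  } else {
    sample(c(0L, 1L), 1, prob = c(0.7, 0.3))
  }
  items
}

#' Generate a synthetic two-visit cohort
#'
#' Deterministic given the spec (seed included). Controls get one
#' `"control"` visit; mTBI subjects get `"14Day"` and `"6-12Mon"` visits.
#' The follow-up ALPS and PSQI are the 14Day values multiplied by a
#' correlated bivariate-normal ratio pair, so the longitudinal
#' ratio-correlation analysis recovers `rho_ratio` by construction. The
#' memory-problem flag at both visits follows one logistic model on the
#' 14Day (acute) markers, the design the chronic-outcome prediction model
#' assumes.
#'
#' @param spec A [cohort_gen_spec()].
#' @return A validated cohort data frame (class `glym_cohort`).
#' @export
make_synthetic_cohort <- function(spec = cohort_gen_spec()) {
  assert_that(inherits(spec, "cohort_gen_spec"), "spec must be a cohort_gen_spec")
  with_seed(spec$seed, {
    n <- spec$n_control + spec$n_mtbi
    subj <- sprintf("S%04d", seq_len(n))
    grp <- rep(c("control", "mTBI"), c(spec$n_control, spec$n_mtbi))
    age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    sex <- sample(c("F", "M"), n, replace = TRUE)
    education <- pmin(pmax(round(stats::rnorm(n, 15, 3)), 9), 24)
    gcs <- ifelse(grp == "mTBI",
                  sample(13:15, n, replace = TRUE, prob = c(0.05, 0.2, 0.75)),
                  NA_integer_)
    ct <- ifelse(grp == "mTBI", stats::rbinom(n, 1, 0.45), 0L)
    is_m <- grp == "mTBI"

    ## 14Day / control markers
    lwm <- spec$gamma[["intercept"]] + spec$gamma[["age"]] * age +
      spec$gamma[["mtbi"]] * is_m + stats::rnorm(n, 0, spec$sigma_log_wm)
    wm <- exp(lwm)
    alps1 <- spec$beta[["intercept"]] + spec$beta[["age"]] * age +
      stats::rnorm(n, 0, spec$sigma_alps)
    alps1 <- pmax(alps1, 0.2)
    u_bg <- stats::rnorm(n, 0, spec$tau)
    bg1 <- pmax(spec$bg[["intercept"]] + u_bg +
                  stats::rnorm(n, 0, spec$bg[["sigma"]]), 0.01)

    ## symptom counts (non-memory items) and memory flags
    lam <- exp(spec$eta[["intercept"]] + spec$eta[["wm_epvs"]] * wm +
                 spec$eta[["mtbi"]] * is_m)
    n_other1 <- pmin(stats::rpois(n, lam), RPQ_N_ITEMS - 1L)
    logit1 <- spec$delta[["intercept"]] +
      spec$delta[["education"]] * education +
      spec$delta[["ct_or_mri"]] * ct +
      spec$delta[["wm_epvs"]] * wm + spec$delta[["alps"]] * alps1
    mem1 <- stats::rbinom(n, 1, stats::plogis(logit1)) == 1
    mem2 <- stats::rbinom(n, 1, stats::plogis(logit1)) == 1  # chronic outcome,
    ## same acute-marker logit

    psqi1 <- pmin(pmax(round(stats::rnorm(n, 6.5, 3.5)), 1), 21)

    ## longitudinal ratios with target correlation
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    r_alps <- 1 + spec$sd_alps_ratio * z1
    r_psqi <- 1 + spec$sd_psqi_ratio *
      (spec$rho_ratio * z1 + sqrt(1 - spec$rho_ratio^2) * z2)
    r_alps <- pmax(r_alps, 0.05); r_psqi <- pmax(r_psqi, 0.05)

    visit_table <- function(idx, visit, wm_v, alps_v, bg_v, psqi_v,
                            n_other_v, mem_v) {
      items <- t(mapply(rpq_items_from_counts, n_other_v, mem_v))
      tab <- data.frame(subject_id = subj[idx], group = grp[idx],
                        visit = visit, age = age[idx], sex = sex[idx],
                        education = education[idx], gcs = gcs[idx],
                        ct_or_mri_positive = ct[idx],
                        stringsAsFactors = FALSE)
      tab[rpq_cols()] <- as.data.frame(items)
      tab$rpq_total <- rowSums(items)
      tab$n_symptoms <- rowSums(items >= 2)
      tab$memory_problem <- as.integer(items[, RPQ_MEMORY_ITEM] >= 2)
      tab$psqi <- psqi_v
      tab$wm_epvs <- wm_v
      tab$bg_epvs <- bg_v
      tab$alps_index <- alps_v
      tab
    }
    ic <- which(grp == "control"); im <- which(is_m)
    parts <- list()
    if (length(ic) > 0) {
      parts$control <- visit_table(ic, "control", wm[ic], alps1[ic], bg1[ic],
                                   psqi1[ic], n_other1[ic], mem1[ic])
    }
    if (length(im) > 0) {
      parts$v1 <- visit_table(im, "14Day", wm[im], alps1[im], bg1[im],
                              psqi1[im], n_other1[im], mem1[im])
      nm <- length(im)
      wm2 <- wm[im] * exp(stats::rnorm(nm, 0, 0.05))
      bg2 <- pmax(spec$bg[["intercept"]] + spec$bg[["visit"]] + u_bg[im] +
                    stats::rnorm(nm, 0, spec$bg[["sigma"]]), 0.01)
      psqi2 <- pmin(pmax(round(psqi1[im] * r_psqi[im]), 0), 21)
      n_other2 <- pmin(stats::rpois(nm, lam[im]), RPQ_N_ITEMS - 1L)
      parts$v2 <- visit_table(im, "6-12Mon", wm2, alps1[im] * r_alps[im], bg2,
                              psqi2, n_other2, mem2[im])
    }
    tab <- do.call(rbind, parts)
    rownames(tab) <- NULL
    validate_cohort(tab[order(tab$subject_id, tab$visit), ])
  })
}
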