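## End-to-end demo workflow: synthetic cohort -> per-subject phantoms ->
## marker measurement -> statistical battery -> serialisable report.

demo_stats_battery <- function(tab, boot_seed) {
  out <- list()
  safe <- function(expr) tryCatch(expr, error = function(e) {
    list(error = conditionMessage(e))
  })
  ctrl <- tab[tab$visit == "control", ]
  v1 <- tab[tab$visit == "14Day", ]

  out$group_wm <- safe({
    t <- welch_t_test(ctrl$wm_epvs, v1$wm_epvs)
    list(statistic = t$statistic, p = t$p_value, estimate = t$estimate)
  })
  out$group_alps <- safe({
    t <- welch_t_test(ctrl$alps_index, v1$alps_index)
    list(statistic = t$statistic, p = t$p_value, estimate = t$estimate)
  })
  out$age_wm_control <- safe({
    t <- pearson_correlation(ctrl$age, log(ctrl$wm_epvs))
    list(r = t$estimate, p = t$p_value)
  })
  out$age_alps_control <- safe({
    t <- pearson_correlation(ctrl$age, ctrl$alps_index)
    list(r = t$estimate, p = t$p_value)
  })
  out$symptoms_wm_14day <- safe({
    t <- adjusted_association(v1$n_symptoms, v1$wm_epvs,
                              covariates = data.frame(age = v1$age,
                                                      sex = v1$sex == "M"))
    list(slope = t$estimate, partial_r = t$partial_r, p = t$p_value)
  })
  out$visit_effect_bg <- safe({
    t <- fit_lmm_visit(tab, "bg_epvs")
    list(estimate = t$estimate, p = t$p_value, tau = t$tau)
  })
  out$ratio_alps_psqi <- safe({
    t <- ratio_change_correlation(tab, "alps_index", "psqi")
    list(r = t$estimate, p = t$p_value, n_pairs = t$n_pairs)
  })
  out$prediction <- safe({
    v2 <- tab[tab$visit == "6-12Mon", ]
    dat <- v1[match(v2$subject_id, v1$subject_id), ]
    dat$memory_6_12mon <- v2$memory_problem
    dat$sex_male <- as.integer(dat$sex == "M")
    basic <- c("age", "sex_male", "education", "gcs", "ct_or_mri_positive")
    markers <- c("wm_epvs", "bg_epvs", "alps_index")
    m1 <- stepwise_logistic(dat, "memory_6_12mon", basic)
    m2 <- stepwise_logistic(dat, "memory_6_12mon", c(basic, markers))
    s1 <- stats::predict(m1$fit, newdata = dat, type = "response")
    s2 <- stats::predict(m2$fit, newdata = dat, type = "response")
    cmp <- compare_auc_bootstrap(s1, s2, dat$memory_6_12mon,
                                 n_boot = 500, seed = boot_seed)
    list(model1_selected = m1$selected, model2_selected = m2$selected,
         model2_coefs = m2$coef_table,
         auc_model1 = cmp$auc_a, auc_model2 = cmp$auc_b,
         delta_auc = cmp$estimate, p_compare = cmp$p_value)
  })
  ## FDR within the demo's association family
  fam <- c("age_wm_control", "age_alps_control", "symptoms_wm_14day",
           "visit_effect_bg", "ratio_alps_psqi")
  ps <- vapply(fam, function(k) {
    p <- out[[k]]$p
    if (is.null(p)) NA_real_ else p
  }, numeric(1))
  out$fdr_adjusted <- as.list(stats::setNames(fdr_adjust(ps), fam))
  out
}

#' Run the end-to-end synthetic demo
#'
#' Generates a two-visit cohort, measures the glymphatic markers of a subset
#' of subjects from per-subject phantoms (structural phantoms segmented by
#' the calibrated ePVS pipeline; DWI phantoms fitted by the kurtosis
#' pipeline), runs the statistical battery on the resulting table, and
#' returns (optionally writes) a serialisable report. Bit-reproducible for
#' a fixed seed.
#'
#' @param cohort_spec A [cohort_gen_spec()]; its seed is overridden by
#'   `seed`.
#' @param seed Master seed for the whole demo.
#' @param n_imaging_subjects How many subjects get phantom-measured markers
#'   (the rest keep their generator values as measured values); `0` skips
#'   imaging entirely, `Inf` images everyone.
#' @param structural_shape Grid of the per-subject structural phantoms.
#' @param dwi_snr Rician SNR of the per-subject DWI phantoms.
#' @param out_dir If non-`NULL`, writes `metrics.json`, `cohort.csv` and
#'   `manifest.json` there.
#' @return An object of class `glym_demo_report`: list with the measured
#'   cohort table, the statistics, imaging diagnostics, and the manifest.
#' @export
run_demo <- function(cohort_spec = cohort_gen_spec(n_control = 10, n_mtbi = 10),
                     seed = 1L, n_imaging_subjects = 6,
                     structural_shape = c(64, 64, 64), dwi_snr = 30,
                     out_dir = NULL) {
  manifest <- new_manifest()
  cohort_spec$seed <- seed
  tab <- make_synthetic_cohort(cohort_spec)
  manifest <- manifest_add(manifest, "cohort",
                           params = list(seed = seed,
                                         n_control = cohort_spec$n_control,
                                         n_mtbi = cohort_spec$n_mtbi),
                           inputs = list(cohort = content_digest(tab)))
  imaging <- list()
  subjects <- unique(tab$subject_id)
  n_img <- min(length(subjects), n_imaging_subjects)
  if (n_img > 0) {
    img_subjects <- subjects[seq_len(n_img)]
    ## one calibration phantom fixes the vesselness threshold for all runs
    ## noise-free calibration phantom with the same tube geometry as the
    ## subject phantoms: the calibrated threshold sits on the tube response,
    ## well above the noise tail
    cal_spec <- structural_phantom_spec(shape = structural_shape,
                                        pvs_count = c(WM = 25, BG = 3),
                                        pvs_radius_mm = c(0.5, 0.8),
                                        pvs_length_mm = c(5, 10),
                                        noise_sigma = c(t1w = 0, t2w = 0),
                                        seed = seed + 77777L)
    cal <- make_structural_phantom(cal_spec)
    cal_res <- run_epvs(cal$t1w, cal$t2w, cal$labels, regions = "WM")
    h_cal <- calibrate_threshold(cal_res$vesselness,
                                 region_mask(cal$labels, "WM"),
                                 cal$true_burden[["WM"]])
    ## freeze the vesselness scaling of the calibration run so the absolute
    ## threshold transfers to the (noisy) subject phantoms
    frangi_cal <- frangi_params(c = attr(cal_res$vesselness, "c_used"))
    manifest <- manifest_add(manifest, "epvs_calibration",
                             params = list(h = as.numeric(h_cal),
                                           c = attr(cal_res$vesselness, "c_used")))
    for (k in seq_along(img_subjects)) {
      sid <- img_subjects[k]
      rows <- which(tab$subject_id == sid)
      for (ri in rows) {
        vseed <- seed + 1000L * k + match(tab$visit[ri], VALID_VISITS)
        truth_wm <- tab$wm_epvs[ri]
        sp <- structural_phantom_spec(
          shape = structural_shape,
          pvs_count = c(WM = max(1, min(80, round(truth_wm * 60))), BG = 2),
          pvs_radius_mm = c(0.5, 0.8), pvs_length_mm = c(5, 10),
          noise_sigma = c(t1w = 0.01, t2w = 0.015), seed = vseed)
        phs <- make_structural_phantom(sp)
        seg <- run_epvs(phs$t1w, phs$t2w, phs$labels, regions = c("WM", "BG"),
                        frangi = frangi_cal,
                        seg_params = list(
                          WM = segmentation_params(h = as.numeric(h_cal)),
                          BG = segmentation_params(h = as.numeric(h_cal) * 1.5)))
        tab$wm_epvs[ri] <- seg$regions$WM$burden_pct
        tab$bg_epvs[ri] <- seg$regions$BG$burden_pct
        truth_alps <- tab$alps_index[ri]
        spd <- make_alps_tensor_field(truth_alps * 1.0e-3, 1.0e-3, 1.5e-3,
                                      truth_alps * 1.0e-3, 1.5e-3, 1.0e-3,
                                      snr = dwi_snr, noise_model = "rician",
                                      seed = vseed)
        phd <- make_dwi_phantom(spd)
        ares <- suppressWarnings(
          run_alps(phd$dwi, phd$gtab, phd$mask, phd$spacing,
                   attr(spd, "roi_centers")))
        tab$alps_index[ri] <- ares$alps_index
        imaging[[length(imaging) + 1L]] <-
          list(subject = sid, visit = tab$visit[ri],
               wm_true = truth_wm, wm_measured = seg$regions$WM$burden_pct,
               alps_true = truth_alps, alps_measured = ares$alps_index)
      }
    }
    manifest <- manifest_add(manifest, "imaging",
                             params = list(n_imaging_subjects = n_img,
                                           structural_shape = structural_shape,
                                           dwi_snr = dwi_snr))
  }
  stats <- demo_stats_battery(tab, boot_seed = seed + 424242L)
  manifest <- manifest_add(manifest, "stats",
                           inputs = list(table = content_digest(tab)))
  report <- structure(list(cohort = tab, stats = stats, imaging = imaging,
                           seed = seed, manifest = manifest),
                      class = "glym_demo_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(seed = seed, stats = stats, imaging = imaging),
      file.path(out_dir, "metrics.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
    write_cohort_table(tab, file.path(out_dir, "cohort.csv"), overwrite = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

#' @export
print.glym_demo_report <- function(x, ...) {
  cat(sprintf("<glym_demo_report> seed %d, %d rows, %d imaged visits\n",
              x$seed, nrow(x$cohort), length(x$imaging)))
  if (!is.null(x$stats$prediction$auc_model1)) {
    cat(sprintf("  memory prediction AUC: basic %.3f, + markers %.3f (p = %.3g)\n",
                x$stats$prediction$auc_model1, x$stats$prediction$auc_model2,
                x$stats$prediction$p_compare))
  }
  invisible(x)
}

#' Validate a bundle of pipeline inputs
#'
#' Runs the named consistency checks (grid agreement, gradient-table sanity,
#' cohort schema) and returns a check table; nothing is thrown, so callers
#' can enumerate all failures at once.
#'
#' @param t1w,t2w Optional [glym_volume()]s.
#' @param labels Optional [glym_labelmap()].
#' @param dwi Optional 4-D array.
#' @param gtab Optional [gradient_table()].
#' @param cohort Optional cohort data frame.
#' @return Data frame with columns `check`, `ok`, `message`; attribute
#'   `all_ok`.
#' @export
validate_inputs <- function(t1w = NULL, t2w = NULL, labels = NULL,
                            dwi = NULL, gtab = NULL, cohort = NULL) {
  checks <- list()
  add <- function(name, expr) {
    res <- tryCatch({ force(expr); list(ok = TRUE, msg = "ok") },
                    error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
    checks[[length(checks) + 1L]] <<- data.frame(check = name, ok = res$ok,
                                                 message = res$msg)
  }
  if (!is.null(t1w) && !is.null(t2w)) {
    add("t1w_t2w_same_grid",
        assert_that(same_grid(t1w, t2w), "T1w and T2w grids differ"))
  }
  if (!is.null(t1w) && !is.null(labels)) {
    add("labels_same_grid",
        assert_that(same_grid(t1w, labels), "labels not on the T1w grid"))
  }
  if (!is.null(labels)) {
    add("labels_have_wm",
        assert_that(any(labels$legend == "WM"), "no WM region in legend"))
  }
  if (!is.null(gtab)) {
    add("gradient_table_valid",
        gradient_table(gtab$bval, rbind(gtab$gx, gtab$gy, gtab$gz)))
  }
  if (!is.null(dwi) && !is.null(gtab)) {
    add("dwi_matches_gradients",
        assert_that(dim(dwi)[4] == nrow(gtab),
                    "DWI has %d volumes, gradient table %d entries",
                    dim(dwi)[4], nrow(gtab)))
  }
  if (!is.null(cohort)) {
    add("cohort_schema", validate_cohort(cohort))
  }
  out <- do.call(rbind, checks)
  if (is.null(out)) out <- data.frame(check = character(), ok = logical(),
                                      message = character())
  attr(out, "all_ok") <- all(out$ok)
  out
}
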