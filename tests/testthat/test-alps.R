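roi_centers_default <- function() {
  list(proj_left = c(-8, 0, 0), proj_right = c(8, 0, 0),
       assoc_left = c(-20, 0, 0), assoc_right = c(20, 0, 0))
}

test_that("ROI voxel counts follow the area / spacing arithmetic", {
  r1 <- make_alps_rois(c(64, 64, 16), c(1, 1, 1), roi_centers_default())
  expect_equal(r1$n_side, 4)                  # 16 mm^2 on a 1 mm grid
  expect_equal(sum(r1$proj_left), 16)
  r2 <- make_alps_rois(c(40, 32, 12), c(2, 2, 2), roi_centers_default())
  expect_equal(r2$n_side, 2)                  # 2 x 2 voxels on a 2 mm grid
  expect_equal(sum(r2$proj_left), 4)

  ## left/right mirror symmetry about the midsagittal plane
  nx <- 40
  expect_identical(r2$proj_right, r2$proj_left[nx:1, , ])
  expect_identical(r2$assoc_right, r2$assoc_left[nx:1, , ])

  ctr <- roi_centers_default(); ctr$proj_left <- c(-200, 0, 0)
  expect_error(make_alps_rois(c(40, 32, 12), c(2, 2, 2), ctr), "outside")
})

test_that("isotropic tensor fields give ALPS exactly 1", {
  spec <- make_alps_tensor_field(1e-3, 1e-3, 1e-3, 1e-3, 1e-3, 1e-3)
  ph <- make_dwi_phantom(spec)
  res <- run_alps(ph$dwi, ph$gtab, ph$mask, ph$spacing, attr(spec, "roi_centers"))
  expect_equal(res$alps_index, 1, tolerance = 1e-9)
})

test_that("noiseless anisotropic field recovers the analytic ALPS", {
  spec <- make_alps_tensor_field(1.5e-3, 1.0e-3, 1.5e-3, 1.5e-3, 1.5e-3, 1.0e-3)
  ph <- make_dwi_phantom(spec)
  for (fit in c("dki", "dti")) {
    res <- run_alps(ph$dwi, ph$gtab, ph$mask, ph$spacing,
                    attr(spec, "roi_centers"), fit = fit)
    expect_equal(res$alps_index, 1.5, tolerance = 1e-9)
  }
})

test_that("ALPS is scale-invariant and symmetric in the stored means", {
  spec <- make_alps_tensor_field(1.2e-3, 0.9e-3, 1.5e-3, 1.4e-3, 1.5e-3, 1.1e-3)
  ph <- make_dwi_phantom(spec)
  res <- run_alps(ph$dwi, ph$gtab, ph$mask, ph$spacing, attr(spec, "roi_centers"))
  ## index recomputable from its own stored means
  b <- res$bilateral_means
  expect_equal(res$alps_index,
               ((b$dxx_proj + b$dxx_assoc) / 2) / ((b$dyy_proj + b$dzz_assoc) / 2))

  spec_k <- make_alps_tensor_field(3 * 1.2e-3, 3 * 0.9e-3, 3 * 1.5e-3,
                                   3 * 1.4e-3, 3 * 1.5e-3, 3 * 1.1e-3)
  ## scaling all diffusivities by 3 must not move the index
  ph_k <- make_dwi_phantom(spec_k)
  res_k <- run_alps(ph_k$dwi, ph_k$gtab, ph_k$mask, ph_k$spacing,
                    attr(spec_k, "roi_centers"))
  expect_equal(res_k$alps_index, res$alps_index, tolerance = 1e-9)
})

test_that("swapping left and right ROIs leaves the index unchanged", {
  spec <- make_alps_tensor_field(1.3e-3, 1.0e-3, 1.5e-3, 1.3e-3, 1.5e-3, 1.0e-3,
                                 snr = 40, noise_model = "rician", seed = 2)
  ph <- make_dwi_phantom(spec)
  tf <- suppressWarnings(fit_dki_lls(ph$dwi, ph$gtab, ph$mask))
  maps <- extract_diffusivity_maps(tf)
  rois <- make_alps_rois(dim(ph$dwi)[1:3], ph$spacing, attr(spec, "roi_centers"))
  swapped <- rois
  swapped$proj_left <- rois$proj_right; swapped$proj_right <- rois$proj_left
  swapped$assoc_left <- rois$assoc_right; swapped$assoc_right <- rois$assoc_left
  r1 <- compute_alps_index(maps, rois, fit_mask = tf$mask)
  r2 <- compute_alps_index(maps, swapped, fit_mask = tf$mask)
  expect_equal(r1$alps_index, r2$alps_index, tolerance = 1e-12)
})

test_that("per-side averaging agrees with bilateral averaging on symmetric fields", {
  spec <- make_alps_tensor_field(1.4e-3, 1.0e-3, 1.5e-3, 1.4e-3, 1.5e-3, 1.0e-3)
  ph <- make_dwi_phantom(spec)
  tf <- fit_dki_lls(ph$dwi, ph$gtab, ph$mask)
  maps <- extract_diffusivity_maps(tf)
  rois <- make_alps_rois(dim(ph$dwi)[1:3], ph$spacing, attr(spec, "roi_centers"))
  a <- compute_alps_index(maps, rois, fit_mask = tf$mask, side_average = "before_ratio")
  b <- compute_alps_index(maps, rois, fit_mask = tf$mask, side_average = "per_side")
  expect_equal(a$alps_index, b$alps_index, tolerance = 1e-9)
})

test_that("empty ROI-mask intersections and bad denominators error", {
  spec <- make_alps_tensor_field(1.3e-3, 1e-3, 1.3e-3, 1.3e-3, 1.3e-3, 1e-3)
  ph <- make_dwi_phantom(spec)
  tf <- fit_dki_lls(ph$dwi, ph$gtab, ph$mask)
  maps <- extract_diffusivity_maps(tf)
  rois <- make_alps_rois(dim(ph$dwi)[1:3], ph$spacing, attr(spec, "roi_centers"))
  expect_error(compute_alps_index(maps, rois,
                                  fit_mask = array(FALSE, dim(ph$dwi)[1:3])),
               "fit mask")
})
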