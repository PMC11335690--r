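test_that("structural phantom is a pure function of its spec", {
  spec <- structural_phantom_spec(shape = c(48, 48, 48),
                                  pvs_count = c(WM = 4, BG = 0),
                                  margin_voxels = c(WM = 4, BG = 2), seed = 3)
  a <- make_structural_phantom(spec)
  b <- make_structural_phantom(spec)
  expect_identical(a$t1w$data, b$t1w$data)
  expect_identical(a$t2w$data, b$t2w$data)
  expect_identical(a$pvs_truth, b$pvs_truth)
})

test_that("zero tube count gives empty truth and zero burden", {
  spec <- structural_phantom_spec(shape = c(48, 48, 48),
                                  pvs_count = c(WM = 0, BG = 0),
                                  noise_sigma = c(t1w = 0, t2w = 0))
  ph <- make_structural_phantom(spec)
  expect_false(any(ph$pvs_truth))
  expect_equal(unname(ph$true_burden), c(0, 0))
})

test_that("supersampled cylinder volume matches the analytic volume", {
  ## one axial tube, radius 1 mm, length 10 mm, in a large WM block
  spec <- structural_phantom_spec(shape = c(64, 64, 64), spacing = c(1, 1, 1),
                                  pvs_count = c(WM = 1),
                                  pvs_radius_mm = c(1, 1),
                                  pvs_length_mm = c(10, 10),
                                  orientation = "axial",
                                  noise_sigma = c(t1w = 0, t2w = 0),
                                  margin_voxels = c(WM = 6), seed = 11)
  ph <- make_structural_phantom(spec)
  vol_true <- pi * 1^2 * 10                    # 31.416 mm^3
  vol_est <- sum(ph$pvs_fraction) * prod(spec$spacing)
  expect_lt(abs(vol_est - vol_true) / vol_true, 0.02)
  ## truth lies inside WM + BG support
  region <- ph$labels$labels %in% c(1L, 3L)
  expect_true(all(region[ph$pvs_truth]))
})

test_that("true burden is consistent with the rendered fraction", {
  spec <- structural_phantom_spec(shape = c(48, 48, 48),
                                  pvs_count = c(WM = 5),
                                  noise_sigma = c(t1w = 0, t2w = 0),
                                  margin_voxels = c(WM = 5), seed = 9)
  ph <- make_structural_phantom(spec)
  wm <- ph$labels$labels == 1L
  expect_equal(ph$true_burden[["WM"]], 100 * sum(ph$pvs_fraction[wm]) / sum(wm))
  expect_gte(ph$true_burden[["WM"]], 0)
  expect_lte(ph$true_burden[["WM"]], 100)
})

test_that("noiseless DWI phantom reproduces the forward model exactly", {
  gt <- default_gradient_table()
  lab <- array(1L, c(3, 3, 3))
  reg <- list(`1` = list(D = c(1e-3, 1e-3, 1e-3, 0, 0, 0), S0 = 800))
  ph <- make_dwi_phantom(dwi_phantom_spec(lab, reg, gt))
  ## b = 0 volumes equal S0 exactly
  expect_equal(unique(as.vector(ph$dwi[, , , gt$bval == 0])), 800)
  ## isotropic D = 1e-3, b = 1000: S/S0 = exp(-1)
  i1000 <- which(gt$bval == 1000)[1]
  expect_equal(ph$dwi[1, 1, 1, i1000] / 800, exp(-1), tolerance = 1e-12)
  i2500 <- which(gt$bval == 2500)[1]
  expect_equal(ph$dwi[1, 1, 1, i2500] / 800, exp(-2.5), tolerance = 1e-12)
})

test_that("rician mode matches the Rician mean at b = 0", {
  gt <- gradient_table(c(0, 0), matrix(0, 3, 2))
  lab <- array(1L, c(22, 22, 22))             # ~1e4 voxels
  reg <- list(`1` = list(D = c(1e-3, 1e-3, 1e-3, 0, 0, 0), S0 = 1000))
  ph <- make_dwi_phantom(dwi_phantom_spec(lab, reg, gt, snr = 50,
                                          noise_model = "rician", seed = 21))
  expect_equal(mean(ph$dwi[, , , 1]),
               oracle_rician_mean(1000, 1000 / 50), tolerance = 0.01)
})

test_that("unphysical kurtosis for the b-range is rejected by region", {
  gt <- default_gradient_table()
  lab <- array(1L, c(2, 2, 2))
  reg <- list(`1` = list(D = c(1e-3, 1e-3, 1e-3, 0, 0, 0), K = 5, S0 = 100))
  expect_error(make_dwi_phantom(dwi_phantom_spec(lab, reg, gt)),
               "region 1")
})

test_that("tensor specs are validated", {
  gt <- default_gradient_table()
  lab <- array(1L, c(2, 2, 2))
  bad <- list(`1` = list(D = c(-1e-3, 1e-3, 1e-3, 0, 0, 0), S0 = 100))
  expect_error(dwi_phantom_spec(lab, bad, gt), "positive-definite")
  expect_error(dwi_phantom_spec(lab, list(`1` = list(D = c(1e-3, 1e-3, 1e-3, 0, 0, 0), S0 = 100)),
                                gt, snr = -2, noise_model = "rician"), "snr")
})

test_that("ALPS tensor-field ground truths follow the closed form", {
  iso <- make_alps_tensor_field(1e-3, 1e-3, 1e-3, 1e-3, 1e-3, 1e-3)
  expect_equal(attr(iso, "alps_truth"), 1)
  hi <- make_alps_tensor_field(1.5e-3, 1.0e-3, 1.5e-3, 1.5e-3, 1.5e-3, 1.0e-3)
  expect_equal(attr(hi, "alps_truth"), 1.5)
  mix <- make_alps_tensor_field(1.2e-3, 0.9e-3, 1.5e-3, 1.4e-3, 1.5e-3, 1.1e-3)
  expect_equal(attr(mix, "alps_truth"), 1.3)
  expect_error(make_alps_tensor_field(-1e-3, 1e-3, 1e-3, 1e-3, 1e-3, 1e-3),
               "positive")
})

test_that("DWI phantoms are bit-reproducible given the seed", {
  spec <- make_alps_tensor_field(1.4e-3, 1e-3, 1.4e-3, 1.4e-3, 1.4e-3, 1e-3,
                                 snr = 20, noise_model = "rician", seed = 33)
  a <- make_dwi_phantom(spec)
  b <- make_dwi_phantom(spec)
  expect_identical(a$dwi, b$dwi)
})
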