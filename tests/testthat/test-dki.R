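single_region_phantom <- function(D6, K = NULL, S0 = 1000, dims = c(4, 4, 4),
                                  gtab = default_gradient_table(), ...) {
  lab <- array(1L, dims)
  reg <- list(`1` = c(list(D = D6, S0 = S0), if (!is.null(K)) list(K = K)))
  make_dwi_phantom(dwi_phantom_spec(lab, reg, gtab, ...))
}

test_that("noiseless DTI fit inverts the forward model to machine precision", {
  D6 <- c(1.5e-3, 0.4e-3, 0.4e-3, 0, 0, 0)
  ph <- single_region_phantom(D6)
  tf <- fit_dti_wls(ph$dwi, ph$gtab, ph$mask)
  expect_lt(max(abs(tf$D[2, 2, 2, ] - D6)), 1e-9)
  expect_equal(tf$s0[2, 2, 2], 1000, tolerance = 1e-9)

  iso <- c(0.9e-3, 0.9e-3, 0.9e-3, 0, 0, 0)
  ph2 <- single_region_phantom(iso)
  tf2 <- fit_dti_wls(ph2$dwi, ph2$gtab, ph2$mask)
  md <- mean(tf2$D[1, 1, 1, 1:3])
  expect_equal(md, 0.9e-3, tolerance = 1e-12)
})

test_that("DTI WLS has small median bias under Rician noise", {
  gt <- default_gradient_table(n_b0 = 2, n_inner = 45, n_outer = 0)
  gt <- gt[gt$bval <= 1000, ]
  class(gt) <- c("glym_gradients", "data.frame")
  D6 <- c(1.5e-3, 0.8e-3, 0.8e-3, 0, 0, 0)
  ph <- single_region_phantom(D6, dims = c(22, 22, 22), gtab = gt,
                              snr = 30, noise_model = "rician", seed = 6)
  tf <- suppressWarnings(fit_dti_wls(ph$dwi, ph$gtab, ph$mask))
  dxx <- tf$D[, , , 1]
  expect_lt(abs(median(dxx) - 1.5e-3) / 1.5e-3, 0.03)
})

test_that("noiseless DKI fit recovers D and K exactly and nests DTI", {
  ph <- single_region_phantom(c(1e-3, 1e-3, 1e-3, 0, 0, 0), K = 1)
  tf <- fit_dki_lls(ph$dwi, ph$gtab, ph$mask)
  expect_lt(max(abs(tf$D[2, 2, 2, 1:3] - 1e-3)), 1e-8)
  mk <- mean_kurtosis(tf)
  expect_lt(abs(mk[2, 2, 2] - 1), 1e-8)

  ## K = 0 phantom: DKI and DTI agree
  ph0 <- single_region_phantom(c(1.3e-3, 0.7e-3, 1.0e-3, 0.1e-3, 0, 0))
  t_dki <- fit_dki_lls(ph0$dwi, ph0$gtab, ph0$mask)
  t_dti <- fit_dti_wls(ph0$dwi, ph0$gtab, ph0$mask)
  expect_lt(max(abs(t_dki$D[2, 2, 2, ] - t_dti$D[2, 2, 2, ])), 1e-8)
  expect_lt(max(abs(mean_kurtosis(t_dki)[2, 2, 2])), 1e-8)
})

test_that("the two-shell scheme yields a well-posed kurtosis design", {
  X <- glymkit:::dki_design(default_gradient_table())
  expect_equal(qr(X)$rank, 22)
  expect_lt(kappa(X), 1e8)
})

test_that("single-shell input is rejected with advice", {
  gt <- default_gradient_table(n_outer = 0)
  gt <- gt[gt$bval <= 1000, ]; class(gt) <- c("glym_gradients", "data.frame")
  ph <- single_region_phantom(c(1e-3, 1e-3, 1e-3, 0, 0, 0), gtab = gt)
  expect_error(fit_dki_lls(ph$dwi, ph$gtab, ph$mask), "fit_dti_wls")
})

test_that("diffusivity maps are tensor diagonals, not eigenvalues", {
  D6 <- c(1.2e-3, 0.8e-3, 1.0e-3, 0.3e-3, 0.2e-3, 0.1e-3)
  ph <- single_region_phantom(D6)
  tf <- fit_dti_wls(ph$dwi, ph$gtab, ph$mask)
  maps <- extract_diffusivity_maps(tf)
  expect_equal(maps$dxx$data[2, 2, 2], D6[1], tolerance = 1e-9)
  expect_equal(maps$dyy$data[2, 2, 2], D6[2], tolerance = 1e-9)
  expect_equal(maps$dzz$data[2, 2, 2], D6[3], tolerance = 1e-9)

  ## rotating the tensor 90 degrees about z swaps Dxx and Dyy
  R <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  Dm <- glymkit:::d6_to_matrix(D6)
  Dr <- R %*% Dm %*% t(R)
  D6r <- c(Dr[1, 1], Dr[2, 2], Dr[3, 3], Dr[1, 2], Dr[1, 3], Dr[2, 3])
  phr <- single_region_phantom(D6r)
  tfr <- fit_dti_wls(phr$dwi, phr$gtab, phr$mask)
  mapsr <- extract_diffusivity_maps(tfr)
  expect_equal(mapsr$dxx$data[2, 2, 2], maps$dyy$data[2, 2, 2], tolerance = 1e-9)
  expect_equal(mapsr$dyy$data[2, 2, 2], maps$dxx$data[2, 2, 2], tolerance = 1e-9)
  expect_equal(mapsr$dzz$data[2, 2, 2], maps$dzz$data[2, 2, 2], tolerance = 1e-9)

  ## changing only off-diagonals leaves the diagonal maps unchanged
  D6b <- D6; D6b[4:6] <- c(0.05e-3, 0.15e-3, 0.02e-3)
  phb <- single_region_phantom(D6b)
  tfb <- fit_dti_wls(phb$dwi, phb$gtab, phb$mask)
  mapsb <- extract_diffusivity_maps(tfb)
  expect_equal(mapsb$dxx$data[2, 2, 2], D6[1], tolerance = 1e-9)
})

test_that("non-positive signals are clipped and counted, not fatal", {
  ph <- single_region_phantom(c(1e-3, 1e-3, 1e-3, 0, 0, 0))
  dwi <- ph$dwi
  dwi[1, 1, 1, 5] <- 0
  expect_warning(tf <- fit_dti_wls(dwi, ph$gtab, ph$mask), "clipped")
  expect_equal(tf$n_clipped, 1)
})

test_that("rician floor correction is the identity on noiseless data", {
  ph <- single_region_phantom(c(1e-3, 1e-3, 1e-3, 0, 0, 0))
  out <- rician_floor_correct(ph$dwi, ph$gtab, pool_radius = 2)
  expect_equal(attr(out, "sigma"), 0)
  expect_identical(as.vector(out), as.vector(ph$dwi))
})
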