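## Analytic test images: Gaussian-profile structures of amplitude A and
## profile sd w (mm), dark on a bright background, sampled on an isotropic
## grid.
analytic_image <- function(kind, n = 33, spacing = 0.7, A = 1, w = 1) {
  ctr <- (n - 1) / 2
  ax <- ((0:(n - 1)) - ctr) * spacing
  X <- array(ax, c(n, n, n))
  Y <- array(rep(ax, each = n), c(n, n, n))
  Z <- array(rep(ax, each = n * n), c(n, n, n))
  r2 <- switch(kind, tube = X^2 + Y^2, blob = X^2 + Y^2 + Z^2, plate = X^2)
  glym_volume(1 - A * exp(-r2 / (2 * w^2)), spacing = rep(spacing, 3))
}

test_that("constant and empty-structure volumes give zero vesselness", {
  v <- glym_volume(array(3.7, c(12, 12, 12)), spacing = c(0.7, 0.7, 0.7))
  expect_true(all(frangi_vesselness(v)$data == 0))
})

test_that("tubes score higher than blobs; plates are suppressed", {
  p <- frangi_params(scales = c(0.7, 1.05), c = 0.5)
  ctr <- c(17, 17, 17)
  v_tube <- frangi_vesselness(analytic_image("tube"), p)$data[ctr[1], ctr[2], ctr[3]]
  v_blob <- frangi_vesselness(analytic_image("blob"), p)$data[ctr[1], ctr[2], ctr[3]]
  v_plate <- frangi_vesselness(analytic_image("plate"), p)$data[ctr[1], ctr[2], ctr[3]]
  expect_gt(v_tube, v_blob)
  expect_lt(v_plate, 0.05 * v_tube)

  ## centre vesselness agrees with the closed-form Hessian-eigenvalue oracle
  ## (best over the two scales), within discretisation error
  o_tube <- max(sapply(c(0.7, 1.05), function(s)
    oracle_vesselness_center("tube", 1, 1, s, cc = 0.5)))
  o_blob <- max(sapply(c(0.7, 1.05), function(s)
    oracle_vesselness_center("blob", 1, 1, s, cc = 0.5)))
  expect_equal(v_tube, o_tube, tolerance = 0.05)
  expect_equal(v_blob, o_blob, tolerance = 0.05)
})

test_that("Hessian eigenvalues at a tube axis match the analytic values", {
  sigma <- 0.7; w <- 1; spacing <- 0.7
  img <- analytic_image("tube", n = 33, spacing = spacing, w = w)
  h <- glymkit:::hessian_at_scale(-img$data + 1, rep(spacing, 3), sigma)
  ctr <- 17
  s2 <- sigma^2 + w^2
  lam_expect <- -sigma^2 * (w^2 / s2) / s2     # transverse eigenvalue
  expect_equal(h$xx[ctr, ctr, ctr], lam_expect, tolerance = 0.02)
  expect_equal(h$yy[ctr, ctr, ctr], lam_expect, tolerance = 0.02)
  expect_equal(h$zz[ctr, ctr, ctr], 0, tolerance = 1e-6)
  expect_equal(h$xy[ctr, ctr, ctr], 0, tolerance = 1e-6)
})

test_that("vesselness is equivariant under axis-aligned rotations", {
  p <- frangi_params(scales = c(0.7), c = 0.5)
  img <- analytic_image("tube", n = 21)
  v1 <- frangi_vesselness(img, p)$data
  ## rotate the volume 90 degrees about x (y -> z, z -> -y)
  rot <- function(a) {
    b <- aperm(a, c(1, 3, 2))
    b[, , dim(b)[3]:1]
  }
  img_rot <- glym_volume(rot(img$data), spacing = img$spacing)
  v2 <- frangi_vesselness(img_rot, p)$data
  expect_lt(max(abs(v2 - rot(v1))), 1e-6)
})

test_that("vesselness is nonnegative and zero where the sign condition fails", {
  set.seed(4)
  v <- glym_volume(array(rnorm(16^3), c(16, 16, 16)), spacing = rep(1, 3))
  out <- frangi_vesselness(v, frangi_params(scales = 1, c = 1,
                                            polarity = "bright_tubes"))
  expect_true(all(out$data >= 0))
  h <- glymkit:::hessian_at_scale(v$data, rep(1, 3), 1)
  e <- glymkit:::eig3sym_absorder(h$xx, h$yy, h$zz, h$xy, h$xz, h$yz)
  bad <- array(e$l2 > 0 | e$l3 > 0, dim(v$data))
  expect_true(all(out$data[bad] == 0))
})
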