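## Diffusion-signal forward model and DWI phantom generation.
##
## Signal model (per voxel, direction g, b-value b):
##   log S = log S0 - b * Dapp(g) + (1/6) * b^2 * MD^2 * Wapp(g)
## with Dapp(g) = g' D g, MD = tr(D)/3, and Wapp(g) the fourth-order kurtosis
## tensor W contracted four times with g. The directional kurtosis is
## K(g) = Wapp(g) * MD^2 / Dapp(g)^2, so an isotropic W with Wapp = K0 and an
## isotropic D give K(g) = K0 in every direction.

## Canonical ordering of the 15 unique components of the symmetric 4th-order
## kurtosis tensor, with their index quadruples and permutation multiplicities.
w_component_table <- function() {
  data.frame(
    i = c(1, 2, 3, 1, 1, 1, 2, 1, 2, 1, 1, 2, 1, 1, 1),
    j = c(1, 2, 3, 1, 1, 2, 2, 3, 3, 1, 1, 2, 1, 2, 2),
    k = c(1, 2, 3, 1, 1, 2, 2, 3, 3, 2, 3, 3, 2, 2, 3),
    l = c(1, 2, 3, 2, 3, 2, 3, 3, 3, 2, 3, 3, 3, 3, 3),
    mult = c(1, 1, 1, 4, 4, 4, 4, 4, 4, 6, 6, 6, 12, 12, 12)
  )
}

## Row of g (x) g (x) g (x) g monomials, weighted by multiplicity, for each
## gradient direction: Wapp(g) = w4_row(g) %*% W15.
w4_design <- function(gx, gy, gz) {
  tab <- w_component_table()
  g <- cbind(gx, gy, gz)
  out <- matrix(0, length(gx), nrow(tab))
  for (c_i in seq_len(nrow(tab))) {
    out[, c_i] <- tab$mult[c_i] *
      g[, tab$i[c_i]] * g[, tab$j[c_i]] * g[, tab$k[c_i]] * g[, tab$l[c_i]]
  }
  out
}

## Isotropic kurtosis tensor with Wapp(g) = k0 for all unit g.
isotropic_w15 <- function(k0) {
  w <- numeric(15)
  w[1:3] <- k0            # W_iiii
  w[10:12] <- k0 / 3      # W_iijj
  w
}

## Dapp design row: Dapp(g) = d_row(g) %*% D6 with D6 = (xx,yy,zz,xy,xz,yz).
d_design <- function(gx, gy, gz) {
  cbind(gx^2, gy^2, gz^2, 2 * gx * gy, 2 * gx * gz, 2 * gy * gz)
}

d6_to_matrix <- function(d6) {
  matrix(c(d6[1], d6[4], d6[5],
           d6[4], d6[2], d6[6],
           d6[5], d6[6], d6[3]), 3, 3)
}

assert_spd <- function(d6, label = "tensor") {
  ev <- eigen(d6_to_matrix(d6), symmetric = TRUE, only.values = TRUE)$values
  assert_that(all(ev > 0), "%s is not symmetric positive-definite", label)
}

#' Specification for a DWI phantom
#'
#' A labelled grid where each region carries one diffusion tensor (and
#' optionally a kurtosis tensor) and an S0; the forward model above generates
#' the 4-D series. Noise is Rician by default (magnitude of a complex
#' Gaussian perturbation with per-channel sd `S0_region / snr`), Gaussian and
#' noiseless modes exist for analytic checks.
#'
#' @param labels 3-D integer array of region ids (0 allowed; voxels labelled 0
#'   produce zero signal and are excluded from the fit mask).
#' @param regions Named list, one entry per region id (names are the ids as
#'   strings): each a list with `D` (6 components, mm^2/s, order
#'   xx,yy,zz,xy,xz,yz), optional `K` (scalar isotropic kurtosis) or `W`
#'   (15 components), and `S0`.
#' @param gtab A [gradient_table()].
#' @param spacing Voxel size mm.
#' @param snr S0-to-noise ratio at b = 0 (per region); required when
#'   `noise_model != "none"`.
#' @param noise_model `"none"`, `"rician"`, or `"gaussian"`.
#' @param seed RNG seed.
#' @return An object of class `dwi_phantom_spec`.
#' @export
dwi_phantom_spec <- function(labels, regions, gtab,
                             spacing = c(2, 2, 2),
                             snr = Inf,
                             noise_model = c("none", "rician", "gaussian"),
                             seed = 1L) {
  noise_model <- match.arg(noise_model)
  assert_that(length(dim(labels)) == 3L, "labels must be a 3-D array")
  assert_that(inherits(gtab, "glym_gradients"), "gtab must be a glym_gradients")
  if (noise_model != "none") {
    assert_that(is.finite(snr) && snr > 0, "snr must be finite and > 0 when noise is enabled")
  }
  present <- setdiff(sort(unique(as.vector(labels))), 0)
  for (id in present) {
    r <- regions[[as.character(id)]]
    assert_that(!is.null(r), "no region entry for label %d", id)
    assert_that(length(r$D) == 6L, "region %d: D must have 6 components", id)
    assert_spd(r$D, sprintf("region %d diffusion tensor", id))
    assert_that(is_scalar_number(r$S0) && r$S0 > 0, "region %d: S0 must be > 0", id)
  }
  structure(list(labels = labels, regions = regions, gtab = gtab,
                 spacing = rep(as.numeric(spacing), length.out = 3),
                 snr = snr, noise_model = noise_model, seed = seed),
            class = "dwi_phantom_spec")
}

region_w15 <- function(r) {
  if (!is.null(r$W)) {
    assert_that(length(r$W) == 15L, "W must have 15 components")
    as.numeric(r$W)
  } else if (!is.null(r$K)) {
    isotropic_w15(r$K)
  } else {
    numeric(15)
  }
}

## Noise-free per-region signal vector over the gradient table.
region_signal <- function(r, gtab, region_label = "?") {
  Xd <- d_design(gtab$gx, gtab$gy, gtab$gz)
  Xw <- w4_design(gtab$gx, gtab$gy, gtab$gz)
  D6 <- as.numeric(r$D)
  w15 <- region_w15(r)
  md <- mean(D6[1:3])
  dapp <- as.vector(Xd %*% D6)
  wapp <- as.vector(Xw %*% w15)
  b <- gtab$bval
  ## validity of the quadratic model over the acquired b-range: the signal
  ## must still be decaying at b_max in every direction
  nz <- b > 0
  if (any(nz)) {
    bmax <- max(b)
    slope_at_bmax <- -dapp[nz] + (1 / 3) * bmax * md^2 * wapp[nz]
    if (any(slope_at_bmax >= 0)) {
      stop_glym("kurtosis term too large for the b-range in region %s (signal not decaying at b = %g)",
                region_label, bmax)
    }
  }
  logs <- log(r$S0) - b * dapp + (1 / 6) * b^2 * md^2 * wapp
  exp(logs)
}

#' Generate a DWI phantom with known tensors
#'
#' Noiseless mode reproduces the forward model to machine precision; Rician
#' mode draws two independent Gaussian channels of sd `S0/snr` and takes the
#' magnitude.
#'
#' @param spec A [dwi_phantom_spec()].
#' @return List with `dwi` (4-D array), `gtab`, `spacing`, `mask` (labels
#'   > 0), and `truth`: per-voxel `s0`, `D` (dims x 6), `W` (dims x 15),
#'   plus the region table.
#' @export
make_dwi_phantom <- function(spec) {
  assert_that(inherits(spec, "dwi_phantom_spec"), "spec must be a dwi_phantom_spec")
  with_seed(spec$seed, {
    d <- dim(spec$labels)
    nvol <- nrow(spec$gtab)
    dwi <- array(0, c(d, nvol))
    s0 <- array(0, d)
    Dt <- array(0, c(d, 6))
    Wt <- array(0, c(d, 15))
    present <- setdiff(sort(unique(as.vector(spec$labels))), 0)
    flat <- matrix(0, prod(d), nvol)
    sig_ref <- array(0, d)
    for (id in present) {
      r <- spec$regions[[as.character(id)]]
      sig <- region_signal(r, spec$gtab, as.character(id))
      vox <- which(spec$labels == id)
      flat[vox, ] <- matrix(sig, length(vox), nvol, byrow = TRUE)
      s0[vox] <- r$S0
      D6 <- as.numeric(r$D); w15 <- region_w15(r)
      for (cc in 1:6) Dt[vox + (cc - 1) * prod(d)] <- D6[cc]
      for (cc in 1:15) Wt[vox + (cc - 1) * prod(d)] <- w15[cc]
      sig_ref[vox] <- r$S0
    }
    if (spec$noise_model == "gaussian") {
      sigma <- as.vector(sig_ref) / spec$snr
      flat <- flat + matrix(stats::rnorm(length(flat)), nrow(flat)) * sigma
    } else if (spec$noise_model == "rician") {
      sigma <- as.vector(sig_ref) / spec$snr
      n1 <- matrix(stats::rnorm(length(flat)), nrow(flat)) * sigma
      n2 <- matrix(stats::rnorm(length(flat)), nrow(flat)) * sigma
      flat <- sqrt((flat + n1)^2 + n2^2)
    }
    dwi <- array(flat, c(d, nvol))
    list(dwi = dwi, gtab = spec$gtab, spacing = spec$spacing,
         mask = spec$labels > 0,
         truth = list(s0 = s0, D = Dt, W = Wt, regions = spec$regions,
                      labels = spec$labels))
  })
}

#' DWI phantom spec with analytic ground-truth ALPS
#'
#' Builds the block geometry of the ALPS measurement in phantom standard
#' space: bilateral projection-fiber regions whose principal diffusion axis
#' runs along Z (inferior-superior) and bilateral association-fiber regions
#' with principal axis along Y (anterior-posterior), embedded in an isotropic
#' background. The six diagonal diffusivities are free; ground truth is
#'
#'   ALPS = ((dxx_proj + dxx_assoc)/2) / ((dyy_proj + dzz_assoc)/2)
#'
#' @param dxx_proj,dyy_proj,dzz_proj Diagonal diffusivities of the projection
#'   region (mm^2/s).
#' @param dxx_assoc,dyy_assoc,dzz_assoc Diagonal diffusivities of the
#'   association region.
#' @param k_iso Optional isotropic kurtosis applied to all regions (0 = pure
#'   tensor field).
#' @param shape,spacing Grid geometry (defaults 40 x 32 x 12 at 2 mm).
#' @param s0 Non-diffusion-weighted signal.
#' @param gtab Gradient table (default [default_gradient_table()]).
#' @param snr,noise_model,seed Passed to [dwi_phantom_spec()].
#' @return A `dwi_phantom_spec` with attributes `alps_truth` (numeric) and
#'   `roi_centers` (named list of world-mm ROI centres for
#'   [make_alps_rois()]).
#' @export
make_alps_tensor_field <- function(dxx_proj, dyy_proj, dzz_proj,
                                   dxx_assoc, dyy_assoc, dzz_assoc,
                                   k_iso = 0,
                                   shape = c(40, 32, 12), spacing = c(2, 2, 2),
                                   s0 = 1000, gtab = default_gradient_table(),
                                   snr = Inf, noise_model = "none", seed = 1L) {
  vals <- c(dxx_proj, dyy_proj, dzz_proj, dxx_assoc, dyy_assoc, dzz_assoc)
  assert_that(all(is.finite(vals)) && all(vals > 0),
              "all six diffusivities must be positive")
  spacing <- rep(as.numeric(spacing), length.out = 3)
  d <- as.integer(shape)
  ## fiber blocks are defined by world-coordinate extents about the grid
  ## centre, so the left/right pair is mirror-symmetric on the lattice by
  ## construction, and each block leaves >= 4 mm of homogeneous margin around
  ## its ROI (room for local signal pooling in the Rician-robust fit).
  x_proj_mm <- 8; x_assoc_mm <- 20
  half_x <- 5; half_y <- 9; half_z <- 7
  aff <- centered_affine(d, spacing)
  wx <- (seq_len(d[1]) - 1) * spacing[1] + aff[1, 4]
  wy <- (seq_len(d[2]) - 1) * spacing[2] + aff[2, 4]
  wz <- (seq_len(d[3]) - 1) * spacing[3] + aff[3, 4]
  WX <- array(wx, d)
  WY <- array(rep(wy, each = d[1]), d)
  WZ <- array(rep(wz, each = d[1] * d[2]), d)
  lab <- array(1L, d)     # 1 = isotropic background
  in_band <- abs(WY) <= half_y & abs(WZ) <= half_z
  lab[in_band & abs(abs(WX) - x_proj_mm) <= half_x] <- 2L   # projection fibers
  lab[in_band & abs(abs(WX) - x_assoc_mm) <= half_x] <- 3L  # association fibers
  d_bg <- mean(vals)
  regions <- list(
    `1` = list(D = c(d_bg, d_bg, d_bg, 0, 0, 0), K = k_iso, S0 = s0),
    `2` = list(D = c(dxx_proj, dyy_proj, dzz_proj, 0, 0, 0), K = k_iso, S0 = s0),
    `3` = list(D = c(dxx_assoc, dyy_assoc, dzz_assoc, 0, 0, 0), K = k_iso, S0 = s0)
  )
  spec <- dwi_phantom_spec(lab, regions, gtab, spacing = spacing, snr = snr,
                           noise_model = noise_model, seed = seed)
  attr(spec, "alps_truth") <- ((dxx_proj + dxx_assoc) / 2) /
                              ((dyy_proj + dzz_assoc) / 2)
  attr(spec, "roi_centers") <- list(
    proj_left   = c(-x_proj_mm, 0, 0),
    proj_right  = c(x_proj_mm, 0, 0),
    assoc_left  = c(-x_assoc_mm, 0, 0),
    assoc_right = c(x_assoc_mm, 0, 0))
  attr(spec, "affine") <- aff
  spec
}
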