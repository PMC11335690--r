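## Diffusion and kurtosis tensor estimation from the log-linearised signal
## model. Both estimators share the design-matrix construction; the DKI fit
## jointly estimates log S0, the 6 diffusion-tensor components and the 15
## components of V = MD^2 * W (linear in the log-signal), then rescales V by
## the fitted MD^2 to report W.

dti_design <- function(gtab) {
  cbind(1, -gtab$bval * d_design(gtab$gx, gtab$gy, gtab$gz))
}

dki_design <- function(gtab) {
  cbind(1,
        -gtab$bval * d_design(gtab$gx, gtab$gy, gtab$gz),
        (gtab$bval^2 / 6) * w4_design(gtab$gx, gtab$gy, gtab$gz))
}

check_dwi_inputs <- function(dwi, gtab, mask) {
  assert_that(length(dim(dwi)) == 4L, "dwi must be a 4-D array")
  assert_that(dim(dwi)[4] == nrow(gtab),
              "dwi has %d volumes but gradient table has %d entries",
              dim(dwi)[4], nrow(gtab))
  d <- dim(dwi)[1:3]
  if (is.null(mask)) mask <- array(TRUE, d)
  assert_that(identical(dim(mask), d), "mask grid does not match dwi grid")
  mask
}

## Clip non-positive signals to a small epsilon; returns list(mat, n_clipped).
clip_signals <- function(sigmat) {
  eps <- max(sigmat) * 1e-8
  if (eps <= 0) eps <- .Machine$double.eps
  n_bad <- sum(sigmat <= 0)
  if (n_bad > 0) {
    warning(sprintf("clipped %d non-positive signal value(s) before log-fit", n_bad),
            call. = FALSE)
    sigmat[sigmat <= 0] <- eps
  }
  list(mat = sigmat, n_clipped = n_bad)
}

## Signal-squared weighted log-linear fit, per voxel. First pass weights by
## the squared observed signal (so near-zero, noise-floor measurements carry
## essentially no leverage); second pass reweights by the squared fitted
## signal.
wls_log_fit <- function(X, logS, sigmat) {
  nvox <- ncol(logS)
  coefs <- matrix(0, ncol(X), nvox)
  cap <- log(2 * max(sigmat))    # fitted-signal weights cannot exceed 4 max(S)^2
  for (v in seq_len(nvox)) {
    w <- sigmat[, v]^2
    Xw <- X * w
    beta <- solve(crossprod(X, Xw), crossprod(Xw, logS[, v]))
    w2 <- exp(pmin(X %*% beta, cap))^2
    Xw2 <- X * as.vector(w2)
    beta2 <- tryCatch(solve(crossprod(X, Xw2), crossprod(Xw2, logS[, v])),
                      error = function(e) beta)
    coefs[, v] <- beta2
  }
  coefs
}

new_tensor_field <- function(dims, spacing, coefs, vox, method, n_clipped,
                             has_w = FALSE) {
  ## coefs: p x nvox matrix, rows = (logS0, D6[, V15])
  nv <- prod(dims)
  s0 <- array(NA_real_, dims)
  s0[vox] <- exp(coefs[1, ])
  D <- array(NA_real_, c(dims, 6))
  for (cc in 1:6) D[vox + (cc - 1) * nv] <- coefs[1 + cc, ]
  W <- NULL
  if (has_w) {
    md <- (coefs[2, ] + coefs[3, ] + coefs[4, ]) / 3
    md2 <- pmax(md^2, .Machine$double.eps)
    W <- array(NA_real_, c(dims, 15))
    for (cc in 1:15) W[vox + (cc - 1) * nv] <- coefs[7 + cc, ] / md2
  }
  mask <- array(FALSE, dims); mask[vox] <- TRUE
  ## negative-eigenvalue report (report-and-clamp policy is opt-in downstream)
  e <- eig3sym(coefs[2, ], coefs[3, ], coefs[4, ], coefs[5, ], coefs[6, ], coefs[7, ])
  n_neg <- sum(e$e3 < 0)
  structure(list(s0 = s0, D = D, W = W, mask = mask, spacing = spacing,
                 method = method, n_clipped = n_clipped,
                 n_negative_eigen = n_neg),
            class = "glym_tensor_field")
}

#' @export
print.glym_tensor_field <- function(x, ...) {
  cat(sprintf("<glym_tensor_field> %s  %s  %d voxels fitted%s\n",
              paste(dim(x$s0), collapse = "x"), x$method, sum(x$mask),
              if (is.null(x$W)) "" else "  (with kurtosis tensor)"))
  if (x$n_negative_eigen > 0) {
    cat(sprintf("  %d voxel(s) with a negative diffusion eigenvalue\n",
                x$n_negative_eigen))
  }
  invisible(x)
}

#' Weighted least-squares diffusion tensor fit
#'
#' Log-linear fit of `log S = log S0 - b g'Dg`, weighted by the squared
#' observed signal (the standard WLS estimator, which undoes the
#' log-transform's variance distortion).
#'
#' @param dwi 4-D array (x, y, z, volume).
#' @param gtab A [gradient_table()] with at least 6 unique non-collinear
#'   directions and one b = 0 entry.
#' @param mask Logical 3-D array of voxels to fit (default: all).
#' @param spacing Voxel size mm (metadata only).
#' @return A `glym_tensor_field` with per-voxel S0 and D (no kurtosis
#'   tensor). Voxels with non-positive signals are clipped to a small epsilon
#'   and counted in `n_clipped`.
#' @export
fit_dti_wls <- function(dwi, gtab, mask = NULL, spacing = c(2, 2, 2)) {
  mask <- check_dwi_inputs(dwi, gtab, mask)
  X <- dti_design(gtab)
  qrX <- qr(X)
  assert_that(qrX$rank == ncol(X),
              "rank-deficient design: need >= 6 unique non-collinear directions plus b = 0")
  d <- dim(dwi)[1:3]
  vox <- which(mask)
  assert_that(length(vox) > 0, "empty fit mask")
  sigmat <- matrix(aperm(dwi, c(4, 1, 2, 3)), nrow = dim(dwi)[4])[, vox, drop = FALSE]
  cl <- clip_signals(sigmat)
  logS <- log(cl$mat)
  coefs <- wls_log_fit(X, logS, cl$mat)
  new_tensor_field(d, spacing, coefs, vox, "dti-wls", cl$n_clipped, has_w = FALSE)
}

#' Linear least-squares diffusion kurtosis fit
#'
#' Joint linear fit of the 22 parameters (log S0, 6 diffusion-tensor and 15
#' kurtosis-tensor components) to the log-signal of a multi-shell
#' acquisition. The diffusion tensor reported by this fit is what feeds the
#' ALPS index in the two-shell pipeline. With `weights = "signal"` (default)
#' a second, signal-squared-weighted pass follows the unweighted solve, which
#' suppresses the influence of the noise-floor-dominated outer shell.
#'
#' @param dwi,gtab,mask,spacing As in [fit_dti_wls()]. The gradient table
#'   must contain at least two distinct nonzero shells and 15 unique
#'   directions on the outer shell.
#' @param weights `"signal"` (WLS pass) or `"none"` (plain LLS).
#' @return A `glym_tensor_field` with S0, D and the kurtosis tensor W.
#' @export
fit_dki_lls <- function(dwi, gtab, mask = NULL, spacing = c(2, 2, 2),
                        weights = c("signal", "none")) {
  weights <- match.arg(weights)
  mask <- check_dwi_inputs(dwi, gtab, mask)
  shells <- sort(unique(gtab$bval[gtab$bval > 0]))
  if (length(shells) < 2) {
    stop_glym("kurtosis fit needs >= 2 nonzero shells (got %d); use fit_dti_wls for single-shell data",
              length(shells))
  }
  outer_dirs <- unique(round(cbind(gtab$gx, gtab$gy, gtab$gz)[gtab$bval == max(shells), ], 6))
  assert_that(nrow(outer_dirs) >= 15,
              "outer shell has %d unique directions; >= 15 required", nrow(outer_dirs))
  X <- dki_design(gtab)
  qrX <- qr(X)
  assert_that(qrX$rank == ncol(X), "rank-deficient kurtosis design")
  d <- dim(dwi)[1:3]
  vox <- which(mask)
  assert_that(length(vox) > 0, "empty fit mask")
  sigmat <- matrix(aperm(dwi, c(4, 1, 2, 3)), nrow = dim(dwi)[4])[, vox, drop = FALSE]
  cl <- clip_signals(sigmat)
  logS <- log(cl$mat)
  coefs <- if (weights == "none") qr.coef(qrX, logS)
           else wls_log_fit(X, logS, cl$mat)
  new_tensor_field(d, spacing, coefs, vox, paste0("dki-", weights), cl$n_clipped,
                   has_w = TRUE)
}

## Box mean of radius r along the three spatial axes of a 4-D array,
## replicate-padded at the borders.
boxmean4 <- function(arr, r) {
  if (r <= 0) return(arr)
  for (ax in 1:3) {
    n <- dim(arr)[ax]
    acc <- array(0, dim(arr))
    for (s in -r:r) {
      idx <- pmin(pmax(seq_len(n) + s, 1L), n)
      acc <- acc + switch(ax,
                          arr[idx, , , , drop = FALSE],
                          arr[, idx, , , drop = FALSE],
                          arr[, , idx, , drop = FALSE])
    }
    arr <- acc / (2 * r + 1)
  }
  arr
}

#' Moment-based Rician noise-floor correction
#'
#' Magnitude MRI signals satisfy `E[M^2] = nu^2 + 2 sigma^2` exactly under
#' Rician noise, so the squared amplitude is estimated unbiasedly as
#' `M^2 - 2 sigma^2`. Without correction the noise floor of high-b,
#' high-diffusivity measurements masquerades as kurtosis and inflates the
#' fitted diffusion tensor. With `pool_radius > 0` the second moment is
#' first averaged over a cubic neighbourhood of that voxel radius, which
#' shrinks the variance of the corrected amplitude enough for the
#' log-domain fit to be effectively unbiased in locally homogeneous tissue
#' (at the cost of partial-volume blurring near region boundaries).
#' `sigma` defaults to an estimate from the repeated b = 0 volumes (half
#' the variance of their voxelwise difference, root-mean over the mask);
#' for noiseless data this estimate is 0 and the correction is the
#' identity.
#'
#' @param dwi 4-D array.
#' @param gtab A [gradient_table()] with >= 2 b = 0 volumes when `sigma` is
#'   to be estimated.
#' @param mask Logical array over which `sigma` is estimated (default: all).
#' @param sigma Known noise sd; if `NULL`, estimated from the b = 0 pair.
#' @param pool_radius Voxel radius of the cubic second-moment pooling
#'   neighbourhood (0 = per-voxel correction).
#' @return The corrected 4-D amplitude array, with the `sigma` used attached
#'   as an attribute.
#' @export
rician_floor_correct <- function(dwi, gtab, mask = NULL, sigma = NULL,
                                 pool_radius = 0) {
  assert_that(length(dim(dwi)) == 4L, "dwi must be a 4-D array")
  if (is.null(sigma)) {
    b0 <- which(gtab$bval == 0)
    assert_that(length(b0) >= 2,
                "sigma estimation needs >= 2 b = 0 volumes; pass sigma explicitly")
    s1 <- dwi[, , , b0[1]]; s2 <- dwi[, , , b0[2]]
    if (is.null(mask)) mask <- array(TRUE, dim(dwi)[1:3])
    sigma <- sqrt(mean((s1[mask] - s2[mask])^2) / 2)
  }
  if (sigma == 0) {
    attr(dwi, "sigma") <- 0
    return(dwi)
  }
  m2 <- boxmean4(dwi^2, pool_radius)
  ## floor at a small positive amplitude so the log-fit stays defined; the
  ## signal-squared weights make these entries effectively inert
  out <- sqrt(pmax(m2 - 2 * sigma^2, (0.05 * sigma)^2))
  attr(out, "sigma") <- sigma
  out
}

#' Diagonal diffusivity maps from a tensor field
#'
#' Returns the diagonal tensor components in the volume's axis frame (Dxx,
#' Dyy, Dzz) -- not eigenvalues. These are the maps the ALPS index samples.
#'
#' @param tf A `glym_tensor_field`.
#' @return Named list of three [glym_volume()]s: `dxx`, `dyy`, `dzz`
#'   (NA outside the fit mask is replaced by 0).
#' @export
extract_diffusivity_maps <- function(tf) {
  assert_that(inherits(tf, "glym_tensor_field"), "tf must be a glym_tensor_field")
  one <- function(cc) {
    m <- tf$D[, , , cc]
    m[!tf$mask] <- 0
    glym_volume(m, spacing = tf$spacing,
                affine = centered_affine(dim(tf$s0), tf$spacing))
  }
  list(dxx = one(1), dyy = one(2), dzz = one(3))
}

#' Mean kurtosis map
#'
#' Directional average of the apparent kurtosis over the canonical component
#' directions; for an isotropic tensor pair this equals the scalar kurtosis.
#'
#' @param tf A `glym_tensor_field` fitted with [fit_dki_lls()].
#' @param n_dirs Number of quasi-uniform directions averaged over.
#' @return 3-D array of mean kurtosis (NA outside the mask).
#' @export
mean_kurtosis <- function(tf, n_dirs = 60) {
  assert_that(!is.null(tf$W), "tensor field has no kurtosis tensor")
  i <- seq_len(n_dirs) - 0.5
  phi <- acos(1 - 2 * i / n_dirs); th <- pi * (1 + sqrt(5)) * i
  g <- cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
  Xd <- d_design(g[, 1], g[, 2], g[, 3])
  Xw <- w4_design(g[, 1], g[, 2], g[, 3])
  dims <- dim(tf$s0); nv <- prod(dims)
  Dm <- matrix(tf$D, nv, 6); Wm <- matrix(tf$W, nv, 15)
  md <- rowMeans(Dm[, 1:3, drop = FALSE])
  dapp <- Dm %*% t(Xd)       # nv x n_dirs
  wapp <- Wm %*% t(Xw)
  kapp <- sweep(wapp, 1, md^2, "*") / pmax(dapp^2, .Machine$double.eps)
  array(rowMeans(kapp), dims)
}
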