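## Multiscale Hessian vesselness (Frangi) filtering for tubular-structure
## enhancement. All derivatives are spacing-aware Gaussian derivatives in mm
## units, computed by separable convolution with truncated sampled kernels
## (radius 4 sigma), and the Hessian is gamma-normalised by sigma^2 so
## responses are comparable across scales.

## Sampled Gaussian (derivative) kernel for one axis. `sigma` and `spacing`
## in mm; order 0, 1 or 2. Kernels are renormalised so that the discrete
## response to the monomial of matching order is exact (order 0: sum 1;
## order 1: response to x is 1; order 2: response to x^2/2 is 1, zero mean),
## which makes the Hessian of low-order polynomials exact and the response
## to a constant image identically zero.
gauss_kernel_1d <- function(sigma, spacing, order = 0L) {
  r <- max(1L, ceiling(4 * sigma / spacing))
  x <- (-r:r) * spacing
  g <- exp(-x^2 / (2 * sigma^2))
  if (order == 0L) {
    k <- g / sum(g)
  } else if (order == 1L) {
    k <- -x * g
    k <- k / sum(k * x)          # response to f(x) = x equals 1
  } else if (order == 2L) {
    k <- (x^2 / sigma^2 - 1) * g
    k <- k - mean(k)             # exact zero response to constants
    k <- k / sum(k * x^2 / 2)    # response to f(x) = x^2/2 equals 1
  } else {
    stop_glym("unsupported derivative order %d", order)
  }
  k
}

## Separable convolution of a 3-D array along one axis, replicate padding.
conv_axis <- function(arr, k, axis) {
  d <- dim(arr)
  r <- (length(k) - 1L) %/% 2L
  n <- d[axis]
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  ## replicate padding via clamped row indices
  out <- matrix(0, da[1], ncol(m))
  for (j in seq_along(k)) {
    off <- j - r - 1L
    rows <- pmin(pmax(seq_len(n) + off, 1L), n)
    out <- out + k[j] * m[rows, , drop = FALSE]
  }
  a <- array(out, da)
  aperm(a, order(perm))
}

## The six unique Hessian components of `img` at scale sigma (mm), each
## sigma^2-normalised. Returns a named list of arrays.
hessian_at_scale <- function(img, spacing, sigma) {
  k0 <- lapply(1:3, function(ax) gauss_kernel_1d(sigma, spacing[ax], 0L))
  k1 <- lapply(1:3, function(ax) gauss_kernel_1d(sigma, spacing[ax], 1L))
  k2 <- lapply(1:3, function(ax) gauss_kernel_1d(sigma, spacing[ax], 2L))
  smooth_except <- function(a, skip) {
    for (ax in setdiff(1:3, skip)) a <- conv_axis(a, k0[[ax]], ax)
    a
  }
  dxx <- smooth_except(conv_axis(img, k2[[1]], 1), 1)
  dyy <- smooth_except(conv_axis(img, k2[[2]], 2), 2)
  dzz <- smooth_except(conv_axis(img, k2[[3]], 3), 3)
  dxy <- smooth_except(conv_axis(conv_axis(img, k1[[1]], 1), k1[[2]], 2), c(1, 2))
  dxz <- smooth_except(conv_axis(conv_axis(img, k1[[1]], 1), k1[[3]], 3), c(1, 3))
  dyz <- smooth_except(conv_axis(conv_axis(img, k1[[2]], 2), k1[[3]], 3), c(2, 3))
  s2 <- sigma^2
  list(xx = s2 * dxx, yy = s2 * dyy, zz = s2 * dzz,
       xy = s2 * dxy, xz = s2 * dxz, yz = s2 * dyz)
}

#' Frangi filter parameters
#'
#' @param scales Gaussian scales in mm (positive, sorted ascending).
#' @param alpha Plate-vs-line discrimination constant (on the ratio
#'   `|l2|/|l3|`).
#' @param beta Blob discrimination constant (on `|l1|/sqrt(|l2 l3|)`).
#' @param c Structureness constant: `"auto"` (half the maximum Hessian
#'   Frobenius norm over the volume, per scale) or a numeric vector (length
#'   1 or one per scale). Pass the `c_used` attribute of a previously
#'   computed map to reproduce its scaling on new data (required for
#'   absolute thresholds to transfer across images).
#' @param polarity `"dark_tubes"` (PVS-like: dark tubes on a bright
#'   background; the image is negated internally) or `"bright_tubes"`.
#' @return An object of class `frangi_params`.
#' @export
frangi_params <- function(scales = c(0.35, 0.7, 1.05), alpha = 0.5, beta = 0.5,
                          c = "auto", polarity = c("dark_tubes", "bright_tubes")) {
  polarity <- match.arg(polarity)
  scales <- as.numeric(scales)
  assert_that(length(scales) >= 1 && all(scales > 0) && !is.unsorted(scales),
              "scales must be positive and sorted ascending")
  assert_that(alpha > 0 && beta > 0, "alpha and beta must be > 0")
  if (!identical(c, "auto")) {
    assert_that(is.numeric(c) && all(is.finite(c)) && all(c > 0) &&
                  length(c) %in% c(1L, length(scales)),
                "c must be 'auto' or positive (length 1 or one per scale)")
  }
  structure(list(scales = scales, alpha = alpha, beta = beta, c = c,
                 polarity = polarity), class = "frangi_params")
}

#' Multiscale Frangi vesselness map
#'
#' Hessian-eigenvalue tubularity measure: with eigenvalues ordered
#' `|l1| <= |l2| <= |l3|`, per scale
#'
#'   V = (1 - exp(-Ra^2 / 2 alpha^2)) * exp(-Rb^2 / 2 beta^2)
#'       * (1 - exp(-S^2 / 2 c^2))
#'
#' with `Ra = |l2|/|l3|` (plate suppression), `Rb = |l1|/sqrt(|l2 l3|)`
#' (blob suppression) and `S` the Frobenius norm (noise suppression);
#' vesselness is zero wherever `l2 > 0` or `l3 > 0` (after polarity
#' negation, tubes are bright, so their cross-sectional eigenvalues are
#' negative). The map is the maximum over scales.
#'
#' @param v A [glym_volume()].
#' @param params A [frangi_params()].
#' @return A [glym_volume()] of vesselness values in `[0, 1)`.
#' @export
frangi_vesselness <- function(v, params = frangi_params()) {
  assert_that(inherits(v, "glym_volume"), "v must be a glym_volume")
  assert_that(inherits(params, "frangi_params"), "params must be frangi_params")
  img <- v$data
  if (params$polarity == "dark_tubes") img <- -img
  best <- array(0, dim(img))
  rng <- diff(range(img))
  if (rng == 0) {
    return(glym_volume(best, spacing = v$spacing, affine = v$affine,
                       space_tag = v$space_tag))
  }
  ## structureness below this floor is floating-point residue of the
  ## separable convolutions (exact-zero responses accumulate rounding of
  ## order 1e-16 * image range), not image structure
  s_floor2 <- (1e-10 * rng)^2
  c_fixed <- if (identical(params$c, "auto")) NULL else
    rep(params$c, length.out = length(params$scales))
  c_used <- numeric(length(params$scales))
  for (si in seq_along(params$scales)) {
    sigma <- params$scales[si]
    h <- hessian_at_scale(img, v$spacing, sigma)
    e <- eig3sym_absorder(h$xx, h$yy, h$zz, h$xy, h$xz, h$yz)
    l1 <- e$l1; l2 <- e$l2; l3 <- e$l3
    a2 <- abs(l2); a3 <- abs(l3)
    eps <- .Machine$double.xmin
    ra2 <- (a2 / pmax(a3, eps))^2
    rb2 <- l1^2 / pmax(a2 * a3, eps)
    s2 <- l1^2 + l2^2 + l3^2
    c_val <- if (is.null(c_fixed)) {
      cs <- sqrt(max(s2)) / 2
      if (cs^2 <= s_floor2) 1 else cs
    } else c_fixed[si]
    c_used[si] <- c_val
    vess <- (1 - exp(-ra2 / (2 * params$alpha^2))) *
            exp(-rb2 / (2 * params$beta^2)) *
            (1 - exp(-s2 / (2 * c_val^2)))
    vess[l2 > 0 | l3 > 0] <- 0
    vess[s2 <= s_floor2] <- 0
    best <- pmax(best, array(vess, dim(img)))
  }
  out <- glym_volume(best, spacing = v$spacing, affine = v$affine,
                     space_tag = v$space_tag)
  attr(out, "c_used") <- c_used
  out
}
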