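#' Bilateral ALPS ROI set
#'
#' Builds the four axial square ROIs of the ALPS measurement: bilateral
#' projection-fiber and association-fiber ROIs of a stated in-plane area and
#' slab thickness, placed at given world-mm centres. The left/right pair is
#' forced to be mirror-symmetric about the midsagittal plane (x = 0): right
#' ROIs are constructed by flipping the left ones on the voxel lattice.
#'
#' @param dims Grid dimensions (length 3).
#' @param spacing Voxel size mm.
#' @param centers Named list of world-mm centres with entries `proj_left`,
#'   `proj_right`, `assoc_left`, `assoc_right` (e.g. the `roi_centers`
#'   attribute of [make_alps_tensor_field()]).
#' @param area_mm2 In-plane ROI area (default 16 mm^2). If the side is not a
#'   multiple of the in-plane spacing the nearest achievable voxel count is
#'   used and reported in the result.
#' @param slab_slices Slab thickness in axial slices (default 1).
#' @param affine Voxel-to-world affine; defaults to the centred phantom
#'   affine, under which x = 0 is the midsagittal plane.
#' @return An object of class `alps_roi_set`: named list of logical masks
#'   plus geometry metadata.
#' @export
make_alps_rois <- function(dims, spacing, centers, area_mm2 = 16,
                           slab_slices = 1, affine = NULL) {
  dims <- as.integer(dims)
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (is.null(affine)) affine <- centered_affine(dims, spacing)
  need <- c("proj_left", "proj_right", "assoc_left", "assoc_right")
  assert_that(all(need %in% names(centers)), "centers must name %s",
              paste(need, collapse = ", "))
  assert_that(abs(spacing[1] - spacing[2]) < 1e-9,
              "in-plane spacing must be isotropic for square ROIs")
  n_side <- max(1L, as.integer(round(sqrt(area_mm2) / spacing[1])))
  achieved_area <- (n_side * spacing[1])^2
  inv <- solve(affine)
  to_vox <- function(world) (inv %*% c(world, 1))[1:3]   # 0-based continuous
  build <- function(world) {
    v <- to_vox(world)
    assert_that(all(v > -0.5) && all(v < dims - 0.5),
                "ROI centre (%s) mm falls outside the grid",
                paste(format(world), collapse = ", "))
    start_xy <- round(v[1:2] - (n_side - 1) / 2) + 1L    # 1-based
    z0 <- round(v[3] - (slab_slices - 1) / 2) + 1L
    xr <- start_xy[1]:(start_xy[1] + n_side - 1L)
    yr <- start_xy[2]:(start_xy[2] + n_side - 1L)
    zr <- z0:(z0 + slab_slices - 1L)
    assert_that(all(xr >= 1) && all(xr <= dims[1]) &&
                all(yr >= 1) && all(yr <= dims[2]) &&
                all(zr >= 1) && all(zr <= dims[3]),
                "ROI at (%s) mm extends outside the grid",
                paste(format(world), collapse = ", "))
    m <- array(FALSE, dims)
    m[xr, yr, zr] <- TRUE
    m
  }
  mirror_x <- function(m) m[dims[1]:1, , , drop = FALSE]
  proj_left <- build(centers$proj_left)
  assoc_left <- build(centers$assoc_left)
  proj_right <- mirror_x(proj_left)
  assoc_right <- mirror_x(assoc_left)
  masks <- list(proj_left = proj_left, proj_right = proj_right,
                assoc_left = assoc_left, assoc_right = assoc_right)
  overlap <- Reduce(`+`, masks)
  assert_that(max(overlap) <= 1, "ALPS ROIs overlap")
  structure(c(masks,
              list(n_side = n_side, area_mm2 = achieved_area,
                   requested_area_mm2 = area_mm2, slab_slices = slab_slices,
                   spacing = spacing, dims = dims)),
            class = "alps_roi_set")
}

#' @export
print.alps_roi_set <- function(x, ...) {
  cat(sprintf("<alps_roi_set> 4 ROIs, %dx%d voxels (%.1f mm^2), slab %d slice(s)\n",
              x$n_side, x$n_side, x$area_mm2, x$slab_slices))
  invisible(x)
}

#' DTI-ALPS index from diffusivity maps
#'
#' Samples the diagonal diffusivity maps in the four bilateral ROIs and forms
#'
#'   ALPS = mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)
#'
#' where each term is first averaged over the left and right ROI of its pair.
#' Dxx is the diffusivity along the perivascular (left-right) axis; Dyy and
#' Dzz are the principal-fiber-perpendicular diffusivities in the projection
#' (z-oriented) and association (y-oriented) fiber regions.
#'
#' @param maps Named list with `dxx`, `dyy`, `dzz` [glym_volume()]s (from
#'   [extract_diffusivity_maps()]).
#' @param rois An [make_alps_rois()] result.
#' @param fit_mask Optional logical array restricting the ROI means to fitted
#'   voxels.
#' @param side_average `"before_ratio"` (default: average L/R per term, then
#'   one ratio) or `"per_side"` (form a left and a right index, then average;
#'   identical for mirror-symmetric fields).
#' @return An object of class `alps_result`: list with `alps_index`, the four
#'   bilateral term means, the eight per-ROI means, and provenance.
#' @export
compute_alps_index <- function(maps, rois, fit_mask = NULL,
                               side_average = c("before_ratio", "per_side")) {
  side_average <- match.arg(side_average)
  assert_that(inherits(rois, "alps_roi_set"), "rois must be an alps_roi_set")
  roi_mean <- function(vol, mask) {
    m <- mask
    if (!is.null(fit_mask)) m <- m & fit_mask
    assert_that(any(m), "ROI does not intersect the fit mask")
    mean(vol$data[m])
  }
  means <- list(
    dxx_proj_l  = roi_mean(maps$dxx, rois$proj_left),
    dxx_proj_r  = roi_mean(maps$dxx, rois$proj_right),
    dxx_assoc_l = roi_mean(maps$dxx, rois$assoc_left),
    dxx_assoc_r = roi_mean(maps$dxx, rois$assoc_right),
    dyy_proj_l  = roi_mean(maps$dyy, rois$proj_left),
    dyy_proj_r  = roi_mean(maps$dyy, rois$proj_right),
    dzz_assoc_l = roi_mean(maps$dzz, rois$assoc_left),
    dzz_assoc_r = roi_mean(maps$dzz, rois$assoc_right))
  bl <- list(
    dxx_proj  = (means$dxx_proj_l + means$dxx_proj_r) / 2,
    dxx_assoc = (means$dxx_assoc_l + means$dxx_assoc_r) / 2,
    dyy_proj  = (means$dyy_proj_l + means$dyy_proj_r) / 2,
    dzz_assoc = (means$dzz_assoc_l + means$dzz_assoc_r) / 2)
  if (side_average == "before_ratio") {
    denom <- (bl$dyy_proj + bl$dzz_assoc) / 2
    assert_that(denom > 0, "non-positive ALPS denominator")
    alps <- ((bl$dxx_proj + bl$dxx_assoc) / 2) / denom
  } else {
    dl <- (means$dyy_proj_l + means$dzz_assoc_l) / 2
    dr <- (means$dyy_proj_r + means$dzz_assoc_r) / 2
    assert_that(dl > 0 && dr > 0, "non-positive ALPS denominator")
    alps <- (((means$dxx_proj_l + means$dxx_assoc_l) / 2) / dl +
             ((means$dxx_proj_r + means$dxx_assoc_r) / 2) / dr) / 2
  }
  structure(list(alps_index = alps, bilateral_means = bl, roi_means = means,
                 side_average = side_average,
                 roi_area_mm2 = rois$area_mm2),
            class = "alps_result")
}

#' @export
print.alps_result <- function(x, ...) {
  cat(sprintf("<alps_result> ALPS index = %.4f\n", x$alps_index))
  b <- x$bilateral_means
  cat(sprintf("  Dxx proj %.3e  Dxx assoc %.3e  Dyy proj %.3e  Dzz assoc %.3e (mm^2/s)\n",
              b$dxx_proj, b$dxx_assoc, b$dyy_proj, b$dzz_assoc))
  invisible(x)
}

#' End-to-end ALPS from a DWI series
#'
#' Convenience pipeline: tensor (or kurtosis) fit, diffusivity map
#' extraction, ROI construction, ALPS computation.
#'
#' @param dwi 4-D array.
#' @param gtab A [gradient_table()].
#' @param mask Fit mask (logical array) or `NULL`.
#' @param spacing Voxel size mm.
#' @param centers ROI centres (world mm), as in [make_alps_rois()].
#' @param fit `"dki"` (default; requires two shells) or `"dti"`.
#' @param area_mm2,slab_slices ROI geometry.
#' @param rician_correction Apply [rician_floor_correct()] before fitting
#'   (default `TRUE` when the table has >= 2 b = 0 volumes; a no-op on
#'   noiseless data).
#' @param pool_radius Second-moment pooling radius for the correction
#'   (voxels; default 2).
#' @return An `alps_result` with the fitted `glym_tensor_field` attached as
#'   attribute `tensor_field`.
#' @export
run_alps <- function(dwi, gtab, mask = NULL, spacing = c(2, 2, 2), centers,
                     fit = c("dki", "dti"), area_mm2 = 16, slab_slices = 1,
                     rician_correction = sum(gtab$bval == 0) >= 2,
                     pool_radius = 2) {
  fit <- match.arg(fit)
  rois <- make_alps_rois(dim(dwi)[1:3], spacing, centers,
                         area_mm2 = area_mm2, slab_slices = slab_slices)
  if (isTRUE(rician_correction)) {
    ## noise sd is estimated over the whole mask; the tensor fit itself only
    ## needs the ROI voxels
    dwi <- rician_floor_correct(dwi, gtab, mask, pool_radius = pool_radius)
  }
  roi_union <- rois$proj_left | rois$proj_right | rois$assoc_left | rois$assoc_right
  fit_mask <- if (is.null(mask)) roi_union else (mask & roi_union)
  tf <- if (fit == "dki") fit_dki_lls(dwi, gtab, fit_mask, spacing)
        else fit_dti_wls(dwi, gtab, fit_mask, spacing)
  maps <- extract_diffusivity_maps(tf)
  res <- compute_alps_index(maps, rois, fit_mask = tf$mask)
  attr(res, "tensor_field") <- tf
  res
}
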