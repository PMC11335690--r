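## ePVS segmentation: white-matter-referenced intensity normalisation,
## enhanced perivascular contrast (EPC) image, vesselness thresholding with
## minimum-cluster filtering, and region-normalised burden.

#' White-matter-referenced intensity normalisation
#'
#' Divides the volume by a summary statistic (median by default, robust to
#' PVS inclusions) of its values inside the white-matter mask, so that
#' white matter sits at 1 in both channels before the EPC ratio is formed.
#'
#' @param v A [glym_volume()].
#' @param wm_mask Logical 3-D array (nonempty).
#' @param stat `"median"` or `"mean"`.
#' @return A [glym_volume()] with WM statistic 1.
#' @export
normalize_intensity <- function(v, wm_mask, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  assert_that(inherits(v, "glym_volume"), "v must be a glym_volume")
  assert_that(any(wm_mask), "white-matter mask is empty")
  ref <- if (stat == "median") stats::median(v$data[wm_mask]) else mean(v$data[wm_mask])
  assert_that(is.finite(ref) && ref > 0,
              "white-matter %s must be positive, got %g", stat, ref)
  glym_volume(v$data / ref, spacing = v$spacing, affine = v$affine,
              space_tag = v$space_tag)
}

#' Enhanced perivascular contrast (EPC) image
#'
#' Voxelwise ratio `T1w / max(T2w, epsilon)` of the WM-normalised channels.
#' PVS voxels are CSF-like (dark on T1w, bright on T2w), so their EPC is
#' strictly lower than surrounding white matter; the downstream vesselness
#' filter runs in dark-tube polarity on this image.
#'
#' @param t1w_norm,t2w_norm WM-normalised [glym_volume()]s on one grid.
#' @param epsilon Positive guard for the division (default 1e-6).
#' @return A [glym_volume()].
#' @export
compute_epc <- function(t1w_norm, t2w_norm, epsilon = 1e-6) {
  assert_that(inherits(t1w_norm, "glym_volume") && inherits(t2w_norm, "glym_volume"),
              "inputs must be glym_volumes")
  assert_that(same_grid(t1w_norm, t2w_norm), "T1w and T2w are not on the same grid")
  assert_that(is_scalar_number(epsilon) && epsilon > 0, "epsilon must be > 0")
  epc <- t1w_norm$data / pmax(t2w_norm$data, epsilon)
  glym_volume(epc, spacing = t1w_norm$spacing, affine = t1w_norm$affine,
              space_tag = t1w_norm$space_tag)
}

## Connectivity offsets for 6/18/26-neighbourhoods.
connectivity_offsets <- function(connectivity) {
  assert_that(connectivity %in% c(6, 18, 26), "connectivity must be 6, 18 or 26")
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  manh <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(connectivity),
                 `6` = manh == 1, `18` = manh <= 2, `26` = rep(TRUE, nrow(g)))
  g[keep, , drop = FALSE]
}

## Shift a numeric array by (dx, dy, dz) padding with `fill`.
shift_array <- function(a, off, fill) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    s <- off[ax]
    if (abs(s) >= d[ax]) return(out)
    src[[ax]] <- if (s >= 0) seq_len(d[ax] - s) else (1 - s):d[ax]
    dst[[ax]] <- if (s >= 0) (1 + s):d[ax] else seq_len(d[ax] + s)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]], drop = FALSE]
  out
}

#' Label connected components of a binary mask
#'
#' Iterative minimum-label propagation over the chosen neighbourhood until a
#' fixed point, then relabelling to consecutive integers (sorted by first
#' linear index, so labels are deterministic).
#'
#' @param mask Logical 3-D array.
#' @param connectivity 6, 18 or 26 (face / face+edge / full neighbourhood).
#' @return Integer array: 0 outside the mask, component id inside.
#' @export
label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  assert_that(length(d) == 3L, "mask must be a 3-D array")
  if (!any(mask)) return(array(0L, d))
  ## crop to the bounding box of the mask for speed
  w <- which(mask, arr.ind = TRUE)
  lo <- apply(w, 2, min); hi <- apply(w, 2, max)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  ds <- dim(sub)
  lab <- array(Inf, ds)
  lab[sub] <- which(sub)
  offs <- connectivity_offsets(connectivity)
  repeat {
    new_lab <- lab
    for (i in seq_len(nrow(offs))) {
      sh <- shift_array(lab, c(offs$dx[i], offs$dy[i], offs$dz[i]), Inf)
      new_lab <- pmin(new_lab, sh)
    }
    new_lab[!sub] <- Inf
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  lab[!sub] <- 0
  ids <- sort(unique(lab[lab > 0]))
  lab <- array(match(lab, c(0, ids)) - 1L, ds)
  out <- array(0L, d)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- lab
  out
}

#' Segmentation parameters
#'
#' @param h Vesselness threshold. In `"absolute"` mode this is compared
#'   directly against the vesselness map (comparison is `>= h`); in
#'   `"quantile"` mode `h` is a probability and the threshold is the
#'   `h`-quantile of the vesselness values inside the region.
#' @param min_cluster_voxels Minimum connected-component size retained
#'   (default 9 voxels, ~3 mm^3 at the 0.7 mm working grid).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param threshold_mode `"absolute"` or `"quantile"`.
#' @param boundary_erosion Voxels of Chebyshev erosion applied to the region
#'   mask before thresholding, to exclude filter responses that belong to
#'   region interfaces rather than tubes; `"auto"` (default) uses the
#'   support radius of the largest filter scale recorded on the vesselness
#'   map, or 0 when unknown. The burden denominator always uses the
#'   *uneroded* region.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(h = 2e-7, min_cluster_voxels = 9,
                                connectivity = 26,
                                threshold_mode = c("absolute", "quantile"),
                                boundary_erosion = "auto") {
  threshold_mode <- match.arg(threshold_mode)
  assert_that(is_scalar_number(h) && h >= 0, "h must be >= 0")
  if (threshold_mode == "quantile") {
    assert_that(h >= 0 && h <= 1, "quantile-mode h must be in [0, 1]")
  }
  assert_that(min_cluster_voxels >= 1, "min_cluster_voxels must be >= 1")
  assert_that(connectivity %in% c(6, 18, 26), "connectivity must be 6, 18 or 26")
  if (!identical(boundary_erosion, "auto")) {
    assert_that(is_scalar_number(boundary_erosion) && boundary_erosion >= 0,
                "boundary_erosion must be >= 0 or 'auto'")
  }
  structure(list(h = h, min_cluster_voxels = as.integer(min_cluster_voxels),
                 connectivity = connectivity, threshold_mode = threshold_mode,
                 boundary_erosion = boundary_erosion),
            class = "segmentation_params")
}

resolve_erosion <- function(params, vesselness) {
  if (!identical(params$boundary_erosion, "auto")) {
    return(as.integer(params$boundary_erosion))
  }
  r <- attr(vesselness, "support_radius_voxels")
  if (is.null(r)) 0L else as.integer(r)
}

#' Threshold + minimum-cluster ePVS segmentation
#'
#' Voxels with vesselness `>= h` inside the (optionally eroded) region mask
#' are grouped into connected components; components smaller than
#' `min_cluster_voxels` are removed.
#'
#' @param vesselness A [glym_volume()] vesselness map.
#' @param region_mask Logical 3-D array (nonempty).
#' @param params A [segmentation_params()].
#' @return An object of class `epvs_segmentation`: list with `mask` (logical
#'   array), `cluster_labels` (integer array), `cluster_sizes` (sizes of the
#'   retained clusters), `n_clusters`, `h_used` and the params.
#' @export
segment_epvs <- function(vesselness, region_mask, params = segmentation_params()) {
  assert_that(inherits(vesselness, "glym_volume"), "vesselness must be a glym_volume")
  assert_that(any(region_mask), "region mask is empty")
  assert_that(identical(dim(vesselness$data), dim(region_mask)),
              "vesselness and region mask are not on the same grid")
  support <- region_mask
  er <- resolve_erosion(params, vesselness)
  if (er > 0) support <- erode_mask(support, er)
  h_used <- params$h
  if (params$threshold_mode == "quantile") {
    h_used <- as.numeric(stats::quantile(vesselness$data[support], params$h,
                                         names = FALSE, type = 7))
  }
  supra <- vesselness$data >= h_used & support
  lab <- label_components(supra, params$connectivity)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= params$min_cluster_voxels)
  mask <- array(lab %in% keep & lab > 0, dim(lab))
  ## relabel retained clusters consecutively
  lab_out <- array(0L, dim(lab))
  if (length(keep) > 0) {
    lab_out[mask] <- match(lab[mask], keep)
  }
  structure(list(mask = mask, cluster_labels = lab_out,
                 cluster_sizes = sizes[keep], n_clusters = length(keep),
                 h_used = h_used, erosion_used = er, params = params),
            class = "epvs_segmentation")
}

#' @export
print.epvs_segmentation <- function(x, ...) {
  cat(sprintf("<epvs_segmentation> %d cluster(s), %d voxel(s), h = %g\n",
              x$n_clusters, sum(x$mask), x$h_used))
  invisible(x)
}

#' Region-normalised ePVS burden
#'
#' `burden = 100 * (ePVS voxels inside region) / (region voxels)`. The voxel
#' volume cancels, so the result is a percentage of region volume.
#'
#' @param epvs_mask Logical 3-D array of segmented ePVS voxels.
#' @param region_mask Logical 3-D array; must be nonempty.
#' @return Burden in percent.
#' @export
compute_burden <- function(epvs_mask, region_mask) {
  assert_that(identical(dim(epvs_mask), dim(region_mask)),
              "masks are not on the same grid")
  n_region <- sum(region_mask)
  assert_that(n_region > 0, "region mask is empty")
  100 * sum(epvs_mask & region_mask) / n_region
}

#' Calibrate the vesselness threshold against a known burden
#'
#' Bisects `h` on the vesselness values inside the region until the
#' segmented burden (threshold + cluster filtering) matches a target burden.
#' Intended to be run once on a noise-free phantom with analytic true
#' burden, yielding an absolute threshold transferable to sibling data on
#' the same vesselness scale.
#'
#' @param vesselness A [glym_volume()].
#' @param region_mask Logical array.
#' @param target_burden_pct Target burden (percent of region volume).
#' @param params [segmentation_params()] whose `h` is ignored.
#' @param iterations Bisection steps (default 25).
#' @return The calibrated absolute threshold `h`, with the achieved burden
#'   as attribute `achieved_burden_pct`.
#' @export
calibrate_threshold <- function(vesselness, region_mask, target_burden_pct,
                                params = segmentation_params(),
                                iterations = 25) {
  assert_that(target_burden_pct >= 0 && target_burden_pct <= 100,
              "target burden must be in [0, 100] percent")
  support <- region_mask
  er <- resolve_erosion(params, vesselness)
  if (er > 0) support <- erode_mask(support, er)
  vals <- vesselness$data[support]
  lo <- 0; hi <- max(vals) * (1 + 1e-12)
  burden_at <- function(h) {
    p <- params; p$h <- h; p$threshold_mode <- "absolute"
    seg <- segment_epvs(vesselness, region_mask, p)
    compute_burden(seg$mask, region_mask)
  }
  b_max <- burden_at(hi * 1e-9)
  if (b_max < target_burden_pct) {
    warning(sprintf(paste("maximum reachable burden %.3f%% is below the target",
                          "%.3f%%; returning the most permissive threshold"),
                    b_max, target_burden_pct), call. = FALSE)
  }
  for (i in seq_len(iterations)) {
    mid <- (lo + hi) / 2
    b <- burden_at(mid)
    if (b > target_burden_pct) lo <- mid else hi <- mid
  }
  h <- hi   # burden(hi) <= target: prefer the conservative side
  structure(h, achieved_burden_pct = burden_at(h))
}

#' End-to-end ePVS pipeline on co-registered T1w/T2w volumes
#'
#' Stages: optional resampling to the working grid, WM-referenced
#' normalisation of both channels, EPC image, multiscale dark-tube Frangi
#' vesselness, per-region threshold + cluster segmentation, burden.
#'
#' @param t1w,t2w Co-registered [glym_volume()]s.
#' @param labels A [glym_labelmap()] on the same grid with WM (and optionally
#'   BG) regions.
#' @param regions Character vector of regions to segment (default
#'   `c("WM", "BG")`).
#' @param working_spacing Working grid spacing in mm (default 0.7); inputs
#'   already on this grid are not resampled.
#' @param epc_epsilon Guard for the EPC division.
#' @param frangi [frangi_params()].
#' @param seg_params Named list of [segmentation_params()] per region;
#'   defaults to the white-matter threshold 2e-7 and the slightly higher
#'   basal-ganglia threshold 3e-7, both with minimum cluster size 9.
#' @param manifest Optional run manifest to append to.
#' @return An object of class `epvs_result`: per-region list with the
#'   segmentation, `burden_pct`, plus the shared `epc` and `vesselness`
#'   volumes and the updated manifest.
#' @export
run_epvs <- function(t1w, t2w, labels, regions = c("WM", "BG"),
                     working_spacing = 0.7,
                     epc_epsilon = 1e-6,
                     frangi = frangi_params(),
                     seg_params = list(WM = segmentation_params(h = 2e-7),
                                       BG = segmentation_params(h = 3e-7)),
                     manifest = NULL) {
  assert_that(inherits(labels, "glym_labelmap"), "labels must be a glym_labelmap")
  assert_that(same_grid(t1w, t2w) && same_grid(t1w, labels),
              "T1w, T2w and labels must share one grid")
  ws <- rep(working_spacing, length.out = 3)
  if (max(abs(t1w$spacing - ws)) > 1e-9) {
    t1w <- resample_volume(t1w, ws, "linear")
    t2w <- resample_volume(t2w, ws, "linear")
    labels <- resample_labelmap(labels, ws)
  }
  wm <- region_mask(labels, "WM")
  t1n <- normalize_intensity(t1w, wm)
  t2n <- normalize_intensity(t2w, wm)
  epc <- compute_epc(t1n, t2n, epc_epsilon)
  vess <- frangi_vesselness(epc, frangi)
  ## record the truncated-kernel support radius of the largest scale so the
  ## segmentation can exclude boundary-interface responses exactly
  attr(vess, "support_radius_voxels") <-
    max(ceiling(4 * max(frangi$scales) / vess$spacing))
  out <- list()
  for (rn in regions) {
    rm <- region_mask(labels, rn)
    p <- seg_params[[rn]] %||% segmentation_params()
    seg <- segment_epvs(vess, rm, p)
    out[[rn]] <- list(segmentation = seg,
                      burden_pct = compute_burden(seg$mask, rm),
                      n_clusters = seg$n_clusters)
  }
  manifest <- manifest_add(manifest, "epvs",
                           params = list(working_spacing = ws,
                                         epc_epsilon = epc_epsilon,
                                         scales = frangi$scales,
                                         regions = regions),
                           inputs = list(t1w = content_digest(t1w$data),
                                         t2w = content_digest(t2w$data)))
  structure(list(regions = out, epc = epc, vesselness = vess,
                 manifest = manifest),
            class = "epvs_result")
}

#' @export
print.epvs_result <- function(x, ...) {
  cat("<epvs_result>\n")
  for (rn in names(x$regions)) {
    r <- x$regions[[rn]]
    cat(sprintf("  %s: burden %.3f%%, %d cluster(s)\n",
                rn, r$burden_pct, r$n_clusters))
  }
  invisible(x)
}
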