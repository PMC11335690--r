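#' Specification for a structural (T1w/T2w) phantom
#'
#' Describes a block-compartment "standard space" head phantom: a white-matter
#' (WM) slab containing two basal-ganglia (BG) blocks and a central CSF
#' ventricle, wrapped in a gray-matter (GM) shell. Perivascular spaces are
#' rendered as straight cylindrical inclusions with CSF-like contrast (dark on
#' T1w, bright on T2w), placed inside WM and/or BG. Ground-truth PVS volume is
#' analytic via 3x supersampled partial-volume rendering, so the true burden
#' is known exactly by construction.
#'
#' @param shape Grid dimensions (length 3, voxels).
#' @param spacing Voxel size in mm (length 3 or scalar).
#' @param intensities Named list per region (`WM`, `GM`, `BG`, `CSF`, `PVS`)
#'   of `c(t1w =, t2w =)` intensities in arbitrary units.
#' @param pvs_count Named vector: number of tubes per region, e.g.
#'   `c(WM = 20, BG = 4)`.
#' @param pvs_radius_mm Length-2 range of tube radii (mm).
#' @param pvs_length_mm Length-2 range of tube lengths (mm).
#' @param orientation `"uniform"` (random 3-D directions) or `"axial"`
#'   (z-aligned tubes, convenient for geometry checks).
#' @param noise_sigma Gaussian noise sd per channel, in the same arbitrary
#'   units (0 = noiseless).
#' @param margin_voxels Tubes are kept at least this many voxels away from
#'   the region boundary so that boundary-localised filter responses cannot
#'   overlap true PVS. Either a single number or a named vector per region;
#'   the WM default matches the boundary erosion of the default
#'   segmentation support, the BG default is smaller (the region is thin,
#'   so BG tubes may be cropped by the support erosion -- BG segmentation
#'   is the less reliable of the two by construction).
#' @param seed RNG seed; the phantom is a pure function of the spec.
#' @return An object of class `structural_phantom_spec`.
#' @export
structural_phantom_spec <- function(shape = c(72, 72, 72),
                                    spacing = c(0.7, 0.7, 0.7),
                                    intensities = list(
                                      WM  = c(t1w = 1.00, t2w = 1.00),
                                      GM  = c(t1w = 0.70, t2w = 1.30),
                                      BG  = c(t1w = 0.78, t2w = 1.15),
                                      CSF = c(t1w = 0.20, t2w = 2.80),
                                      PVS = c(t1w = 0.20, t2w = 2.80)),
                                    pvs_count = c(WM = 12, BG = 2),
                                    pvs_radius_mm = c(0.4, 0.7),
                                    pvs_length_mm = c(4, 10),
                                    orientation = c("uniform", "axial"),
                                    noise_sigma = c(t1w = 0.02, t2w = 0.03),
                                    margin_voxels = c(WM = 6, BG = 2),
                                    seed = 1L) {
  orientation <- match.arg(orientation)
  spacing <- rep(as.numeric(spacing), length.out = 3)
  assert_that(all(shape >= 16), "phantom grid must be at least 16 voxels per axis")
  assert_that(all(pvs_radius_mm > 0) && all(pvs_length_mm > 0),
              "tube radii and lengths must be positive")
  assert_that(all(pvs_count >= 0), "pvs_count must be >= 0")
  assert_that(all(noise_sigma >= 0), "noise_sigma must be >= 0")
  structure(list(shape = as.integer(shape), spacing = spacing,
                 intensities = intensities, pvs_count = pvs_count,
                 pvs_radius_mm = pvs_radius_mm, pvs_length_mm = pvs_length_mm,
                 orientation = orientation, noise_sigma = noise_sigma,
                 margin_voxels = round(margin_voxels), seed = seed),
            class = "structural_phantom_spec")
}

## Centered affine: world origin at the grid centre so left/right mirror
## symmetry is exact on the voxel lattice.
centered_affine <- function(shape, spacing) {
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- -(shape - 1) / 2 * spacing
  aff
}

## Block-compartment label layout shared by the structural phantom.
## 1 = WM, 2 = GM, 3 = BG, 4 = CSF.
phantom_labels <- function(shape, spacing) {
  lab <- array(0L, shape)
  d <- shape
  shell <- pmax(2L, round(d * 0.06))
  gm_lo <- shell + 1L; gm_hi <- d - shell
  lab[gm_lo[1]:gm_hi[1], gm_lo[2]:gm_hi[2], gm_lo[3]:gm_hi[3]] <- 2L
  wm_lo <- gm_lo + pmax(1L, round(d * 0.06)); wm_hi <- gm_hi - pmax(1L, round(d * 0.06))
  lab[wm_lo[1]:wm_hi[1], wm_lo[2]:wm_hi[2], wm_lo[3]:wm_hi[3]] <- 1L
  ## central CSF ventricle
  c0 <- round(d / 2)
  vw <- pmax(1L, round(d * 0.05))
  lab[(c0[1] - vw[1]):(c0[1] + vw[1]),
      (c0[2] - vw[2]):(c0[2] + vw[2]),
      (c0[3] - vw[3]):(c0[3] + vw[3])] <- 4L
  ## two BG blocks flanking the ventricle: elongated along x, thin in y/z so
  ## the surrounding WM keeps slabs thick enough to host tubes after the
  ## boundary erosion of the segmentation support
  bgw <- pmax(2L, round(d * c(0.15, 0.08, 0.08)))
  off <- vw[1] + bgw[1] + pmax(2L, round(d[1] * 0.04))
  for (s in c(-1L, 1L)) {
    xc <- c0[1] + s * off
    lab[(xc - bgw[1]):(xc + bgw[1]),
        (c0[2] - bgw[2]):(c0[2] + bgw[2]),
        (c0[3] - bgw[3]):(c0[3] + bgw[3])] <- 3L
  }
  lab
}

## Partial-volume render of one cylinder (centre p0, unit axis u, radius r,
## length L; p0 in 0-based voxel units, r/L in mm) into `frac`, via ss^3
## supersampling with antialiased subvoxel coverage: each subvoxel
## contributes a linear ramp in its signed distance to the cylinder surface,
## which integrates the cross-section area to O(subvoxel^2) instead of the
## O(subvoxel) error of binary point sampling. Returns the updated fraction
## array and the covered in-region subvoxel mass.
render_cylinder <- function(frac, region, p0, u, r_mm, L_mm, spacing, ss = 3L) {
  d <- dim(frac)
  r_vox <- r_mm / spacing            # per-axis radius in voxel units
  half <- L_mm / 2
  ## bounding box in voxel indices (1-based)
  ext <- half * abs(u) / spacing + r_mm / spacing + 1
  lo <- pmax(1L, floor(p0 - ext) + 1L)
  hi <- pmin(d, ceiling(p0 + ext) + 1L)
  if (any(lo > hi)) return(list(frac = frac, inside = 0, total = 0))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  nb <- c(length(xs), length(ys), length(zs))
  ## subvoxel centre offsets in voxel units
  so <- (seq_len(ss) - (ss + 1) / 2) / ss
  sub_mm <- mean(spacing) / ss              # subvoxel edge in mm
  acc <- array(0, nb)
  for (ox in so) for (oy in so) for (oz in so) {
    ## world-mm displacement of subvoxel centres from the cylinder centre
    px <- (xs - 1 + ox - p0[1]) * spacing[1]
    py <- (ys - 1 + oy - p0[2]) * spacing[2]
    pz <- (zs - 1 + oz - p0[3]) * spacing[3]
    PX <- array(px, nb)
    PY <- array(rep(py, each = nb[1]), nb)
    PZ <- array(rep(pz, each = nb[1] * nb[2]), nb)
    t_ax <- PX * u[1] + PY * u[2] + PZ * u[3]
    d2 <- (PX - t_ax * u[1])^2 + (PY - t_ax * u[2])^2 + (PZ - t_ax * u[3])^2
    w_rad <- pmin(pmax((r_mm - sqrt(d2)) / sub_mm + 0.5, 0), 1)
    w_ax <- pmin(pmax((half - abs(t_ax)) / sub_mm + 0.5, 0), 1)
    acc <- acc + w_rad * w_ax
  }
  sub_in <- acc * region[xs, ys, zs]       # subvoxel hits inside the region
  frac[xs, ys, zs] <- pmin(1, frac[xs, ys, zs] + acc / ss^3)
  list(frac = frac, inside = sum(sub_in), total = sum(acc))
}

#' Generate a structural phantom with known PVS content
#'
#' @param spec A [structural_phantom_spec()].
#' @return An object of class `structural_phantom`: list with `t1w`, `t2w`
#'   ([glym_volume()]s), `labels` ([glym_labelmap()]), `pvs_truth` (logical
#'   array, partial-volume fraction >= 0.5), `pvs_fraction` (the analytic
#'   per-voxel PVS volume fraction before noise), and `true_burden` (percent,
#'   named per region, computed from the supersampled analytic volume).
#' @export
make_structural_phantom <- function(spec) {
  assert_that(inherits(spec, "structural_phantom_spec"),
              "spec must be a structural_phantom_spec")
  with_seed(spec$seed, {
    d <- spec$shape; spacing <- spec$spacing
    lab <- phantom_labels(d, spacing)
    affine <- centered_affine(d, spacing)
    legend <- c(`1` = "WM", `2` = "GM", `3` = "BG", `4` = "CSF")
    frac <- array(0, d)
    region_names <- names(spec$pvs_count)
    inside_count <- stats::setNames(numeric(length(region_names)), region_names)
    for (rn in region_names) {
      n_tubes <- spec$pvs_count[[rn]]
      if (n_tubes == 0) next
      rid <- c(WM = 1L, GM = 2L, BG = 3L, CSF = 4L)[[rn]]
      region <- lab == rid
      margin_r <- if (rn %in% names(spec$margin_voxels)) {
        spec$margin_voxels[[rn]]
      } else max(spec$margin_voxels)
      ## interior band: the whole tube must stay `margin_r` voxels away from
      ## the region border, so a boundary-eroded segmentation support still
      ## contains every tube in full
      interior <- erode_mask(region, margin_r)
      idx <- which(interior)
      assert_that(length(idx) > 0,
                  "region %s too small for margin %d", rn, margin_r)
      coords <- arrayInd(idx, d)
      for (k in seq_len(n_tubes)) {
        placed <- FALSE
        for (try in 1:200) {
          p0 <- coords[sample.int(nrow(coords), 1L), ] - 1 +
            stats::runif(3, -0.5, 0.5)
          u <- if (spec$orientation == "axial") c(0, 0, 1) else {
            z <- stats::rnorm(3); z / sqrt(sum(z^2))
          }
          r_mm <- stats::runif(1, spec$pvs_radius_mm[1], spec$pvs_radius_mm[2])
          L_mm <- stats::runif(1, spec$pvs_length_mm[1], spec$pvs_length_mm[2])
          res <- render_cylinder(frac, interior, p0, u, r_mm, L_mm, spacing)
          if (res$total > 0 && res$inside / res$total > 0.99) {
            frac <- res$frac
            inside_count[[rn]] <- inside_count[[rn]] + res$inside
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop_glym("could not place tube %d in region %s after 200 tries", k, rn)
        }
      }
    }
    ## analytic burden: supersampled PVS volume over region volume
    true_burden <- c(WM = 0, BG = 0)
    for (rn in c("WM", "BG")) {
      rid <- c(WM = 1L, BG = 3L)[[rn]]
      n_reg <- sum(lab == rid)
      ## fraction integrates subvoxel volume: sum(frac over region voxels)
      true_burden[[rn]] <- 100 * sum(frac[lab == rid]) / n_reg
    }
    ## render channels
    ints <- spec$intensities
    base <- function(channel) {
      v <- array(0, d)
      v[lab == 1L] <- ints$WM[[channel]]
      v[lab == 2L] <- ints$GM[[channel]]
      v[lab == 3L] <- ints$BG[[channel]]
      v[lab == 4L] <- ints$CSF[[channel]]
      v <- v * (1 - frac) + ints$PVS[[channel]] * frac
      v
    }
    t1 <- base("t1w"); t2 <- base("t2w")
    if (spec$noise_sigma[["t1w"]] > 0) {
      t1 <- t1 + array(stats::rnorm(prod(d), 0, spec$noise_sigma[["t1w"]]), d)
    }
    if (spec$noise_sigma[["t2w"]] > 0) {
      t2 <- t2 + array(stats::rnorm(prod(d), 0, spec$noise_sigma[["t2w"]]), d)
    }
    structure(list(
      t1w = glym_volume(t1, spacing, affine),
      t2w = glym_volume(t2, spacing, affine),
      labels = glym_labelmap(lab, spacing, affine, legend = legend),
      pvs_truth = frac >= 0.5,
      pvs_fraction = frac,
      true_burden = true_burden,
      spec = spec), class = "structural_phantom")
  })
}

## Chebyshev erosion by `r` voxels (iterated 26-neighbour erosion).
erode_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  m <- mask
  for (i in seq_len(r)) {
    m <- shrink_once(m)
    if (!any(m)) break
  }
  m
}

## Logical shift along one axis with FALSE padding at the border.
shift_mask <- function(m, ax, s) {
  d <- dim(m)
  out <- array(FALSE, d)
  n <- d[ax]
  if (n <= abs(s)) return(out)
  src <- if (s > 0) 1:(n - s) else (1 - s):n
  dst <- if (s > 0) (1 + s):n else 1:(n + s)
  if (ax == 1) out[dst, , ] <- m[src, , , drop = FALSE]
  else if (ax == 2) out[, dst, ] <- m[, src, , drop = FALSE]
  else out[, , dst] <- m[, , src, drop = FALSE]
  out
}

## One step of 3x3x3 box erosion, done separably per axis.
shrink_once <- function(m) {
  for (ax in 1:3) {
    m <- m & shift_mask(m, ax, 1L) & shift_mask(m, ax, -1L)
  }
  m
}
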