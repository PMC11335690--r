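#' Image volume container
#'
#' A `glym_volume` is the carrier for every 3-D scalar image in the package
#' (T1w, T2w, EPC, vesselness, diffusivity maps): a numeric array plus voxel
#' spacing in mm, a 4x4 voxel-to-world affine, and a free-text space tag.
#' Voxel indices are 0-based in world-coordinate computations; registration is
#' assumed to have happened upstream, so all volumes entering a pipeline stage
#' must share one grid.
#'
#' @param data 3-D numeric array; all values must be finite.
#' @param spacing Numeric length-3, voxel size in mm per axis; strictly
#'   positive.
#' @param affine Optional 4x4 voxel-to-world matrix (0-based voxel indices).
#'   Defaults to a diagonal affine built from `spacing` with origin 0.
#' @param space_tag Free-text label for the coordinate space, e.g.
#'   `"phantom-std"`.
#' @return An object of class `glym_volume`.
#' @export
glym_volume <- function(data, spacing = c(1, 1, 1), affine = NULL,
                        space_tag = "phantom-std") {
  data <- unclass(data)
  assert_that(is.numeric(data) || is.logical(data), "volume data must be numeric")
  data <- array(as.numeric(data), dim = dim(data) %||% length(data))
  assert_that(length(dim(data)) == 3L, "volume data must be a 3-D array")
  assert_that(all(dim(data) >= 1L), "volume has a zero-length axis")
  assert_that(all(is.finite(data)), "volume contains non-finite voxels")
  spacing <- as.numeric(spacing)
  assert_that(length(spacing) == 3L && all(is.finite(spacing)) && all(spacing > 0),
              "spacing must be 3 strictly positive numbers (mm)")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- as.matrix(affine)
  assert_that(all(dim(affine) == c(4L, 4L)), "affine must be 4x4")
  assert_that(abs(det(affine)) > 1e-12, "affine must be invertible")
  structure(list(data = data, spacing = spacing, affine = affine,
                 space_tag = as.character(space_tag)),
            class = "glym_volume")
}

#' @export
print.glym_volume <- function(x, ...) {
  cat(sprintf("<glym_volume> %s  spacing %s mm  space '%s'\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 4), collapse = "x"),
              x$space_tag))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.glym_volume <- function(x) dim(x$data)

#' Label map container
#'
#' Integer region labels on the grid of a companion [glym_volume()], plus a
#' legend mapping each nonzero label to a region name (WM, GM, BG, CSF, ...).
#' Stands in for an upstream anatomical segmentation, which is outside the
#' scope of this package.
#'
#' @param labels 3-D array of nonnegative integers (0 = background).
#' @param spacing,affine,space_tag As in [glym_volume()].
#' @param legend Named character vector: names are label integers as strings,
#'   values are region names. Must cover every nonzero label present.
#' @return An object of class `glym_labelmap`.
#' @export
glym_labelmap <- function(labels, spacing = c(1, 1, 1), affine = NULL,
                          space_tag = "phantom-std",
                          legend = c(`1` = "WM", `2` = "GM", `3` = "BG", `4` = "CSF")) {
  labels <- unclass(labels)
  assert_that(length(dim(labels)) == 3L, "labels must be a 3-D array")
  assert_that(all(is.finite(labels)) && all(labels >= 0) &&
                all(labels == round(labels)),
              "labels must be nonnegative integers")
  present <- setdiff(sort(unique(as.vector(labels))), 0)
  missing <- setdiff(as.character(present), names(legend))
  assert_that(length(missing) == 0,
              "legend missing entries for labels: %s", paste(missing, collapse = ", "))
  v <- glym_volume(labels, spacing = spacing, affine = affine, space_tag = space_tag)
  structure(list(labels = array(as.integer(labels), dim(labels)),
                 spacing = v$spacing, affine = v$affine,
                 space_tag = v$space_tag, legend = legend),
            class = "glym_labelmap")
}

#' @export
print.glym_labelmap <- function(x, ...) {
  cat(sprintf("<glym_labelmap> %s  spacing %s mm\n",
              paste(dim(x$labels), collapse = "x"),
              paste(format(x$spacing, digits = 4), collapse = "x")))
  tab <- table(x$labels[x$labels > 0])
  for (l in names(tab)) {
    cat(sprintf("  %s (%s): %d voxels\n", x$legend[[l]], l, tab[[l]]))
  }
  invisible(x)
}

#' Binary region mask from a label map
#'
#' @param labels A [glym_labelmap()].
#' @param region Region name as in the legend (e.g. `"WM"`).
#' @return Logical 3-D array.
#' @export
region_mask <- function(labels, region) {
  assert_that(inherits(labels, "glym_labelmap"), "labels must be a glym_labelmap")
  ids <- as.integer(names(labels$legend)[labels$legend == region])
  assert_that(length(ids) > 0, "region '%s' not present in legend", region)
  array(labels$labels %in% ids, dim(labels$labels))
}

same_grid <- function(a, b, tol = 1e-6) {
  da <- if (inherits(a, "glym_labelmap")) dim(a$labels) else dim(a$data)
  db <- if (inherits(b, "glym_labelmap")) dim(b$labels) else dim(b$data)
  identical(da, db) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$affine - b$affine)) < tol
}

#' Read a 3-D NIfTI volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file with a 3-D payload.
#' @return A [glym_volume()] with spacing and affine taken from the header.
#' @export
read_volume <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  assert_that(length(d) == 3L,
              "expected a 3-D volume, got %d-D payload in %s", length(d), path)
  assert_that(all(d >= 1L), "volume in %s has a zero-length axis", path)
  data <- as.array(img)
  assert_that(all(is.finite(data)), "volume in %s contains non-finite voxels", path)
  aff <- unclass(RNifti::xform(img))
  affine <- rbind(aff[1:3, , drop = FALSE], c(0, 0, 0, 1))
  glym_volume(data, spacing = RNifti::pixdim(img)[1:3], affine = affine,
              space_tag = "from-file")
}

#' Write a volume to NIfTI
#'
#' Lossless for double payloads (`datatype = "double"`, the default).
#'
#' @param v A [glym_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param overwrite Refuse to clobber an existing file unless `TRUE`.
#' @param datatype NIfTI on-disk datatype, passed to [RNifti::writeNifti()].
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, overwrite = FALSE, datatype = "double") {
  assert_that(inherits(v, "glym_volume"), "v must be a glym_volume")
  if (file.exists(path) && !overwrite) {
    stop_glym("file exists and overwrite = FALSE: %s", path)
  }
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  RNifti::qform(img) <- structure(v$affine, code = 2L)
  RNifti::sform(img) <- structure(v$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a 4-D DWI series to NIfTI
#'
#' @param data 4-D array (x, y, z, volume).
#' @param spacing Voxel size in mm (length 3).
#' @param path Output path.
#' @param overwrite As in [write_volume()].
#' @return `path`, invisibly.
#' @export
write_dwi <- function(data, spacing, path, overwrite = FALSE) {
  assert_that(length(dim(data)) == 4L, "DWI payload must be 4-D")
  if (file.exists(path) && !overwrite) {
    stop_glym("file exists and overwrite = FALSE: %s", path)
  }
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- c(spacing, 1)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a 4-D DWI series
#'
#' @param path NIfTI file with 4-D payload.
#' @return List with `data` (4-D array) and `spacing` (mm, length 3).
#' @export
read_dwi <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  img <- RNifti::readNifti(path)
  assert_that(length(dim(img)) == 4L, "expected a 4-D series in %s", path)
  list(data = as.array(img), spacing = RNifti::pixdim(img)[1:3])
}

#' Resample a volume to a new voxel spacing
#'
#' The output grid keeps the input's world origin and direction and covers the
#' same world extent (voxel-centre span). Linear mode performs trilinear
#' interpolation and cannot overshoot the input value range; nearest mode is
#' for label payloads and introduces no new values.
#'
#' @param v A [glym_volume()].
#' @param target_spacing Numeric length-3 (or scalar, recycled), mm.
#' @param mode `"linear"` or `"nearest"`.
#' @return A [glym_volume()] on the new grid.
#' @export
resample_volume <- function(v, target_spacing, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  assert_that(inherits(v, "glym_volume"), "v must be a glym_volume")
  target_spacing <- rep(as.numeric(target_spacing), length.out = 3)
  assert_that(all(is.finite(target_spacing)) && all(target_spacing > 0),
              "target spacing must be strictly positive")
  d <- dim(v$data)
  span <- (d - 1) * v$spacing                     # world extent of voxel centres
  n_out <- pmax(1L, as.integer(floor(span / target_spacing + 1e-9)) + 1L)
  ## source voxel coordinates (0-based, continuous) of output voxel centres
  scale <- target_spacing / v$spacing
  cx <- (seq_len(n_out[1]) - 1) * scale[1]
  cy <- (seq_len(n_out[2]) - 1) * scale[2]
  cz <- (seq_len(n_out[3]) - 1) * scale[3]
  out <- interp_trilinear(v$data, cx, cy, cz, nearest = (mode == "nearest"))
  new_affine <- v$affine %*% diag(c(scale, 1))
  glym_volume(out, spacing = target_spacing, affine = new_affine,
              space_tag = v$space_tag)
}

## Separable gather interpolation on a full output grid. cx/cy/cz are 0-based
## continuous source coordinates per output axis; clamped to the valid range.
interp_trilinear <- function(arr, cx, cy, cz, nearest = FALSE) {
  d <- dim(arr)
  clamp <- function(x, hi) pmin(pmax(x, 0), hi)
  cx <- clamp(cx, d[1] - 1); cy <- clamp(cy, d[2] - 1); cz <- clamp(cz, d[3] - 1)
  if (nearest) {
    ix <- as.integer(round(cx)) + 1L
    iy <- as.integer(round(cy)) + 1L
    iz <- as.integer(round(cz)) + 1L
    return(arr[ix, iy, iz, drop = FALSE])
  }
  x0 <- pmin(floor(cx), max(d[1] - 2, 0)); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(cy), max(d[2] - 2, 0)); y0 <- pmax(y0, 0)
  z0 <- pmin(floor(cz), max(d[3] - 2, 0)); z0 <- pmax(z0, 0)
  fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
  i0 <- as.integer(x0) + 1L; j0 <- as.integer(y0) + 1L; k0 <- as.integer(z0) + 1L
  i1 <- pmin(i0 + 1L, d[1]); j1 <- pmin(j0 + 1L, d[2]); k1 <- pmin(k0 + 1L, d[3])
  n <- c(length(cx), length(cy), length(cz))
  FX <- array(fx, n); FY <- array(rep(fy, each = n[1]), n)
  FZ <- array(rep(fz, each = n[1] * n[2]), n)
  g <- function(ii, jj, kk) arr[ii, jj, kk, drop = FALSE]
  out <- g(i0, j0, k0) * (1 - FX) * (1 - FY) * (1 - FZ) +
         g(i1, j0, k0) * FX       * (1 - FY) * (1 - FZ) +
         g(i0, j1, k0) * (1 - FX) * FY       * (1 - FZ) +
         g(i1, j1, k0) * FX       * FY       * (1 - FZ) +
         g(i0, j0, k1) * (1 - FX) * (1 - FY) * FZ +
         g(i1, j0, k1) * FX       * (1 - FY) * FZ +
         g(i0, j1, k1) * (1 - FX) * FY       * FZ +
         g(i1, j1, k1) * FX       * FY       * FZ
  out
}

#' Resample a label map (nearest neighbour)
#'
#' @param lm A [glym_labelmap()].
#' @param target_spacing mm, as in [resample_volume()].
#' @return A [glym_labelmap()] on the new grid.
#' @export
resample_labelmap <- function(lm, target_spacing) {
  assert_that(inherits(lm, "glym_labelmap"), "lm must be a glym_labelmap")
  v <- glym_volume(lm$labels, spacing = lm$spacing, affine = lm$affine,
                   space_tag = lm$space_tag)
  r <- resample_volume(v, target_spacing, mode = "nearest")
  glym_labelmap(r$data, spacing = r$spacing, affine = r$affine,
                space_tag = r$space_tag, legend = lm$legend)
}
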