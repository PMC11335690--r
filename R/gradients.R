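#' Diffusion gradient table
#'
#' Per-volume b-value (s/mm^2) and unit gradient direction pairs. The on-disk
#' dialect is the FSL two-file convention: a `.bval` file with one row of
#' b-values and a `.bvec` file with three rows (x, y, z components), one
#' column per volume.
#'
#' @param bvals Numeric vector of b-values in s/mm^2.
#' @param bvecs 3 x N matrix (or N x 3, auto-detected) of directions.
#' @return An object of class `glym_gradients`: data frame with columns
#'   `bval`, `gx`, `gy`, `gz`.
#' @export
gradient_table <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L && ncol(bvecs) == 3L) bvecs <- t(bvecs)
  assert_that(nrow(bvecs) == 3L, "bvecs must be 3 x N")
  assert_that(ncol(bvecs) == length(bvals),
              "bval/bvec length mismatch: %d vs %d", length(bvals), ncol(bvecs))
  assert_that(all(is.finite(bvals)) && all(bvals >= 0), "b-values must be finite and >= 0")
  assert_that(any(bvals == 0), "gradient table must contain at least one b = 0 entry")
  norms <- sqrt(colSums(bvecs^2))
  nz <- bvals > 0
  if (any(nz & norms == 0)) {
    stop_glym("all-zero gradient direction with b > 0 at volume(s) %s",
              paste(which(nz & norms == 0), collapse = ", "))
  }
  off <- nz & abs(norms - 1) > 1e-3
  if (any(off)) {
    warning(sprintf("renormalized %d non-unit gradient direction(s)", sum(off)),
            call. = FALSE)
  }
  renorm <- nz & norms > 0
  bvecs[, renorm] <- sweep(bvecs[, renorm, drop = FALSE], 2, norms[renorm], "/")
  bvecs[, !nz] <- 0
  g <- data.frame(bval = bvals, gx = bvecs[1, ], gy = bvecs[2, ], gz = bvecs[3, ])
  class(g) <- c("glym_gradients", "data.frame")
  g
}

#' Read an FSL-dialect gradient table
#'
#' @param bval_path Path to the whitespace-separated b-value file.
#' @param bvec_path Path to the 3-row direction file.
#' @return A [gradient_table()]. Non-unit nonzero directions are renormalized
#'   with a warning.
#' @export
read_gradient_table <- function(bval_path, bvec_path) {
  assert_that(file.exists(bval_path), "file not found: %s", bval_path)
  assert_that(file.exists(bvec_path), "file not found: %s", bvec_path)
  bvals <- scan(bval_path, quiet = TRUE)
  rows <- readLines(bvec_path)
  rows <- rows[nzchar(trimws(rows))]
  assert_that(length(rows) == 3L, "bvec file must have 3 rows, found %d", length(rows))
  bvecs <- t(vapply(rows, function(r) scan(text = r, quiet = TRUE),
                    numeric(length(bvals))))
  gradient_table(bvals, bvecs)
}

#' Write a gradient table in the FSL dialect
#'
#' @param g A [gradient_table()].
#' @param bval_path,bvec_path Output paths.
#' @return Invisibly, `c(bval_path, bvec_path)`.
#' @export
write_gradient_table <- function(g, bval_path, bvec_path) {
  assert_that(inherits(g, "glym_gradients"), "g must be a glym_gradients")
  writeLines(paste(format(g$bval, trim = TRUE), collapse = " "), bval_path)
  m <- rbind(g$gx, g$gy, g$gz)
  writeLines(apply(m, 1, function(r) paste(format(r, trim = TRUE, digits = 15),
                                           collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Deterministic two-shell acquisition scheme
#'
#' Builds the default diffusion encoding emulated by the phantom generators:
#' `n_b0` b = 0 volumes, then `n_inner` directions on the inner shell and
#' `n_outer` on the outer shell. Directions are spread quasi-uniformly over
#' the sphere with a golden-angle (Fibonacci) spiral, so the scheme is
#' reproducible without any RNG.
#'
#' @param n_b0 Number of b = 0 volumes (default 2).
#' @param n_inner,n_outer Directions on each shell (defaults 45 and 90).
#' @param b_inner,b_outer Shell b-values in s/mm^2 (defaults 1000 and 2500).
#' @return A [gradient_table()] with `n_b0 + n_inner + n_outer` entries.
#' @export
default_gradient_table <- function(n_b0 = 2, n_inner = 45, n_outer = 90,
                                   b_inner = 1000, b_outer = 2500) {
  fib_sphere <- function(n, offset = 0.5) {
    i <- seq_len(n) - offset
    phi <- acos(1 - 2 * i / n)
    theta <- pi * (1 + sqrt(5)) * i
    rbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  }
  bvals <- c(rep(0, n_b0), rep(b_inner, n_inner), rep(b_outer, n_outer))
  bvecs <- cbind(matrix(0, 3, n_b0), fib_sphere(n_inner), fib_sphere(n_outer, 0.25))
  gradient_table(bvals, bvecs)
}
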