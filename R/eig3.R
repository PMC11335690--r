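## Closed-form eigenvalues of many symmetric 3x3 matrices at once, via the
## trigonometric method (Cardano). Inputs are arrays (or vectors) of the six
## unique components; outputs are the three eigenvalues in *descending
## algebraic* order. Used by both the Hessian vesselness filter and the
## tensor-field eigenvalue clamp, where per-voxel eigen() calls would be far
## too slow.
eig3sym <- function(a11, a22, a33, a12, a13, a23) {
  q <- (a11 + a22 + a33) / 3
  p1 <- a12^2 + a13^2 + a23^2
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  iso <- p < .Machine$double.eps * (abs(q) + 1)
  ps <- ifelse(iso, 1, p)   # avoid 0/0; overwritten below for iso entries
  b11 <- (a11 - q) / ps; b22 <- (a22 - q) / ps; b33 <- (a33 - q) / ps
  b12 <- a12 / ps; b13 <- a13 / ps; b23 <- a23 / ps
  detB <- b11 * (b22 * b33 - b23^2) -
          b12 * (b12 * b33 - b23 * b13) +
          b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  e1[iso] <- q[iso]; e2[iso] <- q[iso]; e3[iso] <- q[iso]
  list(e1 = e1, e2 = e2, e3 = e3)   # e1 >= e2 >= e3
}

## Same eigenvalues reordered by *increasing magnitude* (|l1| <= |l2| <= |l3|),
## the ordering the vesselness ratios are defined on.
eig3sym_absorder <- function(a11, a22, a33, a12, a13, a23) {
  e <- eig3sym(a11, a22, a33, a12, a13, a23)
  m <- cbind(as.vector(e$e1), as.vector(e$e2), as.vector(e$e3))
  am <- abs(m)
  ## rank the three columns by |.| rowwise without apply()
  o1 <- (am[, 1] > am[, 2]) + (am[, 1] > am[, 3])
  o2 <- (am[, 2] >= am[, 1]) + (am[, 2] > am[, 3])
  o3 <- (am[, 3] >= am[, 1]) + (am[, 3] >= am[, 2])
  out <- matrix(0, nrow(m), 3)
  idx <- cbind(seq_len(nrow(m)), o1 + 1L); out[idx] <- m[, 1]
  idx <- cbind(seq_len(nrow(m)), o2 + 1L); out[idx] <- m[, 2]
  idx <- cbind(seq_len(nrow(m)), o3 + 1L); out[idx] <- m[, 3]
  list(l1 = out[, 1], l2 = out[, 2], l3 = out[, 3])
}
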