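## Independent oracles the tests compare the package against. These are
## deliberately naive implementations (breadth-first search, exhaustive
## enumeration, direct formula evaluation) kept free of any package
## internals that they check.

## Breadth-first-search flood fill: returns an integer component labelling
## of `mask` under the given connectivity.
oracle_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  manh <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- switch(as.character(connectivity),
                 `6` = offs[manh == 1, ], `18` = offs[manh <= 2, ], offs)
  offs <- as.matrix(offs)
  lab <- array(0L, d)
  todo <- which(mask)
  coords <- arrayInd(todo, d)
  rownames(coords) <- NULL
  coord_of <- array(0L, c(prod(d), 3))
  coord_of[todo, ] <- coords
  comp <- 0L
  for (s in todo) {
    if (lab[s] > 0L) next
    comp <- comp + 1L
    queue <- integer(4096); queue[1] <- s; head <- 1L; tail <- 1L
    lab[s] <- comp
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      cv <- coord_of[v, ]
      for (k in seq_len(nrow(offs))) {
        nb <- cv + offs[k, ]
        if (any(nb < 1L) || any(nb > d)) next
        li <- nb[1] + (nb[2] - 1L) * d[1] + (nb[3] - 1L) * d[1] * d[2]
        if (mask[li] && lab[li] == 0L) {
          lab[li] <- comp
          tail <- tail + 1L
          if (tail > length(queue)) queue <- c(queue, integer(length(queue)))
          queue[tail] <- li
        }
      }
    }
  }
  lab
}

## Threshold + min-cluster segmentation via the BFS oracle.
oracle_segment <- function(vess, region, h, min_size, connectivity = 26) {
  supra <- vess >= h & region
  lab <- oracle_components(supra, connectivity)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  array(lab %in% keep & lab > 0, dim(lab))
}

## Exhaustive pairwise concordance AUC with tie correction.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

## Brute-force Benjamini-Hochberg: adj_(i) = min_{j >= i} m * p_(j) / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

## Welch formula evaluated directly.
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

## Pearson r and its t-transform p, evaluated directly.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

## Chi-squared statistic from expected counts.
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  list(stat = sum((tab - e)^2 / e),
       df = (nrow(tab) - 1) * (ncol(tab) - 1))
}

## Frangi vesselness evaluated from closed-form Hessian eigenvalues of a
## Gaussian-profile structure observed at scale sigma (image profile sd w):
## the smoothed profile has sd^2 = sigma^2 + w^2 and the sigma^2-normalised
## eigenvalues below. `kind` selects tube / blob / plate; amplitude A > 0
## corresponds to the *negated* (bright) structure.
oracle_vesselness_center <- function(kind, A, w, sigma, alpha = 0.5,
                                     beta = 0.5, cc = 0.5) {
  s2 <- sigma^2 + w^2
  peak <- A * switch(kind,
                     tube = w^2 / s2,          # 2-D Gaussian cross-section
                     blob = (w^2 / s2)^(3 / 2),
                     plate = sqrt(w^2 / s2))
  lam <- -sigma^2 * peak / s2
  ev <- switch(kind,
               tube = c(0, lam, lam),
               blob = c(lam, lam, lam),
               plate = c(0, 0, lam))
  ev <- ev[order(abs(ev))]
  l1 <- ev[1]; l2 <- ev[2]; l3 <- ev[3]
  if (l2 > 0 || l3 > 0) return(0)
  ra2 <- if (l3 == 0) 0 else (l2 / l3)^2
  rb2 <- if (l2 * l3 == 0) 0 else l1^2 / abs(l2 * l3)
  S2 <- sum(ev^2)
  (1 - exp(-ra2 / (2 * alpha^2))) * exp(-rb2 / (2 * beta^2)) *
    (1 - exp(-S2 / (2 * cc^2)))
}

## Mean of a Rician variable at high SNR (asymptotic expansion; relative
## error O((sigma/nu)^4)).
oracle_rician_mean <- function(nu, sigma) {
  nu + sigma^2 / (2 * nu)
}
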