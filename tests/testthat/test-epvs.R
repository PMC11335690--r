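test_that("white-matter normalisation rescales by the WM statistic", {
  d <- c(8, 8, 8)
  wm <- array(FALSE, d); wm[2:6, 2:6, 2:6] <- TRUE
  v <- glym_volume(array(1, d) + wm * 1)       # WM voxels are 2, rest 1
  out <- normalize_intensity(v, wm)
  expect_equal(median(out$data[wm]), 1, tolerance = 1e-12)
  expect_equal(out$data[1, 1, 1], 0.5)

  one <- glym_volume(array(1, d))
  expect_equal(normalize_intensity(one, wm)$data, one$data)
  expect_error(normalize_intensity(v, array(FALSE, d)), "empty")
  expect_error(normalize_intensity(glym_volume(array(0, d)), wm), "positive")
})

test_that("EPC is the guarded T1w/T2w ratio with PVS darker than WM", {
  d <- c(4, 4, 4)
  t1 <- glym_volume(array(1, d)); t2 <- glym_volume(array(1, d))
  expect_equal(compute_epc(t1, t2)$data, array(1, d))

  t1$data[1] <- 0.2; t2$data[1] <- 2.0         # PVS-like voxel
  epc <- compute_epc(t1, t2)
  expect_equal(epc$data[1], 0.1)
  expect_lt(epc$data[1], epc$data[2])

  t2$data[2] <- 0                              # guarded division
  expect_true(all(is.finite(compute_epc(t1, t2)$data)))

  t2b <- glym_volume(array(1, c(5, 4, 4)))
  expect_error(compute_epc(t1, t2b), "grid")
})

test_that("segmentation keeps only clusters at the minimum size", {
  d <- c(16, 16, 16)
  vess <- array(0, d)
  vess[2:9, 2, 2] <- 1                         # 8-voxel line
  vess[2:10, 5, 5] <- 1                        # 9-voxel line
  v <- glym_volume(vess, spacing = rep(0.7, 3))
  region <- array(TRUE, d)
  seg <- segment_epvs(v, region, segmentation_params(h = 0.5,
                                                     min_cluster_voxels = 9,
                                                     boundary_erosion = 0))
  expect_equal(seg$n_clusters, 1)
  expect_equal(sum(seg$mask), 9)
  expect_true(all(which(seg$mask) %in% which(vess > 0)))

  ## nothing above threshold
  seg0 <- segment_epvs(v, region, segmentation_params(h = 2,
                                                      boundary_erosion = 0))
  expect_equal(seg0$n_clusters, 0)
  expect_false(any(seg0$mask))

  expect_error(segment_epvs(v, array(FALSE, d), segmentation_params()),
               "empty")
})

test_that("segmentation equals the flood-fill oracle on random maps", {
  set.seed(71)
  for (i in 1:12) {
    vess <- array(stats::rbinom(20^3, 1, 0.12) * runif(20^3, 0.5, 1), c(20, 20, 20))
    v <- glym_volume(vess, spacing = rep(0.7, 3))
    region <- array(TRUE, c(20, 20, 20))
    conn <- sample(c(6, 18, 26), 1)
    min_sz <- sample(c(1, 5, 9), 1)
    seg <- segment_epvs(v, region,
                        segmentation_params(h = 0.5, min_cluster_voxels = min_sz,
                                            connectivity = conn,
                                            boundary_erosion = 0))
    orc <- oracle_segment(vess, region, 0.5, min_sz, conn)
    expect_identical(seg$mask, orc)
  }
})

test_that("segmentation is invariant to joint rescaling of map and threshold", {
  set.seed(13)
  vess <- array(runif(16^3), c(16, 16, 16))
  region <- array(TRUE, c(16, 16, 16))
  v1 <- glym_volume(vess, spacing = rep(0.7, 3))
  v2 <- glym_volume(vess * 1e-4, spacing = rep(0.7, 3))
  s1 <- segment_epvs(v1, region, segmentation_params(h = 0.6, boundary_erosion = 0))
  s2 <- segment_epvs(v2, region, segmentation_params(h = 0.6e-4, boundary_erosion = 0))
  expect_identical(s1$mask, s2$mask)
})

test_that("burden equals the counting oracle and respects bounds", {
  d <- c(10, 10, 10)
  region <- array(TRUE, d)
  mask <- array(FALSE, d); mask[1:5] <- TRUE
  expect_equal(compute_burden(mask, region), 0.5)
  expect_equal(compute_burden(region, region), 100)
  expect_error(compute_burden(mask, array(FALSE, d)), "empty")

  set.seed(8)
  for (i in 1:50) {
    m <- array(rbinom(prod(d), 1, runif(1, 0.05, 0.6)) > 0, d)
    r <- array(rbinom(prod(d), 1, 0.7) > 0, d)
    if (!any(r)) next
    b <- compute_burden(m, r)
    expect_equal(b, 100 * sum(m & r) / sum(r))
    expect_gte(b, 0); expect_lte(b, 100)
  }
})

test_that("noise-free tube-free phantom yields zero burden end to end", {
  spec <- structural_phantom_spec(shape = c(48, 48, 48),
                                  pvs_count = c(WM = 0, BG = 0),
                                  noise_sigma = c(t1w = 0, t2w = 0))
  ph <- make_structural_phantom(spec)
  res <- run_epvs(ph$t1w, ph$t2w, ph$labels)
  expect_equal(res$regions$WM$burden_pct, 0)
  expect_equal(res$regions$BG$burden_pct, 0)
})

test_that("label_components matches the oracle across connectivities", {
  set.seed(5)
  m <- array(rbinom(14^3, 1, 0.2) > 0, c(14, 14, 14))
  for (conn in c(6, 18, 26)) {
    lab <- label_components(m, conn)
    orc <- oracle_components(m, conn)
    ## same partition: cross-table is a permutation matrix
    expect_equal(max(lab), max(orc))
    tab <- table(lab[m], orc[m])
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})
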