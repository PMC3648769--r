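# Smoothing, voxelwise regression, cluster extraction, sphere ROI, overlap.

test_that("gaussian smoothing: identity, DC preservation, Gaussian shape", {
  set.seed(21)
  arr <- array(runif(6^3), c(6, 6, 6))
  expect_identical(gaussian_smooth(arr, 0, spacings = 2), arr)
  expect_error(gaussian_smooth(arr, -1, spacings = 2), ">= 0")
  # constants pass through unchanged, including at the boundary
  const <- array(3.7, c(6, 6, 6))
  expect_equal(gaussian_smooth(const, 8, spacings = 2), const, tolerance = 1e-12)
  # delta impulse far from the boundary: mass conserved, and the response
  # falls off as exp(-d^2 / (2 sigma_vox^2)) along each axis.  "Far" means
  # beyond twice the truncated kernel half-width, so every row the impulse
  # touches carries the full (untruncated) normalization.
  n <- 31L; c0 <- 16L
  imp <- array(0, c(n, n, n)); imp[c0, c0, c0] <- 1
  sm <- gaussian_smooth(imp, fwhm_mm = 4, spacings = 1)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  sig <- 4 / (2 * sqrt(2 * log(2)))
  for (dx in 1:3)
    expect_equal(sm[c0 + dx, c0, c0] / sm[c0, c0, c0],
                 exp(-dx^2 / (2 * sig^2)), tolerance = 1e-9)
  # separability: off-axis value is the product of axis profiles
  expect_equal(sm[c0 + 1, c0 + 2, c0] / sm[c0, c0, c0],
               exp(-(1 + 4) / (2 * sig^2)), tolerance = 1e-9)
  # anisotropic voxels: per-axis sigma in voxel units
  sm2 <- gaussian_smooth(imp, fwhm_mm = 4, spacings = c(1, 2, 1))
  expect_equal(sm2[c0, c0 + 1, c0] / sm2[c0, c0, c0],
               exp(-2^2 / (2 * sig^2)), tolerance = 1e-9)
})

test_that("voxelwise T equals the per-voxel least-squares oracle", {
  set.seed(31)
  g <- grid_iso(c(4, 4, 4), 2)
  n <- 15
  Y <- matrix(rnorm(n * 64), n, 64)
  x <- rnorm(n)
  imgs <- gm_image_set(Y, g)
  st <- voxelwise_slope_t(imgs, x)
  expect_equal(as.vector(st$t_values), oracle_t_map(Y, x), tolerance = 1e-10)
  expect_equal(st$df, n - 2L)
  expect_equal(as.vector(st$p_values),
               pt(oracle_t_map(Y, x), n - 2, lower.tail = FALSE),
               tolerance = 1e-10)
  # duplicating every (image, score) pair: df doubles, T per the oracle
  Y2 <- rbind(Y, Y); x2 <- c(x, x)
  st2 <- voxelwise_slope_t(gm_image_set(Y2, g), x2)
  expect_equal(st2$df, 2 * n - 2L)
  expect_equal(as.vector(st2$t_values), oracle_t_map(Y2, x2), tolerance = 1e-8)
  expect_error(voxelwise_slope_t(imgs, rep(1, n)), "constant")
  expect_error(voxelwise_slope_t(imgs, x[-1]), "length")
})

test_that("the Pearson identity holds: r = 0.5, n = 101 gives T ~ 5.745", {
  set.seed(32)
  n <- 101
  x <- rnorm(n)
  e <- rnorm(n)
  e <- residuals(lm(e ~ x))                      # exactly orthogonal noise
  zx <- as.vector(scale(x)); ze <- as.vector(scale(e))
  r <- 0.5
  y <- r * zx + sqrt(1 - r^2) * ze               # sample correlation exactly 0.5
  g <- grid_iso(c(1, 1, 1), 2)
  st <- voxelwise_slope_t(gm_image_set(matrix(y, ncol = 1), g), x)
  expect_equal(drop(st$t_values), r * sqrt((n - 2) / (1 - r^2)),
               tolerance = 1e-10)
  expect_equal(drop(st$t_values), 5.745, tolerance = 1e-3)
  # orthogonal construction: T exactly 0
  st0 <- voxelwise_slope_t(gm_image_set(matrix(ze, ncol = 1), g), x)
  expect_equal(drop(st0$t_values), 0, tolerance = 1e-10)
})

test_that("constant-intensity voxels are flagged T = 0, p = 1", {
  g <- grid_iso(c(2, 1, 1), 2)
  Y <- cbind(rep(2.5, 10), rnorm(10))
  st <- voxelwise_slope_t(gm_image_set(Y, g), rnorm(10))
  expect_equal(st$t_values[1, 1, 1], 0)
  expect_equal(st$p_values[1, 1, 1], 1)
  expect_equal(st$n_constant, 1L)
})

test_that("extent rule is strict: 150 rejected, 151 retained", {
  g <- grid_iso(c(10, 10, 10), 2)
  t_arr <- array(0, c(10, 10, 10))
  t_arr[2:6, 2:6, 2:7] <- 8                      # 5 x 5 x 6 = 150 voxels
  st <- make_stat_map(t_arr, df = 99, g)
  cfg <- cluster_config(p_voxel = 0.001, k_min = 150)
  expect_length(suprathreshold_clusters(st, cfg)$clusters, 0)
  t_arr[7, 6, 7] <- 8                            # 151st, face-adjacent
  st <- make_stat_map(t_arr, df = 99, g)
  cl <- suprathreshold_clusters(st, cfg)
  expect_length(cl$clusters, 1)
  expect_equal(cl$clusters[[1]]$size_voxels, 151)
  expect_equal(cl$clusters[[1]]$size_mm3, 151 * 8)
})

test_that("corner-touching blobs split by connectivity as expected", {
  g <- grid_iso(c(6, 6, 6), 2)
  t_arr <- array(0, c(6, 6, 6))
  t_arr[1:2, 1:2, 1:2] <- 5
  t_arr[3:4, 3:4, 3:4] <- 5                      # touches only at a corner
  st <- make_stat_map(t_arr, df = 20, g)
  n_at <- function(conn) length(suprathreshold_clusters(
    st, cluster_config(k_min = 0, connectivity = conn))$clusters)
  expect_equal(n_at(6), 2)
  expect_equal(n_at(18), 2)
  expect_equal(n_at(26), 1)
})

test_that("component labeling agrees with the propagation oracle", {
  set.seed(41)
  for (conn in c(6, 18, 26)) {
    for (rep in 1:3) {
      bin <- array(runif(8^3) < 0.35, c(8, 8, 8))
      got <- alemorph:::.label_components(bin, conn)
      want <- oracle_label(bin, conn)
      expect_equal(label_partition(got), label_partition(want))
    }
  }
})

test_that("cluster peaks: bump centers, separation, deterministic ties", {
  g <- grid_iso(c(16, 8, 8), 2)
  cen <- alemorph:::.grid_centers(g)
  c1 <- c(5, 7, 7); c2 <- c(25, 7, 7)            # 20 mm apart
  tv <- 6 * exp(-rowSums(sweep(cen, 2, c1)^2) / 50) +
        5 * exp(-rowSums(sweep(cen, 2, c2)^2) / 50) + 1
  st <- make_stat_map(array(tv, c(16, 8, 8)), df = 50, g)
  cl <- suprathreshold_clusters(st, cluster_config(p_voxel = 0.15, k_min = 0))
  expect_length(cl$clusters, 1)                  # one connected cluster
  pk <- cluster_peaks(st, cl$clusters[[1]], min_separation_mm = 8,
                      labels = cl$labels)
  expect_gte(nrow(pk), 2)
  expect_lte(sqrt(sum((unlist(pk[1, c("x_mm", "y_mm", "z_mm")]) - c1)^2)), 2 * sqrt(3))
  expect_lte(sqrt(sum((unlist(pk[2, c("x_mm", "y_mm", "z_mm")]) - c2)^2)), 2 * sqrt(3))
  # mutual separation respected
  expect_gte(sqrt(sum((unlist(pk[1, c("x_mm", "y_mm", "z_mm")]) -
                         unlist(pk[2, c("x_mm", "y_mm", "z_mm")]))^2)), 8)
  # plateau: single peak at the lexicographically smallest voxel
  t2 <- array(0, c(16, 8, 8)); t2[4:6, 4:6, 4:6] <- 7
  st2 <- make_stat_map(t2, df = 50, g)
  cl2 <- suprathreshold_clusters(st2, cluster_config(k_min = 0))
  pk2 <- cluster_peaks(st2, cl2, min_separation_mm = 8)
  expect_equal(unlist(pk2[1, c("vx", "vy", "vz")], use.names = FALSE),
               c(3, 3, 3))
  # single-voxel cluster: the peak is itself
  t3 <- array(0, c(16, 8, 8)); t3[2, 2, 2] <- 9
  st3 <- make_stat_map(t3, df = 50, g)
  cl3 <- suprathreshold_clusters(st3, cluster_config(k_min = 0))
  pk3 <- cluster_peaks(st3, cl3)
  expect_equal(nrow(pk3), 1)
  expect_equal(unlist(pk3[1, c("vx", "vy", "vz")], use.names = FALSE),
               c(1, 1, 1))
})

test_that("sphere ROI matches the center-distance scan; radius is monotone", {
  g <- grid_iso(c(10, 10, 10), 2)
  ctr <- c(9, 9, 9)
  roi <- sphere_roi(ctr, 10, g)
  cen <- alemorph:::.grid_centers(g)
  want <- rowSums(sweep(cen, 2, ctr)^2) <= 100
  expect_equal(as.vector(roi$values), want)
  counts <- vapply(c(1, 3, 5, 8, 12), function(r)
    sum(suppressWarnings(sphere_roi(ctr, r, g))$values), 1L)
  expect_true(all(diff(counts) >= 0))
  # radius below half a voxel centered on a voxel center: exactly 1 voxel
  expect_equal(sum(sphere_roi(c(8, 8, 8), 0.9, g)$values), 1)
  expect_warning(sphere_roi(c(500, 0, 0), 5, g), "outside")
  expect_error(sphere_roi(c(0, 0, 0), 0, g), "> 0")
})

test_that("overlap report: disjoint, nested, and random cases", {
  g <- grid_iso(c(6, 6, 6), 2)
  a <- sphere_roi(c(2, 2, 2), 3, g)
  b <- sphere_roi(c(9, 9, 9), 3, g)
  expect_equal(overlap_report(a, b)$overlap_voxels, 0)
  inner <- sphere_roi(c(5, 5, 5), 3, g)
  outer <- sphere_roi(c(5, 5, 5), 7, g)
  rep1 <- overlap_report(inner, outer)
  expect_equal(rep1$overlap_voxels, sum(inner$values))
  expect_equal(rep1$fraction_a, 1)
  set.seed(51)
  ra <- volume(array(runif(216) < 0.4, c(6, 6, 6)), g)
  rb <- volume(array(runif(216) < 0.4, c(6, 6, 6)), g)
  want <- 0
  for (i in 1:216) want <- want + (ra$values[i] && rb$values[i])
  rep2 <- overlap_report(ra, rb)
  expect_equal(rep2$overlap_voxels, want)
  expect_equal(rep2$overlap_mm3, want * 8)
  g2 <- grid_iso(c(6, 6, 6), 3)
  expect_error(overlap_report(ra, volume(rb$values, g2)), "different grids")
})

test_that("null covariate: voxelwise p < 0.001 rate is calibrated (reduced)", {
  set.seed(61)
  g <- grid_iso(c(10, 10, 10), 2)
  n <- 31; reps <- 25
  hits <- 0; total <- 0
  for (r in seq_len(reps)) {
    Y <- matrix(rnorm(n * 1000), n, 1000)
    st <- voxelwise_slope_t(gm_image_set(Y, g), rnorm(n))
    hits <- hits + sum(st$p_values < 0.001)
    total <- total + 1000
  }
  rate <- hits / total
  se <- sqrt(0.001 * 0.999 / total)
  expect_lt(abs(rate - 0.001), 3 * se)
})
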