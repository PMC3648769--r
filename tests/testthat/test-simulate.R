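# Synthetic-data generators: masks, foci, cohorts, gray-matter image sets.

test_that("toy mask rasterization matches the center-inclusion scan", {
  g <- grid_iso(c(10, 10, 10), 2)
  m <- make_toy_mask(g, c(9, 9, 9), c(7, 5, 4))
  cen <- alemorph:::.grid_centers(g)
  want <- ((cen[, 1] - 9) / 7)^2 + ((cen[, 2] - 9) / 5)^2 +
    ((cen[, 3] - 9) / 4)^2 <= 1
  expect_equal(as.vector(m$values), want)
  # semi-axes below half a voxel centered on a voxel center: one voxel
  m1 <- make_toy_mask(g, c(8, 8, 8), c(0.9, 0.9, 0.9))
  expect_equal(sum(m1$values), 1)
  expect_error(make_toy_mask(g, c(200, 0, 0), c(3, 3, 3)), "outside the grid")
  expect_error(make_toy_mask(g, c(9, 9, 9), c(0, 5, 4)), "> 0")
})

test_that("bilateral masks form two components when separated", {
  g <- grid_iso(c(20, 10, 10), 2, origin_mm = c(-19, 0, 0))
  m <- make_toy_mask(g, c(10, 9, 9), c(5, 4, 4), bilateral = TRUE)
  lab <- oracle_label(m$values, 26)
  expect_equal(max(lab), 2)
})

test_that("foci simulation: degenerate spread, determinism, TAL round trip", {
  m <- toy_mask_fixture()
  ctr <- colMeans(alemorph:::.mask_centers(m))
  cfg0 <- foci_sim_config(n_studies = 5, centers_mm = matrix(ctr, 1),
                          sigma_mm = 1e-12, bg_fraction = 0, tal_fraction = 0,
                          seed = 3)
  f0 <- simulate_foci(cfg0, m)
  expect_lt(max(abs(as.matrix(f0[, c("x_mm", "y_mm", "z_mm")]) -
                      matrix(ctr, nrow(f0), 3, byrow = TRUE))), 1e-6)
  # identical seed, identical table
  expect_identical(simulate_foci(cfg0, m), f0)
  # all-TAL table: harmonization recovers the stored MNI ground truth
  cfg1 <- foci_sim_config(n_studies = 8, centers_mm = matrix(ctr, 1),
                          sigma_mm = 4, tal_fraction = 1, seed = 9)
  f1 <- simulate_foci(cfg1, m)
  expect_true(all(f1$space == "TAL"))
  h <- harmonize_space(f1)
  expect_lt(max(abs(as.matrix(h[, c("x_mm", "y_mm", "z_mm")]) -
                      attr(f1, "mni_truth"))), 1e-6)
  # generated tables pass the consumer validators
  expect_s3_class(foci_table(as.data.frame(f1)), "foci_table")
})

test_that("pure-background foci are uniform over mask voxels (GOF)", {
  g <- grid_iso(c(8, 8, 8), 2)
  m <- make_toy_mask(g, c(7, 7, 7), c(6, 5, 5))
  nvox <- sum(m$values)
  cfg <- foci_sim_config(n_studies = 1200, lambda = 7,
                         centers_mm = matrix(c(7, 7, 7), 1),
                         bg_fraction = 1, tal_fraction = 0, seed = 11)
  f <- simulate_foci(cfg, m)
  expect_gt(nrow(f), 8000)
  idx <- world_to_voxel(as.matrix(f[, c("x_mm", "y_mm", "z_mm")]), g)
  lin <- idx[, 1] + 1 + idx[, 2] * 8 + idx[, 3] * 64
  counts <- tabulate(match(lin, which(m$values)), nbins = nvox)
  gof <- suppressWarnings(chisq.test(counts))
  expect_gt(gof$p.value, 0.01)
})

test_that("cohort simulation reproduces drawn totals exactly", {
  key <- escale_key()
  co <- simulate_cohort(cohort_sim_config(n_subjects = 30, seed = 12), key)
  rescored <- apply(co[, sprintf("item%02d", 1:25)], 1, score_escale, key = key)
  expect_equal(unname(rescored), co$total_score)
  expect_true(all(co$total_score >= 25 & co$total_score <= 175))
  # SD -> 0: everyone at the mean with valid responses
  co0 <- simulate_cohort(cohort_sim_config(n_subjects = 5, mean_total = 100,
                                           sd_total = 0, seed = 1), key)
  expect_true(all(co0$total_score == 100))
  expect_true(all(as.matrix(co0[, sprintf("item%02d", 1:25)]) %in% 1:7))
  # determinism
  expect_identical(simulate_cohort(cohort_sim_config(n_subjects = 30, seed = 12),
                                   key), co)
})

test_that("large-cohort mean approaches the target (Monte Carlo)", {
  co <- simulate_cohort(cohort_sim_config(n_subjects = 10000, seed = 13))
  se <- 13.3 / sqrt(10000)
  expect_lt(abs(mean(co$total_score) - 91.6), 3 * se + 0.5)  # +0.5 rounding slack
  expect_lt(abs(sd(co$total_score) - 13.3), 0.5)
})

test_that("gm simulation: null construction and exact noise-free recovery", {
  set.seed(14)
  scores <- rnorm(12, 91.6, 13.3)
  # beta = 0: extremely unlikely to produce any k > 150 cluster
  cfg0 <- gm_sim_config(shape = c(12, 12, 12), beta = 0, seed = 2)
  imgs0 <- simulate_gm_dataset(cfg0, scores)
  st0 <- voxelwise_slope_t(imgs0, scores)
  expect_length(suprathreshold_clusters(st0, cluster_config())$clusters, 0)
  # noise-free, unsmoothed: T is +Inf on the bump support, exactly
  cfg1 <- gm_sim_config(shape = c(12, 12, 12), noise_sd = 0,
                        smooth_fwhm_mm = 0, seed = 2)
  imgs1 <- simulate_gm_dataset(cfg1, scores)
  gt <- attr(imgs1, "ground_truth")
  st1 <- voxelwise_slope_t(imgs1, scores)
  support <- gt$bump > 0
  expect_true(all(is.infinite(st1$t_values[support])))
  cl1 <- suprathreshold_clusters(st1, cluster_config(k_min = 0))
  expect_equal(array(cl1$labels > 0, dim(support)), support)
  # determinism
  imgs1b <- simulate_gm_dataset(cfg1, scores)
  expect_identical(imgs1$data, imgs1b$data)
  expect_error(simulate_gm_dataset(gm_sim_config(shape = c(12, 12, 12),
                                                 locus_mm = c(999, 0, 0)),
                                   scores), "empty support")
})

test_that("implanted effect is recovered near the locus (reduced run)", {
  hits <- 0
  for (s in 1:6) {
    co <- simulate_cohort(cohort_sim_config(seed = 100 + s))
    imgs <- simulate_gm_dataset(gm_sim_config(seed = 200 + s), co$total_score)
    gt <- attr(imgs, "ground_truth")
    st <- voxelwise_slope_t(imgs, co$total_score)
    cl <- suprathreshold_clusters(st, cluster_config())
    if (length(cl$clusters)) {
      pv <- cl$clusters[[1]]$peak_voxel
      if (sqrt(sum((pv - gt$locus_voxel)^2)) <= 2) hits <- hits + 1
    }
  }
  expect_gte(hits, 5)
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(77)
  before <- .Random.seed
  invisible(simulate_cohort(cohort_sim_config(n_subjects = 5, seed = 1)))
  m <- toy_mask_fixture()
  invisible(simulate_foci(foci_sim_config(n_studies = 2,
                                          centers_mm = matrix(c(11, 11, 11), 1),
                                          seed = 4), m))
  expect_identical(.Random.seed, before)
})
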