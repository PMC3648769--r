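# Seeded synthetic-data generators: toy masks, foci tables with latent
# activation centers, questionnaire cohorts with a target total-score
# distribution, and gray-matter image sets with an implanted linear
# covariate effect.  All generators are bit-reproducible under a fixed seed
# and leave the caller's RNG state untouched.

#' Rasterize a toy (optionally bilateral) ellipsoid mask
#'
#' Stand-in for an anatomical region mask: voxel centers inside one
#' ellipsoid, or two mirrored across the world x = 0 plane.
#'
#' @param grid A [volume_grid()].
#' @param center_mm Ellipsoid center (world mm).
#' @param semi_axes_mm Positive semi-axis lengths (length 3).
#' @param bilateral If TRUE, add the ellipsoid mirrored in x.
#' @return A [mask_volume()].
#' @export
make_toy_mask <- function(grid, center_mm, semi_axes_mm, bilateral = FALSE) {
  stopifnot(inherits(grid, "volume_grid"))
  semi_axes_mm <- rep_len(as.numeric(semi_axes_mm), 3L)
  if (any(semi_axes_mm <= 0)) stop("make_toy_mask: semi-axes must be > 0")
  ctr <- drop(.as_xyz_matrix(center_mm))
  cen <- .grid_centers(grid)
  inside <- function(ct) {
    rowSums(sweep(sweep(cen, 2, ct, `-`), 2, semi_axes_mm, `/`)^2) <= 1
  }
  vox <- inside(ctr)
  if (bilateral) vox <- vox | inside(ctr * c(-1, 1, 1))
  if (!any(vox))
    stop("make_toy_mask: ellipsoid lies outside the grid (empty mask)")
  mask_volume(array(vox, dim = grid$shape), grid)
}

#' Configuration for foci simulation
#'
#' Emulates a literature coordinate table: per study, a Poisson(lambda) + 1
#' focus count; each focus is drawn from a mixture of Gaussian clusters
#' around latent centers (spread `sigma_mm`) and a uniform background over
#' mask voxel centers.  A configurable fraction of rows is stored in
#' Talairach coordinates (forward-converted with [mni2tal()] so the
#' pipeline's [tal2mni()] recovers the MNI ground truth).
#'
#' @param n_studies Number of studies (default 16, a typical category size).
#' @param category Category label for all rows.
#' @param lambda Poisson mean of extra foci per study (default 2; plus 1
#'   guarantees each study reports at least one peak, matching ~3 per study).
#' @param centers_mm Matrix (k x 3) of latent activation centers.
#' @param sigma_mm Isotropic spread around centers (default 4).
#' @param bg_fraction Probability a focus is uniform background (default 0.1).
#' @param tal_fraction Fraction of rows labeled TAL (default 0.3).
#' @param n_subjects_range Inclusive range for per-study subject counts
#'   (default c(10, 30)).
#' @param seed Integer seed.
#' @return A `foci_sim_config`.
#' @export
foci_sim_config <- function(n_studies = 16, category = "empathy_for_pain",
                            lambda = 2, centers_mm, sigma_mm = 4,
                            bg_fraction = 0.1, tal_fraction = 0.3,
                            n_subjects_range = c(10, 30), seed = 1L) {
  if (n_studies < 1) stop("foci_sim_config: need at least one study")
  if (bg_fraction < 0 || bg_fraction > 1 || tal_fraction < 0 || tal_fraction > 1)
    stop("foci_sim_config: fractions must lie in [0, 1]")
  if (sigma_mm < 0) stop("foci_sim_config: sigma_mm must be >= 0")
  centers_mm <- .as_xyz_matrix(centers_mm)
  structure(list(n_studies = as.integer(n_studies), category = category,
                 lambda = lambda, centers_mm = centers_mm, sigma_mm = sigma_mm,
                 bg_fraction = bg_fraction, tal_fraction = tal_fraction,
                 n_subjects_range = as.integer(n_subjects_range),
                 seed = as.integer(seed)),
            class = "foci_sim_config")
}

#' Simulate a foci table
#'
#' @param cfg A [foci_sim_config()].
#' @param mask A [mask_volume()] supplying the background support.
#' @return A `foci_table` with attribute `mni_truth` (n x 3 matrix of the
#'   pre-conversion MNI ground-truth coordinates, for round-trip checks).
#' @export
simulate_foci <- function(cfg, mask) {
  stopifnot(inherits(cfg, "foci_sim_config"), inherits(mask, "mask_volume"))
  centers <- .mask_centers(mask)
  .with_seed(cfg$seed, {
    rows <- list()
    for (s in seq_len(cfg$n_studies)) {
      n_f <- stats::rpois(1, cfg$lambda) + 1L
      from_bg <- stats::runif(n_f) < cfg$bg_fraction
      xyz <- matrix(0, n_f, 3)
      if (any(from_bg)) {
        pick <- sample.int(nrow(centers), sum(from_bg), replace = TRUE)
        xyz[from_bg, ] <- centers[pick, , drop = FALSE]
      }
      if (any(!from_bg)) {
        k <- sample.int(nrow(cfg$centers_mm), sum(!from_bg), replace = TRUE)
        xyz[!from_bg, ] <- cfg$centers_mm[k, , drop = FALSE] +
          matrix(stats::rnorm(3 * sum(!from_bg), 0, cfg$sigma_mm),
                 ncol = 3)
      }
      rows[[s]] <- data.frame(
        study_id = sprintf("sim%03d", s),
        category = cfg$category,
        modality = sample(c("fMRI", "PET"), 1, prob = c(0.8, 0.2)),
        space = "MNI",
        x_mm = xyz[, 1], y_mm = xyz[, 2], z_mm = xyz[, 3],
        n_subjects = sample(seq(cfg$n_subjects_range[1],
                                cfg$n_subjects_range[2]), 1),
        stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    truth <- as.matrix(df[, c("x_mm", "y_mm", "z_mm")])
    n <- nrow(df)
    as_tal <- stats::runif(n) < cfg$tal_fraction
    if (any(as_tal)) {
      tal <- mni2tal(truth[as_tal, , drop = FALSE])
      df$x_mm[as_tal] <- tal[, 1]
      df$y_mm[as_tal] <- tal[, 2]
      df$z_mm[as_tal] <- tal[, 3]
      df$space[as_tal] <- "TAL"
    }
    out <- foci_table(df)
    attr(out, "mni_truth") <- unname(truth)
    out
  })
}

#' Configuration for cohort simulation
#'
#' @param n_subjects Cohort size (default 101).
#' @param mean_total Target total-score mean (default 91.6).
#' @param sd_total Target total-score SD (default 13.3); draws are truncated
#'   to the attainable range 25-175.
#' @param seed Integer seed.
#' @return A `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_subjects = 101, mean_total = 91.6,
                              sd_total = 13.3, seed = 1L) {
  if (mean_total < 25 || mean_total > 175)
    stop("cohort_sim_config: mean_total must lie in [25, 175]")
  if (sd_total < 0) stop("cohort_sim_config: sd_total must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects), mean_total = mean_total,
                 sd_total = sd_total, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

# deterministic decomposition of an integer total into 25 item contributions
# in 1..7; responses follow the key's polarity (negative: r = 8 - c)
.decompose_total <- function(total, key) {
  contrib <- rep(1L, 25L)
  extra <- as.integer(total) - 25L
  full <- extra %/% 6L
  rem <- extra %% 6L
  if (full > 0L) contrib[seq_len(full)] <- 7L
  if (rem > 0L) contrib[full + 1L] <- 1L + rem
  r <- contrib
  neg <- key$polarity == "negative"
  r[neg] <- 8L - contrib[neg]
  r
}

#' Simulate a questionnaire cohort
#'
#' Latent totals are drawn from a Normal(mean, SD) truncated to 25-175 and
#' rounded to integers; each total is then decomposed into 25 valid item
#' responses consistent with the key, so that [score_escale()] reproduces
#' the drawn total exactly.
#'
#' @param cfg A [cohort_sim_config()].
#' @param key An [escale_key()].
#' @return Data frame `subject_id, item01..item25, total_score`.
#' @export
simulate_cohort <- function(cfg, key = escale_key()) {
  stopifnot(inherits(cfg, "cohort_sim_config"), inherits(key, "escale_key"))
  totals <- .with_seed(cfg$seed, {
    n <- cfg$n_subjects
    draw <- numeric(0)
    while (length(draw) < n) {
      x <- stats::rnorm(2L * (n - length(draw)), cfg$mean_total, cfg$sd_total)
      draw <- c(draw, x[x >= 25 & x <= 175])
    }
    as.integer(round(draw[seq_len(n)]))
  })
  resp <- t(vapply(totals, .decompose_total, integer(25), key = key))
  colnames(resp) <- sprintf("item%02d", 1:25)
  out <- data.frame(subject_id = sprintf("subj%03d", seq_along(totals)),
                    resp, total_score = totals, stringsAsFactors = FALSE)
  out
}

#' Configuration for gray-matter image simulation
#'
#' The defaults were fixed a priori from a power analysis (see the methods
#' vignette): on a 24^3 grid of 2-mm voxels, a parabolic spherical bump of
#' radius 10 mm at the grid center, slope 3e-3 intensity units per score
#' unit, noise SD 0.05, and 6-mm FWHM post-effect smoothing give an expected
#' center T around 8 for a cohort of 101 with score SD 13.3.
#'
#' @param shape Grid shape (default c(24, 24, 24)).
#' @param voxel_mm Isotropic voxel size (default 2).
#' @param baseline Constant baseline intensity (default 0.5, a typical
#'   gray-matter density).
#' @param locus_mm Effect center in world mm (default: grid center).
#' @param radius_mm Bump radius (default 10).
#' @param beta Slope, intensity units per covariate unit (default 3e-3).
#' @param noise_sd Gaussian noise SD (default 0.05).
#' @param smooth_fwhm_mm Post-effect smoothing FWHM (default 6).
#' @param seed Integer seed.
#' @return A `gm_sim_config`.
#' @export
gm_sim_config <- function(shape = c(24, 24, 24), voxel_mm = 2, baseline = 0.5,
                          locus_mm = NULL, radius_mm = 10, beta = 3e-3,
                          noise_sd = 0.05, smooth_fwhm_mm = 6, seed = 1L) {
  if (radius_mm <= 0) stop("gm_sim_config: radius_mm must be > 0")
  if (noise_sd < 0) stop("gm_sim_config: noise_sd must be >= 0")
  shape <- as.integer(shape)
  if (is.null(locus_mm)) locus_mm <- (shape - 1) / 2 * voxel_mm
  structure(list(shape = shape, voxel_mm = voxel_mm, baseline = baseline,
                 locus_mm = as.numeric(locus_mm), radius_mm = radius_mm,
                 beta = beta, noise_sd = noise_sd,
                 smooth_fwhm_mm = smooth_fwhm_mm, seed = as.integer(seed)),
            class = "gm_sim_config")
}

#' Simulate a gray-matter image set with an implanted covariate effect
#'
#' image_i = baseline + beta * (score_i - mean(score)) * bump + noise, then
#' smoothed; the bump is the parabolic profile max(0, 1 - (d/r)^2) around the
#' locus, so the true effect peaks at the locus.
#'
#' @param cfg A [gm_sim_config()].
#' @param scores Numeric covariate vector, one per subject (>= 3 subjects).
#' @return A [gm_image_set()] with attribute `ground_truth`: list with
#'   `locus_mm`, `locus_voxel` (0-based), `radius_mm`, `beta`, `bump`
#'   (the 3-D profile), and the `grid`.
#' @export
simulate_gm_dataset <- function(cfg, scores) {
  stopifnot(inherits(cfg, "gm_sim_config"))
  n <- length(scores)
  if (n < 3L) stop("simulate_gm_dataset: need at least 3 subjects")
  grid <- grid_iso(cfg$shape, cfg$voxel_mm)
  cen <- .grid_centers(grid)
  d2 <- (cen[, 1] - cfg$locus_mm[1])^2 + (cen[, 2] - cfg$locus_mm[2])^2 +
    (cen[, 3] - cfg$locus_mm[3])^2
  bump <- pmax(0, 1 - d2 / cfg$radius_mm^2)
  if (!any(bump > 0))
    stop("simulate_gm_dataset: grid too small for the bump (empty support)")
  nv <- prod(cfg$shape)
  xc <- scores - mean(scores)
  data <- .with_seed(cfg$seed, {
    m <- matrix(stats::rnorm(n * nv, 0, cfg$noise_sd), nrow = n)
    m <- m + cfg$baseline + outer(cfg$beta * xc, bump)
    m
  })
  imgs <- gm_image_set(data, grid)
  if (cfg$smooth_fwhm_mm > 0) imgs <- gaussian_smooth(imgs, cfg$smooth_fwhm_mm)
  lv <- world_to_voxel(cfg$locus_mm, grid)
  attr(imgs, "ground_truth") <- list(locus_mm = cfg$locus_mm,
                                     locus_voxel = drop(lv),
                                     radius_mm = cfg$radius_mm,
                                     beta = cfg$beta,
                                     bump = array(bump, dim = cfg$shape),
                                     grid = grid)
  imgs
}
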