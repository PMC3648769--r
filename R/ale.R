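# ALE core: per-focus Gaussian probabilities, per-study modeled-activation
# maps with unit total kernel weight, and the across-study union map.
#
# Per-study normalization: every focus of a study carries weight
# 1/n_foci(study), so each study contributes total kernel mass 1 and a study
# reporting many peaks cannot dominate the map.  Values combine by the
# probabilistic union 1 - prod(1 - p), first across the foci of a study,
# then across studies.

#' Specify the isotropic ALE kernel
#'
#' @param fwhm_mm Full-width at half-maximum of the 3-D Gaussian, in mm.
#'   The default 10 mm is the classic choice for coordinate-based ALE.
#' @return List with `fwhm_mm` and the derived `sigma_mm` =
#'   fwhm / (2 sqrt(2 ln 2)).
#' @export
kernel_spec <- function(fwhm_mm = 10) {
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || !is.finite(fwhm_mm) ||
      fwhm_mm <= 0)
    stop("kernel_spec: fwhm_mm must be a single positive number")
  structure(list(fwhm_mm = fwhm_mm,
                 sigma_mm = fwhm_mm / (2 * sqrt(2 * log(2)))),
            class = "kernel_spec")
}

#' Probability contributed by one focus at a displacement
#'
#' `min(1, weight * phi(offset; sigma) * voxel_volume)` with `phi` the
#' trivariate isotropic Gaussian density; symmetric in the offset.
#'
#' @param offset_mm Length-3 displacement or n x 3 matrix of displacements.
#' @param kernel A [kernel_spec()].
#' @param voxel_volume Voxel volume in mm^3 (> 0).
#' @param weight Per-focus weight in (0, 1].
#' @return Probability (vector of length n).
#' @export
focus_probability <- function(offset_mm, kernel, voxel_volume, weight = 1) {
  stopifnot(inherits(kernel, "kernel_spec"))
  if (!is.numeric(voxel_volume) || voxel_volume <= 0)
    stop("focus_probability: voxel_volume must be > 0")
  if (any(weight <= 0) || any(weight > 1))
    stop("focus_probability: weight must lie in (0, 1]")
  off <- .as_xyz_matrix(offset_mm)
  s <- kernel$sigma_mm
  dens <- exp(-rowSums(off^2) / (2 * s^2)) / ((2 * pi)^1.5 * s^3)
  pmin(1, weight * dens * voxel_volume)
}

# per-center union value of one study's foci: 1 - prod_f (1 - p_f), with
# p_f = min(1, w * phi * vv).  centers: V x 3; foci: n x 3; weights length n.
.study_union_values <- function(foci_xyz, weights, centers, sigma, voxel_volume) {
  k <- voxel_volume / ((2 * pi)^1.5 * sigma^3)
  log_surv <- numeric(nrow(centers))
  for (i in seq_len(nrow(foci_xyz))) {
    d2 <- (centers[, 1] - foci_xyz[i, 1])^2 +
          (centers[, 2] - foci_xyz[i, 2])^2 +
          (centers[, 3] - foci_xyz[i, 3])^2
    p <- pmin(1, weights[i] * k * exp(-d2 / (2 * sigma^2)))
    log_surv <- log_surv + log1p(-p)
  }
  -expm1(log_surv)
}

#' Per-study modeled-activation map
#'
#' Each focus carries weight 1/n_foci, so the study's summed focus weights
#' equal unity; per-voxel values are the union of its foci's probabilities.
#' Foci outside the grid still contribute through their true offsets (a
#' warning is logged).
#'
#' @param study A `study` from [group_into_studies()].
#' @param grid A [volume_grid()].
#' @param kernel A [kernel_spec()].
#' @return A [volume()] of per-voxel probabilities in \[0, 1).
#' @export
study_ma_map <- function(study, grid, kernel) {
  stopifnot(inherits(study, "study"), inherits(grid, "volume_grid"),
            inherits(kernel, "kernel_spec"))
  if (study$n_foci < 1L) stop("study_ma_map: study has no foci")
  idx <- world_to_voxel(study$foci, grid)
  if (!all(attr(idx, "in_grid")))
    warning(sprintf("study_ma_map: %d focus/foci of study '%s' lie outside the grid",
                    sum(!attr(idx, "in_grid")), study$study_id), call. = FALSE)
  centers <- .grid_centers(grid)
  w <- rep(1 / study$n_foci, study$n_foci)
  vals <- .study_union_values(study$foci, w, centers, kernel$sigma_mm,
                              grid$voxel_volume)
  volume(array(vals, dim = grid$shape), grid)
}

#' Combined ALE map across studies
#'
#' Per-voxel ALE = 1 - prod over studies of (1 - study value): the union of
#' per-study modeled-activation maps.  With a mask, values are computed on
#' (and zero outside) the mask.
#'
#' @param studies Non-empty list of `study` objects.
#' @param grid A [volume_grid()].
#' @param kernel A [kernel_spec()].
#' @param mask Optional [mask_volume()] restricting the evaluation.
#' @return An `ale_map`: a [volume()] with provenance fields `n_studies`,
#'   `n_foci`, `kernel`, and `masked`.
#' @export
ale_map <- function(studies, grid, kernel, mask = NULL) {
  if (!length(studies)) stop("ale_map: need at least one study")
  stopifnot(all(vapply(studies, inherits, TRUE, "study")),
            inherits(grid, "volume_grid"), inherits(kernel, "kernel_spec"))
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "mask_volume"))
    .check_same_grid(mask, list(grid = grid), "mask and grid")
    centers <- .mask_centers(mask)
  } else {
    centers <- .grid_centers(grid)
  }
  log_surv <- numeric(nrow(centers))
  n_foci <- 0L
  for (st in studies) {
    w <- rep(1 / st$n_foci, st$n_foci)
    sv <- .study_union_values(st$foci, w, centers, kernel$sigma_mm,
                              grid$voxel_volume)
    log_surv <- log_surv + log1p(-sv)
    n_foci <- n_foci + st$n_foci
  }
  vals_sel <- -expm1(log_surv)
  arr <- array(0, dim = grid$shape)
  if (!is.null(mask)) arr[mask$values] <- vals_sel else arr[] <- vals_sel
  out <- volume(arr, grid)
  out$n_studies <- length(studies)
  out$n_foci <- n_foci
  out$kernel <- kernel
  out$masked <- !is.null(mask)
  class(out) <- c("ale_map", class(out))
  out
}
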