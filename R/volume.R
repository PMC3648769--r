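# Volume containers: scalar/binary 3-D arrays bound to a volume_grid.

#' Bind a 3-D array to a grid
#'
#' @param values 3-D numeric/logical array whose dimensions match `grid$shape`.
#' @param grid A [volume_grid()].
#' @return A `volume` object.
#' @export
volume <- function(values, grid) {
  stopifnot(inherits(grid, "volume_grid"))
  values <- as.array(values)
  if (length(dim(values)) != 3L || !all(dim(values) == grid$shape))
    stop("volume: values dimensions must equal grid shape")
  structure(list(values = values, grid = grid), class = "volume")
}

#' Construct a binary mask volume
#'
#' Foreground voxels are those with nonzero values; the mask must be non-empty.
#'
#' @param values 3-D array (logical or 0/1) matching `grid$shape`.
#' @param grid A [volume_grid()].
#' @return A `mask_volume` (also a `volume`); values stored as logical.
#' @export
mask_volume <- function(values, grid) {
  v <- volume(array(as.logical(values), dim = grid$shape), grid)
  if (!any(v$values)) stop("mask_volume: mask has no foreground voxels")
  class(v) <- c("mask_volume", class(v))
  v
}

#' @export
print.volume <- function(x, ...) {
  rng <- range(x$values)
  cat(sprintf("<%s> %s; values in [%.4g, %.4g]\n", class(x)[1],
              paste(dim(x$values), collapse = " x "), rng[1], rng[2]))
  invisible(x)
}

.check_same_grid <- function(a, b, what = "volumes") {
  if (!all(a$grid$shape == b$grid$shape) ||
      max(abs(a$grid$affine - b$grid$affine)) > 1e-8)
    stop(what, " are defined on different grids")
  invisible(TRUE)
}

.mask_centers <- function(mask) .grid_centers(mask$grid, select = mask$values)

#' Rasterize a sphere ROI on a grid
#'
#' Voxels whose centers lie within `radius_mm` of `center` are foreground.
#' A sphere wholly outside the grid yields an empty volume with a warning.
#'
#' @param center World-mm center (`point3` or length-3 numeric).
#' @param radius_mm Sphere radius, > 0.
#' @param grid A [volume_grid()].
#' @return A binary `volume` (not a `mask_volume`: it may be empty).
#' @export
sphere_roi <- function(center, radius_mm, grid) {
  if (!is.numeric(radius_mm) || radius_mm <= 0) stop("sphere_roi: radius must be > 0")
  ctr <- drop(.as_xyz_matrix(center))
  cen <- .grid_centers(grid)
  d2 <- (cen[, 1] - ctr[1])^2 + (cen[, 2] - ctr[2])^2 + (cen[, 3] - ctr[3])^2
  inside <- d2 <= radius_mm^2
  if (!any(inside)) warning("sphere_roi: sphere lies wholly outside the grid")
  volume(array(inside, dim = grid$shape), grid)
}

#' Overlap between two binary volumes
#'
#' @param a,b Binary `volume`s on the same grid.
#' @return List with `overlap_voxels`, `overlap_mm3`, sizes `n_a`/`n_b`, and
#'   `fraction_a`/`fraction_b` (overlap as a fraction of each; `NaN` if empty).
#' @export
overlap_report <- function(a, b) {
  stopifnot(inherits(a, "volume"), inherits(b, "volume"))
  .check_same_grid(a, b)
  av <- as.logical(a$values); bv <- as.logical(b$values)
  n_ab <- sum(av & bv); n_a <- sum(av); n_b <- sum(bv)
  list(overlap_voxels = n_ab,
       overlap_mm3 = n_ab * a$grid$voxel_volume,
       n_a = n_a, n_b = n_b,
       fraction_a = n_ab / n_a, fraction_b = n_ab / n_b)
}

# evaluate a function under a private RNG state, restoring the caller's
.with_seed <- function(seed, expr) {
  seed <- as.integer(seed)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
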