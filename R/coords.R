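# Coordinate spaces, piecewise-affine Talairach/MNI conversion, voxel/world maps.

.TAL_THETA <- 0.05  # radians, rotation about x

# Forward (MNI -> TAL) matrices: rotation about x composed with axis scalings.
# Above the AC plane the z scaling is 0.92, below it 0.84.
.tal_matrices <- local({
  ct <- cos(.TAL_THETA); st <- sin(.TAL_THETA)
  rot <- matrix(c(1, 0, 0,
                  0, ct, st,
                  0, -st, ct), 3, 3, byrow = TRUE)
  up <- rot %*% diag(c(0.99, 0.97, 0.92))
  dn <- rot %*% diag(c(0.99, 0.97, 0.84))
  list(up = up, dn = dn, up_inv = solve(up), dn_inv = solve(dn),
       rot = rot)
})

#' Construct a labeled 3-D point
#'
#' A `point3` is a length-3 numeric coordinate in millimetres carrying a
#' coordinate-space label (`"MNI"`, `"TAL"`, or `"world"`).
#'
#' @param x,y,z Coordinates in mm (finite reals).
#' @param space One of `"MNI"`, `"TAL"`, `"world"`.
#' @return A `point3` object.
#' @export
point3 <- function(x, y, z, space = c("MNI", "TAL", "world")) {
  space <- match.arg(space)
  p <- c(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  if (!all(is.finite(p))) stop("point3: coordinates must be finite reals")
  structure(p, space = space, class = "point3")
}

#' @export
print.point3 <- function(x, ...) {
  cat(sprintf("<point3 %s> (%.3f, %.3f, %.3f) mm\n",
              attr(x, "space"), x[1], x[2], x[3]))
  invisible(x)
}

.as_xyz_matrix <- function(p) {
  if (inherits(p, "point3")) p <- matrix(unclass(p), nrow = 1)
  if (is.null(dim(p))) {
    if (length(p) != 3L) stop("expected a length-3 coordinate or an n x 3 matrix")
    p <- matrix(as.numeric(p), nrow = 1)
  }
  p <- as.matrix(p)
  if (ncol(p) != 3L) stop("coordinate matrix must have 3 columns")
  storage.mode(p) <- "double"
  if (!all(is.finite(p))) stop("coordinates must be finite reals")
  p
}

.restore_point <- function(xyz, template, space) {
  if (inherits(template, "point3"))
    return(point3(xyz[1, 1], xyz[1, 2], xyz[1, 3], space = space))
  if (is.null(dim(template))) return(drop(xyz))
  dimnames(xyz) <- dimnames(template)
  xyz
}

#' Convert MNI coordinates to Talairach space
#'
#' Piecewise-affine mapping: a rotation about the x axis by 0.05 rad followed
#' by axis scalings `diag(0.99, 0.97, 0.92)` above the anterior commissure
#' and `diag(0.99, 0.97, 0.84)` below it.  The above/below branch is decided
#' by the sign of the output-side (Talairach) z, which equals the sign of the
#' rotated z; this makes [tal2mni()] an exact inverse everywhere.
#'
#' @param p A `point3` in MNI space, a length-3 numeric, or an n x 3 matrix
#'   of MNI coordinates in mm.
#' @return Talairach coordinates in the same shape as the input.
#' @export
mni2tal <- function(p) {
  if (inherits(p, "point3") && !identical(attr(p, "space"), "MNI"))
    stop("mni2tal: input point is labeled ", attr(p, "space"), ", expected MNI")
  xyz <- .as_xyz_matrix(p)
  ct <- cos(.TAL_THETA); st <- sin(.TAL_THETA)
  below <- (-st * xyz[, 2] + ct * xyz[, 3]) < 0
  out <- xyz
  if (any(!below)) out[!below, ] <- xyz[!below, , drop = FALSE] %*% t(.tal_matrices$up)
  if (any(below))  out[below, ]  <- xyz[below, , drop = FALSE] %*% t(.tal_matrices$dn)
  .restore_point(out, p, "TAL")
}

#' Convert Talairach coordinates to MNI space
#'
#' Exact inverse of [mni2tal()]; the above/below-AC branch is decided by the
#' sign of the input (Talairach) z.
#'
#' @param p A `point3` in TAL space, a length-3 numeric, or an n x 3 matrix.
#' @return MNI coordinates in the same shape as the input.
#' @export
tal2mni <- function(p) {
  if (inherits(p, "point3") && !identical(attr(p, "space"), "TAL"))
    stop("tal2mni: input point is labeled ", attr(p, "space"), ", expected TAL")
  xyz <- .as_xyz_matrix(p)
  below <- xyz[, 3] < 0
  out <- xyz
  if (any(!below)) out[!below, ] <- xyz[!below, , drop = FALSE] %*% t(.tal_matrices$up_inv)
  if (any(below))  out[below, ]  <- xyz[below, , drop = FALSE] %*% t(.tal_matrices$dn_inv)
  .restore_point(out, p, "MNI")
}

#' Define a voxel raster bound to world space
#'
#' A `volume_grid` couples integer voxel counts per axis with a 4 x 4 affine
#' mapping 0-based voxel indices to world mm (RAS orientation by convention).
#'
#' @param shape Integer vector of length 3: voxel counts per axis.
#' @param affine 4 x 4 voxel-index-to-world matrix; must be invertible.
#' @return A `volume_grid` with derived `voxel_volume` (mm^3).
#' @export
volume_grid <- function(shape, affine) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("volume_grid: shape must be 3 positive voxel counts")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("volume_grid: affine must be 4 x 4")
  d3 <- det(affine[1:3, 1:3])
  if (!is.finite(d3) || abs(d3) < .Machine$double.eps * 64)
    stop("volume_grid: affine is singular")
  structure(list(shape = shape, affine = affine,
                 affine_inv = solve(affine),
                 voxel_volume = abs(d3)),
            class = "volume_grid")
}

#' Convenience constructor for an axis-aligned isotropic grid
#'
#' @param shape Voxel counts per axis.
#' @param voxel_mm Voxel edge lengths, recycled to length 3.
#' @param origin_mm World coordinate of voxel (0,0,0)'s center.
#' @return A [volume_grid()].
#' @export
grid_iso <- function(shape, voxel_mm = 2, origin_mm = c(0, 0, 0)) {
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3L)
  aff <- diag(c(voxel_mm, 1))
  aff[1:3, 4] <- origin_mm
  volume_grid(shape, aff)
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d x %d x %d voxels, voxel volume %.3f mm^3\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_volume))
  invisible(x)
}

# round half away from zero (deterministic, symmetric about voxel centers)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Map world coordinates to voxel indices
#'
#' Applies the grid's inverse affine and rounds to the nearest voxel
#' (half away from zero).  Indices are 0-based.
#'
#' @param p World coordinates (mm): `point3`, length-3 numeric, or n x 3 matrix.
#' @param grid A [volume_grid()].
#' @return Integer n x 3 matrix of voxel indices with a logical attribute
#'   `in_grid` flagging rows that fall inside the raster.
#' @export
world_to_voxel <- function(p, grid) {
  stopifnot(inherits(grid, "volume_grid"))
  xyz <- .as_xyz_matrix(p)
  hom <- cbind(xyz, 1) %*% t(grid$affine_inv)
  idx <- .round_half_away(hom[, 1:3, drop = FALSE])
  ok <- idx[, 1] >= 0 & idx[, 1] < grid$shape[1] &
        idx[, 2] >= 0 & idx[, 2] < grid$shape[2] &
        idx[, 3] >= 0 & idx[, 3] < grid$shape[3]
  storage.mode(idx) <- "integer"
  attr(idx, "in_grid") <- as.logical(ok)
  idx
}

#' Map 0-based voxel indices to world coordinates (voxel centers)
#'
#' @param idx n x 3 matrix (or length-3 vector) of 0-based voxel indices.
#' @param grid A [volume_grid()].
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxel_to_world <- function(idx, grid) {
  stopifnot(inherits(grid, "volume_grid"))
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1)
  hom <- cbind(idx[, 1], idx[, 2], idx[, 3], 1) %*% t(grid$affine)
  hom[, 1:3, drop = FALSE]
}

# world-mm centers of every voxel (column-major order, matching array linear
# indexing) or of the voxels selected by a logical/array mask
.grid_centers <- function(grid, select = NULL) {
  idx <- arrayInd(seq_len(prod(grid$shape)), .dim = grid$shape) - 1L
  if (!is.null(select)) idx <- idx[as.logical(select), , drop = FALSE]
  voxel_to_world(idx, grid)
}
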