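# VBM statistics stage: Gaussian smoothing of gray-matter volumes, voxelwise
# regression of intensity on a behavioral covariate, voxel-p + cluster-extent
# thresholding, peak extraction, and sphere-ROI overlap.

#' Bundle aligned gray-matter images
#'
#' @param data n_subjects x n_voxels matrix of intensities (one row per
#'   subject, voxels in column-major array order), or a list of 3-D arrays.
#' @param grid The shared [volume_grid()].
#' @param subject_ids Character vector of subject identifiers.
#' @return A `gm_image_set`.
#' @export
gm_image_set <- function(data, grid, subject_ids = NULL) {
  stopifnot(inherits(grid, "volume_grid"))
  if (is.list(data)) {
    stopifnot(all(vapply(data, function(a) all(dim(a) == grid$shape), TRUE)))
    data <- do.call(rbind, lapply(data, as.vector))
  }
  data <- as.matrix(data)
  if (ncol(data) != prod(grid$shape))
    stop("gm_image_set: data columns must equal the voxel count of the grid")
  if (nrow(data) < 3L) stop("gm_image_set: need at least 3 subjects")
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_len(nrow(data)))
  if (length(subject_ids) != nrow(data))
    stop("gm_image_set: one subject_id per image required")
  structure(list(data = data, grid = grid,
                 subject_ids = as.character(subject_ids)),
            class = "gm_image_set")
}

#' @export
print.gm_image_set <- function(x, ...) {
  cat(sprintf("<gm_image_set> %d subjects on a %s grid\n", nrow(x$data),
              paste(x$grid$shape, collapse = " x ")))
  invisible(x)
}

# 1-D boundary-renormalized Gaussian convolution matrix (rows sum to 1, so
# constants are preserved at the edges)
.smooth_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  hw <- max(1L, ceiling(4 * sigma_vox))
  d <- outer(seq_len(n), seq_len(n), `-`)
  K <- exp(-d^2 / (2 * sigma_vox^2))
  K[abs(d) > hw] <- 0
  K / rowSums(K)
}

.smooth_array <- function(arr, fwhm_mm, spacings) {
  sh <- dim(arr)
  sig <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / spacings  # per-axis, in voxels
  for (ax in 1:3) {
    if (sig[ax] <= 0) next
    K <- .smooth_matrix(sh[ax], sig[ax])
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    da <- dim(a)
    a <- K %*% matrix(a, nrow = sh[ax])
    dim(a) <- da
    arr <- aperm(a, order(perm))
  }
  arr
}

#' Isotropic Gaussian smoothing in mm units
#'
#' Separable filtering with per-axis sigma derived from the voxel size
#' (anisotropic voxels handled per axis).  The kernel is renormalized at the
#' boundary so constant volumes pass through unchanged; `fwhm_mm = 0` is the
#' identity.
#'
#' @param x A [volume()], a `gm_image_set`, or a 3-D array.
#' @param fwhm_mm Kernel full-width at half-maximum in mm (>= 0).
#' @param spacings Voxel spacings, only needed when `x` is a bare array.
#' @return Smoothed object of the same class.
#' @export
gaussian_smooth <- function(x, fwhm_mm, spacings = NULL) {
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm < 0)
    stop("gaussian_smooth: fwhm_mm must be a single number >= 0")
  if (inherits(x, "gm_image_set")) {
    sp <- sqrt(colSums(x$grid$affine[1:3, 1:3]^2))
    sh <- x$grid$shape
    x$data <- t(apply(x$data, 1, function(v)
      as.vector(.smooth_array(array(v, sh), fwhm_mm, sp))))
    return(x)
  }
  if (inherits(x, "volume")) {
    sp <- sqrt(colSums(x$grid$affine[1:3, 1:3]^2))
    x$values <- .smooth_array(x$values, fwhm_mm, sp)
    return(x)
  }
  if (is.null(spacings)) stop("gaussian_smooth: spacings required for a bare array")
  .smooth_array(as.array(x), fwhm_mm, rep_len(spacings, 3L))
}

#' Voxelwise slope T-map of intensity on a covariate
#'
#' Per voxel, the simple linear regression intensity ~ intercept + covariate;
#' T = slope / SE(slope) with df = n - 2 (equivalently the Pearson identity
#' T = r sqrt((n-2)/(1-r^2))).  P-values are one-sided upper tail (positive
#' association), mirroring a one-sided T contrast.
#'
#' @param images A [gm_image_set()].
#' @param covariate Numeric vector, one value per subject, non-constant.
#' @param mask Optional [mask_volume()]; voxels outside get T = 0, p = 1.
#' @return A `stat_map`: `grid`, `t_values` and `p_values` (3-D arrays),
#'   `df`, and `n_constant` (count of zero-variance voxels, flagged T = 0,
#'   p = 1).
#' @export
voxelwise_slope_t <- function(images, covariate, mask = NULL) {
  stopifnot(inherits(images, "gm_image_set"))
  n <- nrow(images$data)
  if (length(covariate) != n)
    stop("voxelwise_slope_t: covariate length must equal the number of subjects")
  if (stats::var(covariate) == 0)
    stop("voxelwise_slope_t: covariate is constant")
  sel <- if (is.null(mask)) rep(TRUE, ncol(images$data)) else {
    .check_same_grid(mask, images, "mask and images")
    as.vector(mask$values)
  }
  Y <- images$data[, sel, drop = FALSE]
  xc <- covariate - mean(covariate)
  sxx <- sum(xc^2)
  sxy <- drop(crossprod(xc, Y))
  # centered sum of squares; the uncentered shortcut loses ~8 digits to
  # cancellation when the baseline dominates the signal
  syy <- colSums(sweep(Y, 2, colMeans(Y))^2)
  slope <- sxy / sxx
  df <- n - 2L
  ss_res <- pmax(syy - slope^2 * sxx, 0)
  tval <- numeric(length(slope))
  const <- syy <= .Machine$double.eps * n * pmax(colMeans(Y)^2, 1)
  exact <- !const & ss_res <= 1e-12 * pmax(syy, .Machine$double.eps)
  ok <- !const & !exact
  tval[ok] <- slope[ok] / sqrt(ss_res[ok] / df / sxx)
  tval[exact] <- sign(slope[exact]) * Inf
  tval[const] <- 0
  pval <- stats::pt(tval, df, lower.tail = FALSE)
  pval[const] <- 1

  t_arr <- array(0, dim = images$grid$shape)
  p_arr <- array(1, dim = images$grid$shape)
  t_arr[sel] <- tval
  p_arr[sel] <- pval
  structure(list(grid = images$grid, t_values = t_arr, p_values = p_arr,
                 df = df, n_constant = sum(const)),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> df = %d, max T = %.3f\n", x$df, max(x$t_values)))
  invisible(x)
}

#' Clustering configuration
#'
#' @param p_voxel Voxel-level threshold (default 0.001, uncorrected).
#' @param k_min Extent threshold; a cluster survives iff its size is
#'   strictly greater than `k_min` (default 150).
#' @param connectivity 6, 18 or 26 neighbors (default 18).
#' @return A `cluster_config`.
#' @export
cluster_config <- function(p_voxel = 0.001, k_min = 150, connectivity = 18) {
  if (!is.numeric(p_voxel) || p_voxel <= 0 || p_voxel >= 1)
    stop("cluster_config: p_voxel must lie in (0, 1)")
  if (!is.numeric(k_min) || k_min < 0)
    stop("cluster_config: k_min must be >= 0")
  if (!connectivity %in% c(6, 18, 26))
    stop("cluster_config: connectivity must be 6, 18 or 26")
  structure(list(p_voxel = p_voxel, k_min = as.integer(k_min),
                 connectivity = as.integer(connectivity)),
            class = "cluster_config")
}

.neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1)
  g[keep, , drop = FALSE]
}

# connected-component labeling by queue-based flood fill
.label_components <- function(bin, connectivity) {
  sh <- dim(bin)
  labels <- array(0L, dim = sh)
  offs <- .neighbor_offsets(connectivity)
  fg <- which(bin)
  if (!length(fg)) return(labels)
  coords <- arrayInd(fg, .dim = sh)
  lin_of <- array(0L, dim = sh); lin_of[fg] <- seq_along(fg)
  cur <- 0L
  queue <- integer(length(fg))
  for (start in fg) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    labels[start] <- cur
    queue[1L] <- start; head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      vc <- coords[lin_of[v], ]
      for (o in seq_len(nrow(offs))) {
        nb <- vc + offs[o, ]
        if (any(nb < 1L) || any(nb > sh)) next
        lin <- nb[1] + (nb[2] - 1L) * sh[1] + (nb[3] - 1L) * sh[1] * sh[2]
        if (bin[lin] && labels[lin] == 0L) {
          labels[lin] <- cur
          tail <- tail + 1L
          queue[tail] <- lin
        }
      }
    }
  }
  labels
}

#' Extract suprathreshold clusters from a T-map
#'
#' Binarizes at `p < p_voxel`, labels connected components under the
#' configured connectivity, and retains components strictly larger than
#' `k_min` voxels, sorted by peak T descending.
#'
#' @param stat A `stat_map`.
#' @param cfg A [cluster_config()].
#' @return A `cluster_set`: list with `clusters` (each with `label`,
#'   `size_voxels`, `size_mm3`, `peak_voxel` (0-based), `peak_world_mm`,
#'   `peak_t`), the full `labels` array, and `cfg`.  Empty is valid.
#' @export
suprathreshold_clusters <- function(stat, cfg = cluster_config()) {
  stopifnot(inherits(stat, "stat_map"), inherits(cfg, "cluster_config"))
  bin <- stat$p_values < cfg$p_voxel
  labels <- .label_components(bin, cfg$connectivity)
  ncomp <- max(labels)
  clusters <- list()
  if (ncomp > 0L) {
    sizes <- tabulate(labels[labels > 0L], nbins = ncomp)
    keep <- which(sizes > cfg$k_min)
    clusters <- lapply(keep, function(lab) {
      members <- which(labels == lab)
      tmem <- stat$t_values[members]
      # peak tie-break: lexicographic (smallest linear index among max T)
      peak_lin <- members[which(tmem == max(tmem))[1L]]
      peak_idx <- arrayInd(peak_lin, .dim = stat$grid$shape) - 1L
      structure(list(label = lab,
                     size_voxels = sizes[lab],
                     size_mm3 = sizes[lab] * stat$grid$voxel_volume,
                     peak_voxel = drop(peak_idx),
                     peak_world_mm = drop(voxel_to_world(peak_idx, stat$grid)),
                     peak_t = max(tmem)),
                class = "cluster")
    })
    clusters <- clusters[order(-vapply(clusters, `[[`, 1, "peak_t"))]
  }
  structure(list(clusters = clusters, labels = labels, cfg = cfg),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s) (p < %g, k > %d, %d-connectivity)\n",
              length(x$clusters), x$cfg$p_voxel, x$cfg$k_min, x$cfg$connectivity))
  for (cl in x$clusters)
    cat(sprintf("  #%d: %d voxels (%.0f mm^3), peak T = %.3f at (%.1f, %.1f, %.1f) mm\n",
                cl$label, cl$size_voxels, cl$size_mm3, cl$peak_t,
                cl$peak_world_mm[1], cl$peak_world_mm[2], cl$peak_world_mm[3]))
  invisible(x)
}

#' Peaks within a cluster
#'
#' Greedy selection of cluster voxels by descending T with a minimum mutual
#' separation in mm; ties broken by lexicographic (linear) voxel index.
#'
#' @param stat The `stat_map` the cluster came from.
#' @param cluster A `cluster` (from [suprathreshold_clusters()]), or a
#'   `cluster_set` whose labels identify it together with `label`.
#' @param min_separation_mm Minimum distance between reported peaks
#'   (default 8).
#' @param labels The label array of the owning `cluster_set`.
#' @return Data frame of peaks: voxel index columns, world mm columns, `t`,
#'   ordered by descending T.
#' @export
cluster_peaks <- function(stat, cluster, min_separation_mm = 8, labels = NULL) {
  stopifnot(inherits(stat, "stat_map"))
  if (inherits(cluster, "cluster_set")) {
    if (!length(cluster$clusters)) stop("cluster_peaks: empty cluster set")
    labels <- cluster$labels
    cluster <- cluster$clusters[[1L]]
  }
  if (is.null(labels)) stop("cluster_peaks: the label array is required")
  members <- which(labels == cluster$label)
  tmem <- stat$t_values[members]
  ord <- order(-tmem, members)
  members <- members[ord]; tmem <- tmem[ord]
  world <- voxel_to_world(arrayInd(members, .dim = stat$grid$shape) - 1L,
                          stat$grid)
  sel <- integer(0)
  for (i in seq_along(members)) {
    if (!length(sel)) { sel <- i; next }
    d <- sqrt(rowSums((world[sel, , drop = FALSE] -
                         matrix(world[i, ], length(sel), 3, byrow = TRUE))^2))
    if (all(d >= min_separation_mm)) sel <- c(sel, i)
  }
  idx <- arrayInd(members[sel], .dim = stat$grid$shape) - 1L
  data.frame(vx = idx[, 1], vy = idx[, 2], vz = idx[, 3],
             x_mm = world[sel, 1], y_mm = world[sel, 2], z_mm = world[sel, 3],
             t = tmem[sel])
}

#' Cluster table for reporting
#'
#' @param cluster_set A `cluster_set`.
#' @return Data frame: `label, size_voxels, size_mm3, peak_x_mm, peak_y_mm,
#'   peak_z_mm, peak_t`.
#' @export
cluster_table <- function(cluster_set) {
  stopifnot(inherits(cluster_set, "cluster_set"))
  if (!length(cluster_set$clusters))
    return(data.frame(label = integer(0), size_voxels = integer(0),
                      size_mm3 = numeric(0), peak_x_mm = numeric(0),
                      peak_y_mm = numeric(0), peak_z_mm = numeric(0),
                      peak_t = numeric(0)))
  do.call(rbind, lapply(cluster_set$clusters, function(cl)
    data.frame(label = cl$label, size_voxels = cl$size_voxels,
               size_mm3 = cl$size_mm3,
               peak_x_mm = cl$peak_world_mm[1],
               peak_y_mm = cl$peak_world_mm[2],
               peak_z_mm = cl$peak_world_mm[3],
               peak_t = cl$peak_t)))
}
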