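# Permutation inference for ALE: a pooled null of in-mask voxel values from
# randomly placed foci, a single critical score at level alpha, and strict
# thresholding of observed maps.
#
# The null preserves the observed per-study focus counts (hence the 1/n_foci
# weights); only focus placement is randomized — uniform over mask voxel
# centers, with replacement, permutations independent.  The null pools all
# in-mask voxel values across permutations (single-threshold test), not
# per-permutation maxima.

#' Sample the permutation null distribution of ALE scores
#'
#' @param study_sizes Integer vector: number of foci per study, as observed.
#' @param mask A [mask_volume()] with at least 2 foreground voxels.
#' @param grid The evaluation [volume_grid()].
#' @param kernel A [kernel_spec()].
#' @param n_perms Number of permutations (default 10000, as in the classic
#'   single-threshold test).
#' @param seed Integer seed; identical inputs and seed reproduce the samples
#'   bitwise.  The caller's RNG state is left untouched.
#' @return An `ale_null`: `samples` (pooled in-mask ALE values, length
#'   n_perms * n_mask_voxels), `n_perms`, `study_sizes`, `seed`.
#' @export
sample_null <- function(study_sizes, mask, grid, kernel, n_perms = 10000,
                        seed = 1L) {
  stopifnot(inherits(mask, "mask_volume"), inherits(grid, "volume_grid"),
            inherits(kernel, "kernel_spec"))
  study_sizes <- as.integer(study_sizes)
  if (!length(study_sizes) || any(study_sizes < 1L))
    stop("sample_null: study_sizes must be positive integers")
  if (n_perms < 1L) stop("sample_null: n_perms must be >= 1")
  .check_same_grid(mask, list(grid = grid), "mask and grid")
  centers <- .mask_centers(mask)
  nvox <- nrow(centers)
  if (nvox < 2L) stop("sample_null: mask smaller than 2 voxels gives a degenerate null")

  sigma <- kernel$sigma_mm
  vv <- grid$voxel_volume
  n_total <- sum(study_sizes)
  study_of_focus <- rep(seq_along(study_sizes), study_sizes)
  w <- 1 / study_sizes[study_of_focus]

  samples <- .with_seed(seed, {
    out <- vector("list", n_perms)
    k <- vv / ((2 * pi)^1.5 * sigma^3)
    for (perm in seq_len(n_perms)) {
      pick <- sample.int(nvox, n_total, replace = TRUE)
      fx <- centers[pick, , drop = FALSE]
      # per-focus probabilities at every mask voxel: n_total x nvox
      d2 <- outer(rowSums(fx^2), rowSums(centers^2), `+`) -
        2 * (fx %*% t(centers))
      p <- pmin(w * k * exp(-pmax(d2, 0) / (2 * sigma^2)), 1)
      # nested union (within study, then across studies) collapses to one
      # product over all foci because 1 - study_val = prod_f (1 - p_f)
      out[[perm]] <- -expm1(colSums(log1p(-p)))
    }
    unlist(out, use.names = FALSE)
  })
  structure(list(samples = samples, n_perms = as.integer(n_perms),
                 study_sizes = study_sizes, seed = as.integer(seed)),
            class = "ale_null")
}

#' @export
print.ale_null <- function(x, ...) {
  cat(sprintf("<ale_null> %d pooled values from %d permutations (%d studies, seed %d)\n",
              length(x$samples), x$n_perms, length(x$study_sizes), x$seed))
  invisible(x)
}

#' Critical ALE score at significance level alpha
#'
#' The inclusive empirical (1 - alpha)-quantile: the ceiling((1-alpha) * N)-th
#' order statistic of the pooled null samples.
#'
#' @param null An `ale_null` from [sample_null()].
#' @param alpha Significance level in (0, 1) (default 0.01).
#' @return A `critical_score`: list with `alpha` and `value`.
#' @export
critical_score <- function(null, alpha = 0.01) {
  stopifnot(inherits(null, "ale_null"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("critical_score: alpha must lie in (0, 1)")
  n <- length(null$samples)
  if (!n) stop("critical_score: empty null distribution")
  k <- ceiling((1 - alpha) * n)
  k <- min(max(k, 1L), n)
  value <- sort(null$samples, partial = k)[k]
  structure(list(alpha = alpha, value = value), class = "critical_score")
}

#' Threshold an ALE map at the critical score
#'
#' Strict inequality: a voxel survives iff its ALE value exceeds the
#' critical value.
#'
#' @param ale An `ale_map`.
#' @param critical A `critical_score`.
#' @return Binary [volume()] with attribute `n_suprathreshold`.
#' @export
threshold_ale <- function(ale, critical) {
  stopifnot(inherits(ale, "ale_map"), inherits(critical, "critical_score"))
  supra <- ale$values > critical$value
  out <- volume(array(supra, dim = ale$grid$shape), ale$grid)
  attr(out, "n_suprathreshold") <- sum(supra)
  attr(out, "critical_value") <- critical$value
  out
}
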