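# Independent brute-force oracles.  These deliberately use naive loops and
# different algorithms from the package implementations they check.

# minimum Euclidean distance from each row of xyz to any foreground voxel
# center of `mask`, by exhaustive scan
oracle_min_dist <- function(xyz, mask) {
  centers <- voxel_to_world(which(mask$values, arr.ind = TRUE) - 1L, mask$grid)
  apply(xyz, 1, function(p) {
    best <- Inf
    for (i in seq_len(nrow(centers)))
      best <- min(best, sqrt(sum((p - centers[i, ])^2)))
    best
  })
}

# per-voxel ALE by direct evaluation of the nested product formula
oracle_ale <- function(studies, grid, kernel, mask = NULL) {
  centers <- alemorph:::.grid_centers(grid)
  sel <- if (is.null(mask)) rep(TRUE, nrow(centers)) else as.vector(mask$values)
  s <- kernel$sigma_mm
  vv <- grid$voxel_volume
  vals <- numeric(nrow(centers))
  for (v in which(sel)) {
    surv_total <- 1
    for (st in studies) {
      surv_study <- 1
      for (f in seq_len(st$n_foci)) {
        d2 <- sum((centers[v, ] - st$foci[f, ])^2)
        dens <- exp(-d2 / (2 * s^2)) / ((2 * pi)^1.5 * s^3)
        p <- min(1, (1 / st$n_foci) * dens * vv)
        surv_study <- surv_study * (1 - p)
      }
      surv_total <- surv_total * surv_study
    }
    vals[v] <- 1 - surv_total
  }
  array(vals, dim = grid$shape)
}

# connected-component labeling by iterative minimum-label propagation
# (different algorithm from the package's queue flood fill)
oracle_label <- function(bin, connectivity) {
  sh <- dim(bin)
  offs <- alemorph:::.neighbor_offsets(connectivity)
  lab <- array(0L, dim = sh)
  fg <- which(bin)
  lab[fg] <- seq_along(fg)
  coords <- which(bin, arr.ind = TRUE)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(coords))) {
      vc <- coords[i, ]
      cur <- lab[vc[1], vc[2], vc[3]]
      for (o in seq_len(nrow(offs))) {
        nb <- vc + offs[o, ]
        if (any(nb < 1L) || any(nb > sh)) next
        nl <- lab[nb[1], nb[2], nb[3]]
        if (nl > 0L && nl < cur) { cur <- nl; changed <- TRUE }
      }
      lab[vc[1], vc[2], vc[3]] <- cur
    }
    if (!changed) break
  }
  # canonical relabeling 1..k in first-appearance order
  u <- unique(lab[lab > 0L])
  out <- array(0L, dim = sh)
  for (i in seq_along(u)) out[lab == u[i]] <- i
  out
}

# partition of labels as sets of linear indices (order-free comparison)
label_partition <- function(lab) {
  lapply(unname(split(which(lab > 0L), lab[lab > 0L])), sort)
}

# per-voxel regression t via stats::lm
oracle_t_map <- function(Y, x) {
  vapply(seq_len(ncol(Y)), function(j) {
    fit <- summary(stats::lm(Y[, j] ~ x))
    unname(fit$coefficients["x", "t value"])
  }, numeric(1))
}

# stat_map built directly from a T array (for cluster-stage tests)
make_stat_map <- function(t_arr, df, grid) {
  structure(list(grid = grid, t_values = t_arr,
                 p_values = stats::pt(t_arr, df, lower.tail = FALSE),
                 df = df, n_constant = 0L),
            class = "stat_map")
}

# small ellipsoid mask fixture
toy_mask_fixture <- function(shape = c(12, 12, 12), voxel = 2,
                             semi = c(9, 7, 6)) {
  g <- grid_iso(shape, voxel)
  ctr <- (shape - 1) / 2 * voxel
  make_toy_mask(g, ctr, semi)
}

# foci table fixture builder
foci_df <- function(x, y, z, study = "s1", category = "emotion",
                    modality = "fMRI", space = "MNI", n_subjects = 12) {
  data.frame(study_id = study, category = category, modality = modality,
             space = space, x_mm = x, y_mm = y, z_mm = z,
             n_subjects = n_subjects, stringsAsFactors = FALSE)
}
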