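# Foci tables: parsing/validation, space harmonization, the 5-mm
# mask-tolerance outlier filter, and grouping into per-study records.

.FOCI_COLUMNS <- c("study_id", "category", "modality", "space",
                   "x_mm", "y_mm", "z_mm", "n_subjects")
.CATEGORIES <- c("physical_pain", "emotion", "empathy_for_pain", "motor", "other")
.MODALITIES <- c("fMRI", "PET")

.canon_space <- function(x) {
  out <- rep(NA_character_, length(x))
  lx <- tolower(trimws(as.character(x)))
  out[lx %in% c("tal", "talairach")] <- "TAL"
  out[lx == "mni"] <- "MNI"
  out
}

.canon_modality <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[lx == "fmri"] <- "fMRI"
  out[lx == "pet"] <- "PET"
  out
}

.validate_foci <- function(df) {
  errs <- character(0)
  n <- nrow(df)
  bad <- function(cond, msg) {
    rows <- which(cond)
    if (length(rows))
      errs <<- c(errs, sprintf("row %d: %s", rows, msg))
  }
  suppressWarnings({
    xyz_num <- vapply(c("x_mm", "y_mm", "z_mm"), function(cl)
      as.numeric(as.character(df[[cl]])), numeric(n))
    ns <- as.numeric(as.character(df$n_subjects))
  })
  if (n == 1L) xyz_num <- matrix(xyz_num, nrow = 1)
  bad(is.na(df$study_id) | !nzchar(trimws(as.character(df$study_id))),
      "missing study_id")
  bad(!(as.character(df$category) %in% .CATEGORIES),
      sprintf("unknown category (allowed: %s)", paste(.CATEGORIES, collapse = ", ")))
  bad(is.na(.canon_space(df$space)), "unknown space token (allowed: TAL, Talairach, MNI)")
  bad(is.na(.canon_modality(df$modality)), "unknown modality (allowed: fMRI, PET)")
  for (j in 1:3)
    bad(!is.finite(xyz_num[, j]),
        sprintf("non-numeric %s", c("x_mm", "y_mm", "z_mm")[j]))
  bad(!is.finite(ns) | ns < 1 | ns != round(ns),
      "n_subjects must be a positive integer")
  if (length(errs))
    stop("invalid foci table:\n  ", paste(errs, collapse = "\n  "), call. = FALSE)
  data.frame(study_id = as.character(df$study_id),
             category = as.character(df$category),
             modality = .canon_modality(df$modality),
             space = .canon_space(df$space),
             x_mm = xyz_num[, 1], y_mm = xyz_num[, 2], z_mm = xyz_num[, 3],
             n_subjects = as.integer(ns),
             stringsAsFactors = FALSE)
}

#' Build a validated foci table
#'
#' @param df Data frame with columns `study_id, category, modality, space,
#'   x_mm, y_mm, z_mm, n_subjects`.  Space tokens `TAL`, `Talairach`, `MNI`
#'   (case-insensitive) are canonicalized; categories come from the closed
#'   vocabulary `physical_pain, emotion, empathy_for_pain, motor, other`.
#' @return A `foci_table` data frame.  Row-level problems are collected and
#'   reported together with row numbers.
#' @export
foci_table <- function(df) {
  missing_cols <- setdiff(.FOCI_COLUMNS, names(df))
  if (length(missing_cols))
    stop("foci table is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  out <- .validate_foci(df)
  class(out) <- c("foci_table", "data.frame")
  out
}

#' Read a foci table from CSV
#'
#' CSV dialect: UTF-8, comma-separated, header row required, columns
#' `study_id, category, modality, space, x_mm, y_mm, z_mm, n_subjects`.
#'
#' @param path CSV file path.
#' @return A validated `foci_table`.
#' @export
read_foci_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                        strip.white = TRUE)
  foci_table(df)
}

#' Write a foci table as CSV with canonical tokens
#'
#' @param foci A `foci_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_foci_table <- function(foci, path) {
  stopifnot(inherits(foci, "foci_table"))
  utils::write.csv(as.data.frame(foci), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Harmonize all foci to MNI space
#'
#' Talairach rows are converted with [tal2mni()]; MNI rows pass through.
#'
#' @param foci A `foci_table`.
#' @return A `foci_table` with `space` uniformly `"MNI"`.
#' @export
harmonize_space <- function(foci) {
  stopifnot(inherits(foci, "foci_table"))
  is_tal <- foci$space == "TAL"
  if (any(is_tal)) {
    xyz <- tal2mni(as.matrix(foci[is_tal, c("x_mm", "y_mm", "z_mm")]))
    foci$x_mm[is_tal] <- xyz[, 1]
    foci$y_mm[is_tal] <- xyz[, 2]
    foci$z_mm[is_tal] <- xyz[, 3]
    foci$space[is_tal] <- "MNI"
  }
  foci
}

#' Distance from each focus to the nearest mask voxel center
#'
#' @param foci A `foci_table` in MNI space.
#' @param mask A [mask_volume()].
#' @return Numeric vector of Euclidean distances in mm (0 for a focus at a
#'   foreground voxel center).
#' @export
mask_distance <- function(foci, mask) {
  stopifnot(inherits(foci, "foci_table"), inherits(mask, "mask_volume"))
  cen <- .mask_centers(mask)
  xyz <- as.matrix(foci[, c("x_mm", "y_mm", "z_mm")])
  # n_foci x n_mask squared distances via the expansion |f|^2 + |c|^2 - 2 f.c
  cross <- xyz %*% t(cen)
  d2 <- outer(rowSums(xyz^2), rowSums(cen^2), `+`) - 2 * cross
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Apply the mask-tolerance outlier filter
#'
#' A focus is kept iff its distance to the nearest foreground voxel center is
#' at most `tol_mm` (boundary inclusive); foci beyond the grid are handled by
#' the same distance rule, never silently dropped.  The partition is
#' exhaustive and disjoint.
#'
#' @param foci A `foci_table` in MNI space (run [harmonize_space()] first).
#' @param mask A [mask_volume()].
#' @param tol_mm Tolerance in mm (default 5, the usual outlier rule).
#' @return List with `kept` and `excluded` foci tables; both carry a
#'   `dist_mm` column with the measured distances.
#' @export
filter_to_mask <- function(foci, mask, tol_mm = 5) {
  stopifnot(inherits(foci, "foci_table"))
  if (any(foci$space != "MNI"))
    stop("filter_to_mask: foci must be harmonized to MNI first")
  d <- mask_distance(foci, mask)
  foci$dist_mm <- d
  keep <- d <= tol_mm
  out <- list(kept = foci[keep, , drop = FALSE],
              excluded = foci[!keep, , drop = FALSE])
  class(out$kept) <- class(out$excluded) <- c("foci_table", "data.frame")
  if (any(!keep))
    message(sprintf("filter_to_mask: excluded %d of %d foci (distances %s mm)",
                    sum(!keep), length(keep),
                    paste(sprintf("%.1f", d[!keep]), collapse = ", ")))
  out
}

#' Group foci into per-study records
#'
#' One `study` per (study_id, category) pair, so a publication contributing
#' to two analysis categories forms two records; per-study focus counts
#' determine the 1/n_foci kernel weights downstream.
#'
#' @param foci A harmonized, filtered `foci_table`.
#' @param excluded Optional `foci_table` of filtered-out rows (from
#'   [filter_to_mask()]); studies all of whose foci were excluded are
#'   reported with a warning.
#' @return List of `study` objects: `study_id`, `category`, `modality`,
#'   `n_subjects`, `foci` (n x 3 MNI mm matrix), `n_foci`.
#' @export
group_into_studies <- function(foci, excluded = NULL) {
  stopifnot(inherits(foci, "foci_table"))
  if (!is.null(excluded) && nrow(excluded)) {
    gone <- setdiff(paste(excluded$study_id, excluded$category),
                    paste(foci$study_id, foci$category))
    if (length(gone))
      warning("group_into_studies: all foci excluded for: ",
              paste(gone, collapse = "; "), call. = FALSE)
  }
  if (nrow(foci) == 0L) stop("group_into_studies: no foci to group")
  key <- paste(foci$study_id, foci$category, sep = "\r")
  split_rows <- split(seq_len(nrow(foci)), key)
  # deterministic order: first appearance in the table
  split_rows <- split_rows[order(vapply(split_rows, min, 1L))]
  studies <- lapply(split_rows, function(rows) {
    sub <- foci[rows, , drop = FALSE]
    ns <- unique(sub$n_subjects)
    if (length(ns) != 1L)
      stop("group_into_studies: conflicting n_subjects within study '",
           sub$study_id[1], "' (", paste(ns, collapse = ", "), ")")
    structure(list(study_id = sub$study_id[1],
                   category = sub$category[1],
                   modality = sub$modality[1],
                   n_subjects = ns,
                   foci = unname(as.matrix(sub[, c("x_mm", "y_mm", "z_mm")])),
                   n_foci = nrow(sub)),
              class = "study")
  })
  names(studies) <- NULL
  studies
}

#' @export
print.study <- function(x, ...) {
  cat(sprintf("<study %s/%s> %s, n=%d subjects, %d foci\n",
              x$study_id, x$category, x$modality, x$n_subjects, x$n_foci))
  invisible(x)
}
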