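# Image extraction: optional Gaussian smoothing, whole-brain intensity
# normalization, and reduction of each subject's volume to one mean uptake
# value per VOI.

#' Convert a Gaussian FWHM to its standard deviation
#'
#' `sigma = fwhm / (2 * sqrt(2 * log(2)))`; e.g. the conventional 8 mm PET
#' smoothing kernel has sigma 3.39728 mm.
#'
#' @param fwhm Full width at half maximum (same units as the result).
#' @return Standard deviation.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# 1-D convolution matrix with nearest-edge replication: out = K %*% x.
.smooth_matrix <- function(n, sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  w <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (k in seq_along(w)) {
    off <- k - r - 1L
    src <- pmin(pmax(seq_len(n) + off, 1L), n)   # replicate edges
    K[cbind(seq_len(n), src)] <- K[cbind(seq_len(n), src)] + w[k]
  }
  K
}

# Apply a matrix along one axis of a 3-D array.
.apply_axis <- function(arr, K, axis) {
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  a <- array(K %*% matrix(a, nrow = d[1]), dim = d)
  aperm(a, order(perm))
}

#' Smooth a volume with an isotropic world-space Gaussian kernel
#'
#' Separable per-axis filtering; the kernel is specified in millimetres and
#' converted to per-axis voxel sigmas through the affine, so anisotropic
#' voxels (e.g. 1.95 x 1.95 x 4.25 mm PET grids) are handled correctly.
#' Boundaries use nearest-edge replication, which keeps constant images
#' constant and avoids dimming brain-edge voxels. `fwhm_mm = 0` is the
#' identity.
#'
#' @param volume A [brain_volume()].
#' @param fwhm_mm Kernel full width at half maximum in mm (>= 0).
#' @return The smoothed [brain_volume()].
#' @export
gaussian_smooth <- function(volume, fwhm_mm) {
  stopifnot(inherits(volume, "brain_volume"))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm < 0) {
    stop("fwhm_mm must be a single non-negative number", call. = FALSE)
  }
  check_affine(volume$affine)
  if (fwhm_mm == 0) return(volume)
  sigma_vox <- fwhm_to_sigma(fwhm_mm) / voxel_sizes(volume$affine)
  arr <- volume$data
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0) {
      arr <- .apply_axis(arr, .smooth_matrix(dim(arr)[ax], sigma_vox[ax]), ax)
    }
  }
  volume$data <- arr
  volume
}

#' Heuristic brain mask
#'
#' Voxels above 12.5% of the robust maximum (the 99th intensity percentile).
#' Deterministic and adequate for defining "the brain" when normalizing PET
#' counts; supply an explicit mask when a real one is available.
#'
#' @param volume A [brain_volume()].
#' @return Logical array of the volume's shape.
#' @export
auto_brain_mask <- function(volume) {
  stopifnot(inherits(volume, "brain_volume"))
  thr <- 0.125 * stats::quantile(volume$data, 0.99, names = FALSE)
  volume$data > thr
}

#' Normalize voxel intensities by the whole-brain mean
#'
#' Divides every voxel by the mean intensity within the brain mask, so the
#' masked mean of the output is exactly 1. This is the standard count
#' normalization applied to FDG-PET images before covariance analysis.
#'
#' @param volume A [brain_volume()].
#' @param brain_mask Logical array matching the volume, or `"auto"` to use
#'   [auto_brain_mask()].
#' @return The normalized [brain_volume()]; the mask mean used is attached as
#'   attribute `"brain_mean"`.
#' @export
normalize_by_brain_mean <- function(volume, brain_mask = "auto") {
  stopifnot(inherits(volume, "brain_volume"))
  if (identical(brain_mask, "auto")) brain_mask <- auto_brain_mask(volume)
  if (!identical(dim(brain_mask), dim(volume$data))) {
    stop("brain_mask shape does not match the volume", call. = FALSE)
  }
  if (!any(brain_mask)) stop("brain mask is empty", call. = FALSE)
  m <- mean(volume$data[brain_mask])
  if (!is.finite(m) || m <= 0) {
    stop("masked mean intensity is not positive; corrupted image?",
         call. = FALSE)
  }
  volume$data <- volume$data / m
  attr(volume, "brain_mean") <- m
  volume
}

#' Extract per-VOI mean uptake from a volume
#'
#' Entry v is the arithmetic mean of the voxel values inside VOI v's mask, in
#' atlas order.
#'
#' @param volume A [brain_volume()].
#' @param masks A `voi_mask_set` on the same grid and affine.
#' @return Named numeric vector of VOI means (one per VOI), with the volume's
#'   `subject_id` and `group` attached as attributes.
#' @export
extract_voi_means <- function(volume, masks) {
  stopifnot(inherits(volume, "brain_volume"), inherits(masks, "voi_mask_set"))
  # affine tolerance accommodates float32 NIfTI header round trips
  if (!identical(as.integer(dim(volume$data)), masks$shape) ||
      max(abs(volume$affine - masks$affine)) > 1e-4) {
    stop("volume and masks do not share grid and affine", call. = FALSE)
  }
  if (any(vapply(masks$indices, length, integer(1)) == 0L)) {
    stop("empty VOI mask", call. = FALSE)
  }
  out <- vapply(masks$indices, function(idx) mean(volume$data[idx]), numeric(1))
  attr(out, "subject_id") <- volume$subject_id
  attr(out, "group") <- volume$group
  out
}

#' Reduce a list of volumes to a cohort uptake table
#'
#' Applies, per subject, the preprocessing chain smooth (optional) ->
#' normalize -> extract, and stacks the results into a cohort table. Errors in
#' individual subjects are re-signalled with the subject id attached.
#'
#' @param volumes List of [brain_volume()] objects with subject ids and group
#'   labels set.
#' @param masks A `voi_mask_set` shared by all volumes.
#' @param smooth_fwhm Smoothing kernel FWHM in mm; 0 (default) disables
#'   smoothing, for inputs that are already smoothed.
#' @param normalize Normalize by brain mean before extraction (default TRUE).
#' @param brain_mask Mask passed to [normalize_by_brain_mean()].
#' @return A `cohort_table` data frame: `subject_id`, `group`, then one column
#'   per VOI abbreviation.
#' @export
build_cohort_table <- function(volumes, masks, smooth_fwhm = 0,
                               normalize = TRUE, brain_mask = "auto") {
  stopifnot(is.list(volumes), length(volumes) >= 1L)
  rows <- lapply(volumes, function(v) {
    tryCatch({
      if (smooth_fwhm > 0) v <- gaussian_smooth(v, smooth_fwhm)
      if (normalize) v <- normalize_by_brain_mean(v, brain_mask)
      extract_voi_means(v, masks)
    }, error = function(e) {
      stop("subject '", v$subject_id, "': ", conditionMessage(e),
           call. = FALSE)
    })
  })
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- names(masks$indices)
  out <- cbind(
    data.frame(
      subject_id = vapply(volumes, `[[`, character(1), "subject_id"),
      group = vapply(volumes, `[[`, character(1), "group"),
      stringsAsFactors = FALSE
    ),
    tab
  )
  as_cohort_table(out)
}

#' Coerce and validate a cohort uptake table
#'
#' A cohort table is the pipeline's central tabular container: one row per
#' subject with `subject_id`, `group`, and one finite numeric uptake column
#' per VOI.
#'
#' @param x Data frame with `subject_id` and `group` columns followed by VOI
#'   uptake columns.
#' @return `x` classed as `cohort_table`.
#' @export
as_cohort_table <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group") %in% names(x))) {
    stop("cohort table needs 'subject_id' and 'group' columns", call. = FALSE)
  }
  vois <- setdiff(names(x), c("subject_id", "group", "age", "sex"))
  if (!length(vois)) stop("cohort table has no VOI columns", call. = FALSE)
  vals <- as.matrix(x[, vois, drop = FALSE])
  if (!is.numeric(vals) || !all(is.finite(vals))) {
    stop("VOI uptake values must be finite numbers", call. = FALSE)
  }
  rownames(x) <- NULL
  class(x) <- unique(c("cohort_table", class(x)))
  attr(x, "voi_names") <- vois
  x
}

#' Names of the VOI uptake columns of a cohort table
#' @param cohort A `cohort_table`.
#' @return Character vector of VOI column names.
#' @export
voi_columns <- function(cohort) {
  attr(as_cohort_table(cohort), "voi_names")
}

#' Read / write a cohort uptake table as TSV
#'
#' The TSV schema (`subject_id`, `group`, one column per VOI abbreviation,
#' optional `age`/`sex` demographics) is both the output of the imaging path
#' and the direct-input format that bypasses imaging entirely.
#'
#' @param path TSV file path.
#' @return `read_cohort_table()` returns a `cohort_table`.
#' @export
read_cohort_table <- function(path) {
  as_cohort_table(utils::read.delim(path, stringsAsFactors = FALSE,
                                    check.names = FALSE))
}

#' @rdname read_cohort_table
#' @param cohort A `cohort_table`.
#' @export
write_cohort_table <- function(cohort, path) {
  cohort <- as_cohort_table(cohort)
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Split a cohort table by group label, preserving row order within groups.
split_cohort <- function(cohort) {
  cohort <- as_cohort_table(cohort)
  split(cohort, factor(cohort$group, levels = unique(cohort$group)))
}

# VOI uptake values as a subjects x VOIs numeric matrix.
uptake_matrix <- function(cohort) {
  cohort <- as_cohort_table(cohort)
  m <- as.matrix(cohort[, attr(cohort, "voi_names"), drop = FALSE])
  rownames(m) <- cohort$subject_id
  m
}
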