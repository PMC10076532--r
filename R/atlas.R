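# VOI atlas: the 14 default-mode-network volumes of interest and their voxel
# masks on an arbitrary MNI-space image grid.

#' Load the packaged 14-region DMN atlas
#'
#' Returns the default-mode-network volume-of-interest (VOI) table shipped
#' with the package: 14 AAL-derived regions (medial superior frontal,
#' medial-orbital superior frontal, posterior cingulate, hippocampus,
#' inferior parietal, angular gyrus and precuneus, each bilaterally), with
#' the MNI-space millimetre coordinate of each region's central voxel.
#'
#' @return A `voi_atlas` data frame with columns `index`, `name`,
#'   `abbreviation`, `hemisphere` (`"left"`/`"right"`), and the MNI centre
#'   coordinates `x`, `y`, `z` in millimetres.
#' @examples
#' atlas <- load_default_atlas()
#' atlas[atlas$abbreviation == "PCG.L", c("x", "y", "z")]
#' @export
load_default_atlas <- function() {
  path <- system.file("extdata", "dmn_voi_atlas.tsv", package = "metconn",
                      mustWork = TRUE)
  atlas <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_voi_atlas(atlas)
}

#' Validate a VOI atlas table
#'
#' Checks the structural invariants a VOI table must satisfy before it can be
#' used for mask building: required columns, unique abbreviations, hemisphere
#' labels consistent with the sign of the x coordinate.
#'
#' @param atlas A data frame with columns `index`, `name`, `abbreviation`,
#'   `hemisphere`, `x`, `y`, `z`.
#' @return The atlas, classed as `voi_atlas`, invisibly usable downstream.
#' @export
validate_voi_atlas <- function(atlas) {
  need <- c("index", "name", "abbreviation", "hemisphere", "x", "y", "z")
  miss <- setdiff(need, names(atlas))
  if (length(miss)) {
    stop("atlas is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(atlas$abbreviation)) {
    stop("VOI abbreviations must be unique", call. = FALSE)
  }
  if (!all(atlas$hemisphere %in% c("left", "right"))) {
    stop("hemisphere must be 'left' or 'right'", call. = FALSE)
  }
  if (any(atlas$x[atlas$hemisphere == "left"] > 0) ||
      any(atlas$x[atlas$hemisphere == "right"] < 0)) {
    stop("hemisphere labels inconsistent with the sign of x", call. = FALSE)
  }
  if (!all(is.finite(as.matrix(atlas[, c("x", "y", "z")])))) {
    stop("VOI centres must be finite", call. = FALSE)
  }
  class(atlas) <- c("voi_atlas", "data.frame")
  atlas
}

#' Build spherical VOI masks on an image grid
#'
#' Stand-in for full AAL parcel extents (which are not distributed with the
#' package): each VOI becomes the set of voxels whose world-space centre lies
#' within `radius_mm` of the VOI's MNI centre. Masks may overlap; overlap is
#' reported in the returned object, not forbidden. If a VOI centre lies inside
#' the grid but the sphere captures no voxel centre (very coarse grids), the
#' single nearest voxel is included so that no VOI is silently empty.
#'
#' @param atlas A `voi_atlas` table (see [load_default_atlas()]).
#' @param affine 4x4 voxel-to-world affine (0-based voxel indices).
#' @param shape Integer grid dimensions, length 3.
#' @param radius_mm Sphere radius in millimetres (> 0); default 6.
#' @return A `voi_mask_set`: list with `indices` (named list of 1-based linear
#'   voxel indices per VOI), `shape`, `affine`, `radius_mm`, `n_overlap`
#'   (count of voxels claimed by more than one VOI).
#' @export
build_sphere_masks <- function(atlas, affine, shape, radius_mm = 6) {
  atlas <- validate_voi_atlas(as.data.frame(atlas))
  check_affine(affine)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  if (!is.numeric(radius_mm) || length(radius_mm) != 1L || radius_mm <= 0) {
    stop("radius_mm must be a single positive number", call. = FALSE)
  }

  centers <- as.matrix(atlas[, c("x", "y", "z")])
  vox_centers <- world_to_voxel(affine, centers)
  inside <- vox_centers >= -0.5 & vox_centers <= rep(shape - 0.5, each = nrow(vox_centers))
  if (!all(inside)) {
    bad <- atlas$abbreviation[rowSums(inside) < 3L]
    stop("VOI centre(s) outside the image grid (wrong space/orientation?): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  indices <- vector("list", nrow(atlas))
  names(indices) <- atlas$abbreviation
  for (k in seq_len(nrow(atlas))) {
    indices[[k]] <- sphere_voxels(centers[k, ], affine, shape, radius_mm)
  }
  all_idx <- unlist(indices, use.names = FALSE)
  structure(
    list(indices = indices, shape = shape, affine = affine,
         radius_mm = radius_mm, source = "sphere",
         n_overlap = sum(duplicated(all_idx))),
    class = "voi_mask_set"
  )
}

# Enumerate 1-based linear indices of voxels whose centre is within radius of
# a world point. Scans only the bounding box of the sphere in voxel space.
sphere_voxels <- function(center, affine, shape, radius_mm) {
  corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) * radius_mm
  corners <- sweep(corners, 2L, center, "+")
  vox <- world_to_voxel(affine, corners)
  lo <- pmax(floor(apply(vox, 2L, min)), 0)
  hi <- pmin(ceiling(apply(vox, 2L, max)), shape - 1L)
  grid <- as.matrix(expand.grid(seq(lo[1], hi[1]), seq(lo[2], hi[2]),
                                seq(lo[3], hi[3])))
  world <- voxel_to_world(affine, grid)
  d2 <- (world[, 1] - center[1])^2 + (world[, 2] - center[2])^2 +
    (world[, 3] - center[3])^2
  keep <- d2 <= radius_mm^2
  if (!any(keep)) keep <- d2 == min(d2)  # nearest-voxel fallback
  sel <- grid[keep, , drop = FALSE]
  sort(as.integer(1L + sel[, 1] + shape[1] * (sel[, 2] + shape[2] * sel[, 3])))
}

#' Build VOI masks from an integer label image
#'
#' The faithful alternative to sphere masks when a parcellation volume (e.g.
#' an AAL label image resampled to the data grid) is available: each VOI mask
#' is the set of voxels carrying that VOI's label value. Masks from a label
#' image are disjoint by construction.
#'
#' @param label_image Integer-valued 3-D array of parcel labels.
#' @param affine 4x4 voxel-to-world affine of the label image.
#' @param label_map Named integer vector mapping VOI abbreviation to label
#'   value, e.g. `c(PCG.L = 35, ...)`, or the path of a JSON file holding such
#'   a map.
#' @return A `voi_mask_set` (see [build_sphere_masks()]).
#' @export
load_label_masks <- function(label_image, affine, label_map) {
  check_affine(affine)
  if (is.character(label_map) && length(label_map) == 1L) {
    label_map <- unlist(jsonlite::read_json(label_map, simplifyVector = TRUE))
  }
  if (is.null(names(label_map)) || any(!nzchar(names(label_map)))) {
    stop("label_map must be a named abbreviation -> label vector", call. = FALSE)
  }
  dims <- dim(label_image)
  if (length(dims) != 3L) stop("label_image must be 3-D", call. = FALSE)
  indices <- lapply(label_map, function(v) {
    idx <- which(label_image == v)
    if (!length(idx)) {
      stop("label value ", v, " absent from the label image", call. = FALSE)
    }
    as.integer(idx)
  })
  structure(
    list(indices = indices, shape = as.integer(dims), affine = affine,
         radius_mm = NA_real_, source = "label_image", n_overlap = 0L),
    class = "voi_mask_set"
  )
}

#' @export
print.voi_mask_set <- function(x, ...) {
  cat(sprintf("<voi_mask_set> %d VOIs on a %s grid (%s)\n",
              length(x$indices), paste(x$shape, collapse = "x"), x$source))
  sizes <- vapply(x$indices, length, integer(1))
  cat(sprintf("  voxels per VOI: %d-%d; overlapping voxels: %d\n",
              min(sizes), max(sizes), x$n_overlap))
  invisible(x)
}

# World-space centroid of each mask (n x 3 matrix), used for QC and tests.
mask_centroids <- function(masks) {
  out <- t(vapply(masks$indices, function(idx) {
    arr <- arrayInd(idx, masks$shape) - 1L
    colMeans(voxel_to_world(masks$affine, arr))
  }, numeric(3)))
  colnames(out) <- c("x", "y", "z")
  out
}
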