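# Minimal NIfTI-1 (.nii, .nii.gz) and Analyze 7.5 (.hdr/.img) volume IO.
# Scope: 3-D scalar volumes, little/big endian, the common numeric datatypes,
# scl_slope/scl_inter scaling, sform > qform > pixdim affine precedence.

#' Construct a brain volume object
#'
#' @param data 3-D numeric array of voxel values (all finite).
#' @param affine 4x4 voxel-to-world affine; voxel indices are 0-based.
#' @param subject_id Subject identifier.
#' @param group Group label, conventionally `"patient"` or `"control"`.
#' @return A `brain_volume` object.
#' @export
brain_volume <- function(data, affine, subject_id = NA_character_,
                         group = NA_character_) {
  if (length(dim(data)) != 3L) {
    stop("volume data must have 3 spatial dimensions", call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("volume contains non-finite voxel values", call. = FALSE)
  }
  check_affine(affine)
  structure(list(data = data, affine = affine,
                 subject_id = as.character(subject_id),
                 group = as.character(group)),
            class = "brain_volume")
}

#' @export
print.brain_volume <- function(x, ...) {
  cat(sprintf("<brain_volume> %s [%s] %s, voxels %.3g..%.3g, voxel size %s mm\n",
              x$subject_id, x$group, paste(dim(x$data), collapse = "x"),
              min(x$data), max(x$data),
              paste(signif(voxel_sizes(x$affine), 4), collapse = "x")))
  invisible(x)
}

# NIfTI datatype codes -> readBin arguments.
.nifti_dtypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "double",  size = 4L, signed = TRUE),
  `64`  = list(what = "double",  size = 8L, signed = TRUE),
  `256` = list(what = "integer", size = 1L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

.read_raw_header <- function(path) {
  con <- gzfile(path, "rb")  # transparently handles uncompressed files too
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated header in ", path, call. = FALSE)
  hdr
}

.hdr_field <- function(hdr, offset, what, n, size, endian, signed = TRUE) {
  readBin(hdr[(offset + 1L):(offset + n * size)], what, n = n, size = size,
          endian = endian, signed = signed)
}

.parse_header <- function(hdr) {
  endian <- "little"
  if (.hdr_field(hdr, 0L, "integer", 1L, 4L, endian) != 348L) {
    endian <- "big"
    if (.hdr_field(hdr, 0L, "integer", 1L, 4L, endian) != 348L) {
      stop("not a NIfTI-1/Analyze header (sizeof_hdr != 348)", call. = FALSE)
    }
  }
  magic <- rawToChar(hdr[345:347])
  list(
    endian = endian,
    magic = if (magic %in% c("n+1", "ni1")) magic else "",
    dim = .hdr_field(hdr, 40L, "integer", 8L, 2L, endian),
    datatype = .hdr_field(hdr, 70L, "integer", 1L, 2L, endian),
    pixdim = .hdr_field(hdr, 76L, "double", 8L, 4L, endian),
    vox_offset = .hdr_field(hdr, 108L, "double", 1L, 4L, endian),
    scl_slope = .hdr_field(hdr, 112L, "double", 1L, 4L, endian),
    scl_inter = .hdr_field(hdr, 116L, "double", 1L, 4L, endian),
    qform_code = .hdr_field(hdr, 252L, "integer", 1L, 2L, endian),
    sform_code = .hdr_field(hdr, 254L, "integer", 1L, 2L, endian),
    quatern = .hdr_field(hdr, 256L, "double", 6L, 4L, endian),
    srow = matrix(.hdr_field(hdr, 280L, "double", 12L, 4L, endian),
                  nrow = 3L, byrow = TRUE),
    # Analyze 7.5 'originator': 1-based voxel index of the world origin (SPM).
    originator = .hdr_field(hdr, 253L, "integer", 5L, 2L, endian)
  )
}

.affine_from_header <- function(h) {
  if (nzchar(h$magic) && h$sform_code > 0L) {
    return(rbind(h$srow, c(0, 0, 0, 1)))
  }
  if (nzchar(h$magic) && h$qform_code > 0L) {
    b <- h$quatern[1]; c_ <- h$quatern[2]; d <- h$quatern[3]
    a <- sqrt(max(0, 1 - b^2 - c_^2 - d^2))
    R <- matrix(c(
      a*a + b*b - c_*c_ - d*d, 2*(b*c_ - a*d),          2*(b*d + a*c_),
      2*(b*c_ + a*d),          a*a + c_*c_ - b*b - d*d, 2*(c_*d - a*b),
      2*(b*d - a*c_),          2*(c_*d + a*b),          a*a + d*d - b*b - c_*c_
    ), nrow = 3L, byrow = TRUE)
    qfac <- if (h$pixdim[1] < 0) -1 else 1
    R <- R %*% diag(c(h$pixdim[2:3], qfac * h$pixdim[4]))
    return(rbind(cbind(R, h$quatern[4:6]), c(0, 0, 0, 1)))
  }
  # Analyze: diagonal pixdim affine; SPM originator convention if present.
  pd <- abs(h$pixdim[2:4])
  pd[pd == 0] <- 1
  origin <- h$originator[1:3]
  if (all(origin == 0L)) origin <- c(1L, 1L, 1L)
  aff <- diag(c(pd, 1))
  aff[1:3, 4] <- -(origin - 1) * pd
  aff
}

#' Read a NIfTI-1 or Analyze 7.5 brain volume
#'
#' Reads `.nii`, `.nii.gz`, or an Analyze/NIfTI `.hdr`/`.img` pair. The
#' voxel-to-world affine is taken from the sform when set, else the qform,
#' else a diagonal `pixdim` affine (Analyze; the SPM `originator` field sets
#' the origin when present). Analyze files carry no definitive orientation:
#' use `flip` to mirror stated axes explicitly rather than relying on a
#' guessed orientation.
#'
#' @param path File path (`.nii`, `.nii.gz`, `.hdr` or `.img`).
#' @param subject_id,group Metadata attached to the returned volume.
#' @param flip Logical length-3: mirror the corresponding axis (data reversed
#'   and affine updated so world coordinates are preserved).
#' @return A [brain_volume()].
#' @export
read_brain_volume <- function(path, subject_id = NA_character_,
                              group = NA_character_,
                              flip = c(FALSE, FALSE, FALSE)) {
  if (!file.exists(path)) {
    alt <- sub("\\.img$", ".hdr", path)
    if (!file.exists(alt)) stop("file not found: ", path, call. = FALSE)
    path <- alt
  }
  is_pair <- grepl("\\.(hdr|img)$", path)
  hdr_path <- if (grepl("\\.img$", path)) sub("\\.img$", ".hdr", path) else path
  h <- .parse_header(.read_raw_header(hdr_path))
  if (is_pair && identical(h$magic, "n+1")) {
    stop("single-file NIfTI magic in a .hdr; corrupt pair?", call. = FALSE)
  }

  nd <- h$dim[1]
  if (nd < 3L || any(h$dim[2:4] < 1L)) {
    stop("expected a 3-D volume, got dim = ",
         paste(h$dim, collapse = ","), call. = FALSE)
  }
  if (nd > 3L && any(h$dim[5:(nd + 1L)] > 1L)) {
    stop("4-D+ volumes are out of scope; split time points first", call. = FALSE)
  }
  shape <- h$dim[2:4]
  dt <- .nifti_dtypes[[as.character(h$datatype)]]
  if (is.null(dt)) stop("unsupported datatype code ", h$datatype, call. = FALSE)

  if (is_pair || identical(h$magic, "ni1")) {
    data_path <- sub("\\.hdr$", ".img", hdr_path)
    offset <- 0L
  } else {
    data_path <- path
    offset <- as.integer(round(max(h$vox_offset, 348)))
  }
  con <- gzfile(data_path, "rb")
  on.exit(close(con))
  if (offset > 0L) readBin(con, "raw", n = offset)
  n_vox <- prod(shape)
  vals <- readBin(con, dt$what, n = n_vox, size = dt$size,
                  endian = h$endian, signed = dt$signed)
  if (length(vals) < n_vox) stop("truncated image data in ", data_path,
                                 call. = FALSE)
  vals <- as.double(vals)
  if (is.finite(h$scl_slope) && h$scl_slope != 0 &&
      !(h$scl_slope == 1 && h$scl_inter == 0)) {
    vals <- vals * h$scl_slope + h$scl_inter
  }
  arr <- array(vals, dim = shape)
  affine <- .affine_from_header(h)

  flip <- as.logical(flip)
  for (ax in which(flip)) {
    idx <- rep(list(quote(expr = )), 3L)
    idx[[ax]] <- rev(seq_len(shape[ax]))
    arr <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
    affine[, 4] <- affine[, 4] + affine[, ax] * (shape[ax] - 1L)
    affine[, ax] <- -affine[, ax]
  }
  brain_volume(arr, affine, subject_id = subject_id, group = group)
}

#' Write a brain volume as NIfTI-1 or Analyze
#'
#' `.nii`/`.nii.gz` writes a single-file NIfTI-1 (float64, sform set from the
#' volume's affine). `.hdr`/`.img` writes an Analyze 7.5 pair; only diagonal
#' affines can be represented there (the SPM originator encodes the origin),
#' so non-diagonal affines are rejected.
#'
#' @param volume A [brain_volume()].
#' @param path Output path ending in `.nii`, `.nii.gz`, `.hdr` or `.img`.
#' @return `path`, invisibly.
#' @export
write_brain_volume <- function(volume, path) {
  stopifnot(inherits(volume, "brain_volume"))
  shape <- dim(volume$data)
  pd <- voxel_sizes(volume$affine)
  hdr <- raw(348L)
  put <- function(hdr, offset, values, size) {
    b <- writeBin(values, raw(), size = size, endian = "little")
    hdr[(offset + 1L):(offset + length(b))] <- b
    hdr
  }
  hdr <- put(hdr, 0L, 348L, 4L)
  hdr <- put(hdr, 40L, as.integer(c(3L, shape, 1L, 1L, 1L, 1L)), 2L)
  hdr <- put(hdr, 70L, 64L, 2L)                       # float64
  hdr <- put(hdr, 72L, 64L, 2L)
  hdr <- put(hdr, 76L, c(1, pd, 0, 0, 0, 0), 4L)
  hdr <- put(hdr, 112L, c(1, 0), 4L)                  # scl_slope/inter

  if (grepl("\\.(hdr|img)$", path)) {
    offdiag <- volume$affine[1:3, 1:3]; diag(offdiag) <- 0
    if (any(offdiag != 0)) {
      stop("Analyze output supports diagonal affines only; write NIfTI instead",
           call. = FALSE)
    }
    origin <- round(1 - volume$affine[1:3, 4] / pd)
    hdr <- put(hdr, 253L, as.integer(c(origin, 0L, 0L)), 2L)
    hdr_path <- sub("\\.img$", ".hdr", path)
    img_path <- sub("\\.hdr$", ".img", path)
    writeBin(hdr, hdr_path)
    con <- file(img_path, "wb")
    on.exit(close(con))
    writeBin(as.double(volume$data), con, size = 8L, endian = "little")
    return(invisible(path))
  }

  hdr <- put(hdr, 108L, 352, 4L)                      # vox_offset
  hdr <- put(hdr, 254L, 2L, 2L)                       # sform_code = aligned
  hdr <- put(hdr, 280L, as.double(t(volume$affine[1:3, ])), 4L)
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0L))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4L), con)                              # no extensions
  writeBin(as.double(volume$data), con, size = 8L, endian = "little")
  invisible(path)
}
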