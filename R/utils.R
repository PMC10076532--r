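# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a temporary RNG state seeded with `seed`; NULL seed leaves
# the global RNG alone. Restores .Random.seed afterwards so library calls do
# not perturb user-level reproducibility.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Map a 0-based voxel index matrix (n x 3) to world mm through a 4x4 affine.
voxel_to_world <- function(affine, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  out <- cbind(ijk, 1) %*% t(affine)
  out[, 1:3, drop = FALSE]
}

# Inverse mapping: world mm -> continuous 0-based voxel coordinates.
world_to_voxel <- function(affine, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  inv <- tryCatch(solve(affine), error = function(e)
    stop("affine is not invertible", call. = FALSE))
  out <- cbind(xyz, 1) %*% t(inv)
  out[, 1:3, drop = FALSE]
}

# Per-axis voxel edge length in mm implied by an affine.
voxel_sizes <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

check_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)) ||
      !all(is.finite(affine))) {
    stop("affine must be a finite 4x4 matrix", call. = FALSE)
  }
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps) {
    stop("affine is not invertible", call. = FALSE)
  }
  invisible(affine)
}

# Pearson correlation of the columns of X via crossprod; clamps rounding
# spill-over so |r| <= 1 exactly. Errors on zero-variance columns because the
# coefficient is undefined there.
fast_cor <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 3L) stop("need at least 3 rows to correlate", call. = FALSE)
  Xc <- sweep(X, 2L, colMeans(X), "-")
  s <- sqrt(colSums(Xc * Xc))
  if (any(s <= 0)) {
    bad <- colnames(X)[s <= 0] %||% which(s <= 0)
    stop("zero-variance column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  R <- crossprod(Xc) / tcrossprod(s)
  R[R > 1] <- 1
  R[R < -1] <- -1
  diag(R) <- 1
  R
}

# Upper-triangle linear indices and the matching (i, j) pairs for a p x p
# symmetric matrix; the canonical edge ordering used across the package.
upper_tri_index <- function(p) {
  idx <- which(upper.tri(matrix(0, p, p)))
  arr <- arrayInd(idx, c(p, p))
  list(linear = idx, i = arr[, 1L], j = arr[, 2L])
}

edge_labels <- function(voi_names) {
  ut <- upper_tri_index(length(voi_names))
  paste(voi_names[ut$i], "-", voi_names[ut$j])
}
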