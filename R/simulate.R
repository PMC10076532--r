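# Synthetic cohort generator: multivariate-normal VOI uptake with planted
# edge effects, plus an optional voxel-volume renderer so the imaging path
# can be exercised end to end without external data.

#' Default base correlation matrix for simulated cohorts
#'
#' Exchangeable structure mimicking a connected DMN-like covariance:
#' off-diagonal 0.5 everywhere plus a +0.2 within-hemisphere bonus. The
#' matrix is positive definite by construction (sum of scaled all-ones
#' blocks plus a ridge).
#'
#' @param atlas A `voi_atlas`; defaults to the packaged 14-region atlas.
#' @return Correlation matrix with VOI abbreviations as dimnames.
#' @export
default_base_correlation <- function(atlas = load_default_atlas()) {
  atlas <- validate_voi_atlas(as.data.frame(atlas))
  p <- nrow(atlas)
  same_hemi <- outer(atlas$hemisphere, atlas$hemisphere, "==")
  R <- matrix(0.5, p, p) + 0.2 * same_hemi
  diag(R) <- 1
  dimnames(R) <- list(atlas$abbreviation, atlas$abbreviation)
  R
}

#' Specify a two-cohort simulation
#'
#' The stated world of the simulator: group a ("patient") and group b
#' ("control") both draw 14-dimensional uptake vectors from multivariate
#' normals sharing `base_correlation`, except that `planted_edges` adds
#' `delta_r` to the named correlations of group a only. Defaults mirror the
#' study design the pipeline targets: 40 patients vs 41 controls, normalized
#' uptake around 1.2 with between-subject SD 0.12, and small additive
#' measurement noise (SD 0.02).
#'
#' @param n_a,n_b Group sizes (>= 3; defaults 40 and 41).
#' @param base_correlation Target correlation matrix for the control-like
#'   group; default [default_base_correlation()].
#' @param planted_edges `NULL`, or a data frame with columns `voi_i`, `voi_j`
#'   (abbreviations or indices) and `delta_r`, applied to group a.
#' @param uptake_mean,uptake_sd Per-VOI mean and SD of uptake (recycled to
#'   atlas length).
#' @param noise_sd SD of independent additive measurement noise.
#' @param seed Integer seed.
#' @param atlas A `voi_atlas` fixing names and dimension.
#' @return A validated `simulation_spec`.
#' @export
simulation_spec <- function(n_a = 40, n_b = 41,
                            base_correlation = NULL, planted_edges = NULL,
                            uptake_mean = 1.2, uptake_sd = 0.12,
                            noise_sd = 0.02, seed = NULL,
                            atlas = load_default_atlas()) {
  atlas <- validate_voi_atlas(as.data.frame(atlas))
  p <- nrow(atlas)
  if (is.null(base_correlation)) {
    base_correlation <- default_base_correlation(atlas)
  }
  base_correlation <- as.matrix(base_correlation)
  if (!all(dim(base_correlation) == p)) {
    stop("base_correlation must be ", p, "x", p, call. = FALSE)
  }
  if (max(abs(base_correlation - t(base_correlation))) > 1e-12 ||
      any(abs(diag(base_correlation) - 1) > 1e-12) ||
      any(abs(base_correlation) > 1)) {
    stop("base_correlation must be symmetric with unit diagonal and |r| <= 1",
         call. = FALSE)
  }
  if (n_a < 3 || n_b < 3) stop("group sizes must be >= 3", call. = FALSE)
  if (!is.null(planted_edges)) {
    planted_edges <- as.data.frame(planted_edges)
    need <- c("voi_i", "voi_j", "delta_r")
    if (!all(need %in% names(planted_edges))) {
      stop("planted_edges needs columns voi_i, voi_j, delta_r", call. = FALSE)
    }
    to_idx <- function(v) {
      if (is.numeric(v)) return(as.integer(v))
      i <- match(v, atlas$abbreviation)
      if (anyNA(i)) stop("unknown VOI in planted_edges: ",
                         paste(v[is.na(i)], collapse = ", "), call. = FALSE)
      i
    }
    planted_edges$voi_i <- to_idx(planted_edges$voi_i)
    planted_edges$voi_j <- to_idx(planted_edges$voi_j)
    if (any(planted_edges$voi_i == planted_edges$voi_j)) {
      stop("planted_edges: voi_i must differ from voi_j", call. = FALSE)
    }
    tgt <- base_correlation[cbind(planted_edges$voi_i, planted_edges$voi_j)] +
      planted_edges$delta_r
    if (any(abs(tgt) >= 1)) {
      stop("planted_edges: delta_r pushes a correlation outside (-1, 1)",
           call. = FALSE)
    }
  }
  uptake_mean <- rep_len(as.numeric(uptake_mean), p)
  uptake_sd <- rep_len(as.numeric(uptake_sd), p)
  if (any(uptake_sd <= 0) || noise_sd < 0) {
    stop("uptake_sd must be positive and noise_sd non-negative", call. = FALSE)
  }
  structure(
    list(n_a = as.integer(n_a), n_b = as.integer(n_b),
         base_correlation = base_correlation, planted_edges = planted_edges,
         uptake_mean = uptake_mean, uptake_sd = uptake_sd,
         noise_sd = as.numeric(noise_sd), seed = seed, atlas = atlas),
    class = "simulation_spec"
  )
}

#' Repair a symmetric matrix to the nearest correlation matrix
#'
#' Higham-style alternating projection (via [Matrix::nearPD()] with
#' `corr = TRUE`) onto the set of symmetric positive semidefinite matrices
#' with unit diagonal. Planted edge edits can break positive
#' semidefiniteness; repair makes the target sampleable and reports how far
#' it moved.
#'
#' @param R Symmetric matrix with unit diagonal.
#' @param tol Convergence tolerance (default 1e-8).
#' @return The repaired matrix, with attribute `"repair_distance"` (max
#'   absolute elementwise change; 0 when `R` was already valid).
#' @export
nearest_correlation <- function(R, tol = 1e-8) {
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= -tol) {
    attr(R, "repair_distance") <- 0
    return(R)
  }
  fixed <- tryCatch(
    as.matrix(Matrix::nearPD(R, corr = TRUE, conv.tol = tol,
                             posd.tol = 1e-10)$mat),
    error = function(e) stop("nearest-correlation repair failed: ",
                             conditionMessage(e), call. = FALSE)
  )
  ev2 <- eigen(fixed, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev2) < -1e-6) {
    stop("repair did not reach a positive semidefinite matrix", call. = FALSE)
  }
  dimnames(fixed) <- dimnames(R)
  attr(fixed, "repair_distance") <- max(abs(fixed - R))
  fixed
}

# Sample n rows from N(0, Sigma) via Cholesky (with a tiny ridge fallback for
# semidefinite repaired matrices).
.rmvnorm <- function(n, Sigma) {
  ch <- tryCatch(chol(Sigma),
                 error = function(e) chol(Sigma + 1e-10 * diag(nrow(Sigma))))
  matrix(stats::rnorm(n * nrow(Sigma)), n) %*% ch
}

#' Generate a pair of synthetic cohorts
#'
#' Draws each subject's VOI vector from the group's (repaired) multivariate
#' normal, scales by `uptake_sd`, shifts by `uptake_mean`, and adds
#' independent Gaussian measurement noise. Reproducible given `spec$seed`.
#'
#' @param spec A [simulation_spec()].
#' @return List with `cohort_a`, `cohort_b` (cohort tables, groups
#'   `"patient"`/`"control"`) and `ground_truth` (the exact correlation
#'   matrices sampled from, their noise-attenuated observable counterparts,
#'   the planted edge list, and repair distances).
#' @export
generate_cohorts <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  atlas <- spec$atlas
  p <- nrow(atlas)
  Sigma_b <- nearest_correlation(spec$base_correlation)
  Ra <- spec$base_correlation
  if (!is.null(spec$planted_edges)) {
    ii <- spec$planted_edges$voi_i
    jj <- spec$planted_edges$voi_j
    Ra[cbind(ii, jj)] <- Ra[cbind(ii, jj)] + spec$planted_edges$delta_r
    Ra[cbind(jj, ii)] <- Ra[cbind(ii, jj)]
  }
  Sigma_a <- nearest_correlation(Ra)

  # Independent additive noise attenuates observable correlations uniformly.
  atten <- outer(spec$uptake_sd, spec$uptake_sd) /
    outer(sqrt(spec$uptake_sd^2 + spec$noise_sd^2),
          sqrt(spec$uptake_sd^2 + spec$noise_sd^2))
  observable <- function(S) {
    O <- S * atten
    diag(O) <- 1
    O
  }

  draw <- function(n, Sigma, group, prefix) {
    X <- .rmvnorm(n, Sigma)
    X <- sweep(X, 2L, spec$uptake_sd, "*")
    X <- sweep(X, 2L, spec$uptake_mean, "+")
    if (spec$noise_sd > 0) {
      X <- X + matrix(stats::rnorm(n * p, sd = spec$noise_sd), n)
    }
    colnames(X) <- atlas$abbreviation
    as_cohort_table(cbind(
      data.frame(subject_id = sprintf("%s%03d", prefix, seq_len(n)),
                 group = group, stringsAsFactors = FALSE),
      as.data.frame(X)
    ))
  }
  out <- with_seed(spec$seed, {
    list(cohort_a = draw(spec$n_a, Sigma_a, "patient", "pat"),
         cohort_b = draw(spec$n_b, Sigma_b, "control", "con"))
  })
  out$ground_truth <- list(
    Sigma_a = Sigma_a, Sigma_b = Sigma_b,
    observable_a = observable(Sigma_a), observable_b = observable(Sigma_b),
    planted_edges = spec$planted_edges,
    repair_distance_a = attr(Sigma_a, "repair_distance"),
    repair_distance_b = attr(Sigma_b, "repair_distance"),
    seed = spec$seed
  )
  out
}

#' Render a cohort's uptake into voxel volumes
#'
#' Each subject becomes a 3-D volume: constant background inside a brain-like
#' ellipsoid, the subject's uptake value painted inside each VOI's sphere,
#' plus optional Gaussian voxel noise. Defaults echo a typical PET
#' reconstruction grid (128 x 128 x 35 voxels of 1.95 x 1.95 x 4.25 mm).
#' Spheres must not overlap (overlap would corrupt round-trip semantics).
#'
#' @param cohort A `cohort_table`.
#' @param atlas A `voi_atlas` matching the cohort's VOI columns.
#' @param shape,voxel_size Grid dimensions and voxel edge lengths (mm).
#' @param radius_mm VOI sphere radius (default 6).
#' @param background Background intensity inside the brain ellipsoid
#'   (default 0.5; outside the ellipsoid is 0).
#' @param noise_sd SD of additive Gaussian voxel noise (default 0).
#' @param seed Integer seed for the voxel noise.
#' @return List of [brain_volume()] objects, one per subject, with the
#'   `voi_mask_set` used attached as attribute `"masks"`.
#' @export
render_volumes <- function(cohort, atlas = load_default_atlas(),
                           shape = c(128L, 128L, 35L),
                           voxel_size = c(1.95, 1.95, 4.25),
                           radius_mm = 6, background = 0.5, noise_sd = 0,
                           seed = NULL) {
  cohort <- as_cohort_table(cohort)
  atlas <- validate_voi_atlas(as.data.frame(atlas))
  if (!identical(attr(cohort, "voi_names"), atlas$abbreviation)) {
    stop("cohort VOI columns do not match the atlas", call. = FALSE)
  }
  shape <- as.integer(shape)
  affine <- diag(c(voxel_size, 1))
  affine[1:3, 4] <- -(shape - 1) / 2 * voxel_size
  affine[3, 4] <- affine[3, 4] + 10   # shift axial FOV up toward the brain

  masks <- build_sphere_masks(atlas, affine, shape, radius_mm)
  if (masks$n_overlap > 0L) {
    stop("VOI spheres overlap on this grid (radius too large); ",
         "round-trip extraction would be corrupted", call. = FALSE)
  }

  # Brain-like ellipsoid containing all VOI spheres.
  grid <- as.matrix(expand.grid(seq_len(shape[1]) - 1L,
                                seq_len(shape[2]) - 1L,
                                seq_len(shape[3]) - 1L))
  world <- voxel_to_world(affine, grid)
  center <- c(0, -20, 12)
  semi <- c(75, 90, 60)
  inside <- ((world[, 1] - center[1]) / semi[1])^2 +
    ((world[, 2] - center[2]) / semi[2])^2 +
    ((world[, 3] - center[3]) / semi[3])^2 <= 1

  U <- uptake_matrix(cohort)
  with_seed(seed, {
    lapply(seq_len(nrow(cohort)), function(s) {
      vox <- numeric(prod(shape))
      vox[inside] <- background
      for (k in seq_along(masks$indices)) {
        vox[masks$indices[[k]]] <- U[s, k]
      }
      if (noise_sd > 0) {
        vox <- vox + stats::rnorm(length(vox), sd = noise_sd)
      }
      v <- brain_volume(array(vox, dim = shape), affine,
                        subject_id = cohort$subject_id[s],
                        group = cohort$group[s])
      attr(v, "masks") <- masks
      v
    })
  })
}
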