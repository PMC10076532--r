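test_that("simulation spec validates its inputs", {
  expect_s3_class(simulation_spec(), "simulation_spec")
  expect_error(simulation_spec(n_a = 2), ">= 3")
  expect_error(simulation_spec(uptake_sd = 0), "positive")
  expect_error(simulation_spec(
    planted_edges = data.frame(voi_i = "HIP.R", voi_j = "NOPE",
                               delta_r = 0.1)), "unknown VOI")
  expect_error(simulation_spec(
    planted_edges = data.frame(voi_i = "HIP.R", voi_j = "HIP.R",
                               delta_r = 0.1)), "differ")
  # delta pushing r out of (-1, 1) is rejected at spec time
  expect_error(simulation_spec(
    planted_edges = data.frame(voi_i = "HIP.R", voi_j = "PCG.L",
                               delta_r = 0.9)), "outside")
  bad <- default_base_correlation()
  bad[1, 2] <- 0.9   # asymmetric
  expect_error(simulation_spec(base_correlation = bad), "symmetric")
})

test_that("default base correlation is a valid, connected-looking matrix", {
  R <- default_base_correlation()
  expect_equal(R, t(R))
  expect_equal(unname(diag(R)), rep(1, 14))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  # within-hemisphere 0.7, across 0.5
  expect_equal(R["PCG.L", "HIP.L"], 0.7)
  expect_equal(R["PCG.L", "HIP.R"], 0.5)
})

test_that("nearest-correlation repair restores positive semidefiniteness", {
  R <- default_base_correlation()
  expect_equal(attr(nearest_correlation(R), "repair_distance"), 0)

  # an aggressive edit that breaks PSD: three mutually negative strong edges
  bad <- diag(3)
  bad[1, 2] <- bad[2, 1] <- -0.9
  bad[1, 3] <- bad[3, 1] <- -0.9
  bad[2, 3] <- bad[3, 2] <- -0.9
  ev <- eigen(bad, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(min(ev), 0)
  fixed <- nearest_correlation(bad)
  ev2 <- eigen(fixed, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev2), -1e-8)
  expect_equal(unname(diag(fixed)), rep(1, 3), tolerance = 1e-8)
  expect_gt(attr(fixed, "repair_distance"), 0)
})

test_that("cohort generation: shapes, determinism, group structure", {
  spec <- simulation_spec(seed = 123)
  sim <- generate_cohorts(spec)
  expect_identical(nrow(sim$cohort_a), 40L)
  expect_identical(nrow(sim$cohort_b), 41L)
  expect_identical(unique(sim$cohort_a$group), "patient")
  expect_identical(unique(sim$cohort_b$group), "control")
  expect_identical(ncol(sim$cohort_a), 16L)

  sim2 <- generate_cohorts(spec)
  expect_identical(sim, sim2)
  sim3 <- generate_cohorts(simulation_spec(seed = 124))
  expect_false(identical(sim$cohort_a, sim3$cohort_a))
})

test_that("planted edges shift only the targeted correlations (large n)", {
  spec <- simulation_spec(
    n_a = 2000, n_b = 2000, noise_sd = 0,
    planted_edges = data.frame(voi_i = "HIP.R", voi_j = "PCG.L",
                               delta_r = -0.35),
    seed = 321)
  sim <- generate_cohorts(spec)
  Ra <- intersubject_correlation(sim$cohort_a)$R
  Rb <- intersubject_correlation(sim$cohort_b)$R
  expect_lt(abs(Ra["HIP.R", "PCG.L"] - 0.15), 0.05)
  expect_lt(abs(Rb["HIP.R", "PCG.L"] - 0.5), 0.05)
  # an untouched edge stays put in both groups
  expect_lt(abs(Ra["ANG.L", "ANG.R"] - 0.5), 0.05)
  expect_lt(max(abs(Ra - sim$ground_truth$observable_a)), 0.05)
  expect_equal(sim$ground_truth$repair_distance_b, 0)
})

test_that("rendered volumes honour the grid contract and round trip", {
  cohort <- make_cohort(2, group = "patient", seed = 31)
  vols <- render_volumes(cohort, noise_sd = 0)
  expect_identical(dim(vols[[1]]$data), c(128L, 128L, 35L))
  expect_equal(metconn:::voxel_sizes(vols[[1]]$affine), c(1.95, 1.95, 4.25),
               tolerance = 1e-12)
  masks <- attr(vols[[1]], "masks")
  up <- extract_voi_means(vols[[2]], masks)
  expect_equal(unname(up),
               unname(unlist(cohort[2, voi_columns(cohort)])),
               tolerance = 1e-12, ignore_attr = TRUE)
  # overlapping spheres are refused
  expect_error(render_volumes(cohort, radius_mm = 20), "overlap")
})

test_that("noisy rendering recovers uptake within the standard-error bound", {
  cohort <- make_cohort(3, group = "control", seed = 41)
  noise_sd <- 0.05
  vols <- render_volumes(cohort, noise_sd = noise_sd, seed = 99)
  masks <- attr(vols[[1]], "masks")
  n_vox <- vapply(masks$indices, length, integer(1))
  truth <- metconn:::uptake_matrix(cohort)
  errs <- ok <- 0L
  for (s in 1:3) {
    up <- extract_voi_means(vols[[s]], masks)
    dev <- abs(up - truth[s, ])
    bound <- 3 * noise_sd / sqrt(n_vox)
    ok <- ok + sum(dev <= bound)
    errs <- errs + length(dev)
  }
  expect_gte(ok / errs, 0.97)   # 3-sigma bound holds for ~99% of VOI means
})

test_that("volumes written to NIfTI survive the full imaging round trip", {
  cohort <- make_cohort(2, group = "patient", seed = 51)
  vols <- render_volumes(cohort, noise_sd = 0)
  masks <- attr(vols[[1]], "masks")
  paths <- vapply(vols, function(v) {
    p <- tempfile(fileext = ".nii.gz")
    write_brain_volume(v, p)
    p
  }, character(1))
  back <- lapply(seq_along(paths), function(k) {
    read_brain_volume(paths[k], subject_id = cohort$subject_id[k],
                      group = cohort$group[k])
  })
  tab <- build_cohort_table(back, masks, normalize = FALSE)
  expect_equal(as.matrix(tab[, voi_columns(tab)]),
               metconn:::uptake_matrix(cohort), ignore_attr = TRUE,
               tolerance = 1e-10)
})
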