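test_that("BH step-up: worked examples, oracle, ordering invariance, errors", {
  # thresholds i*q/m equal the p-values exactly -> all significant
  res <- bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05), q = 0.05)
  expect_true(all(res$significant))

  res <- bh_fdr(rep(1, 10), q = 0.05)
  expect_false(any(res$significant))
  expect_equal(res$qvalues, rep(1, 10))

  res <- bh_fdr(0.04, q = 0.05)
  expect_true(res$significant)
  expect_equal(res$qvalues, 0.04)

  # p.adjust is the independent oracle
  set.seed(31)
  for (rep in 1:20) {
    p <- runif(50)^2
    expect_equal(bh_fdr(p)$qvalues, p.adjust(p, method = "BH"),
                 tolerance = 1e-12)
  }
  # flags invariant to input ordering
  p <- runif(30)
  ord <- sample(30)
  expect_identical(bh_fdr(p)$significant[ord], bh_fdr(p[ord])$significant)

  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("summary t-test reproduces the published demographics and raw data", {
  res <- two_sample_t_from_summary(34.93, 7.89, 40, 36.46, 7.42, 41)
  expect_equal(round(res$p_value, 2), 0.37)
  expect_equal(res$df, 79)

  expect_equal(two_sample_t_from_summary(5, 1, 10, 5, 1, 12)$statistic, 0)
  expect_equal(two_sample_t_from_summary(5, 1, 10, 5, 1, 12)$p_value, 1)

  # raw-data oracle: construct samples with exactly these summaries
  set.seed(13)
  mk <- function(n, m, s) {
    x <- rnorm(n)
    m + s * (x - mean(x)) / sd(x)
  }
  a <- mk(40, 34.93, 7.89); b <- mk(41, 36.46, 7.42)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  # Welch variant against t.test default
  wl <- two_sample_t_from_summary(34.93, 7.89, 40, 36.46, 7.42, 41,
                                  var_equal = FALSE)
  refw <- t.test(a, b)
  expect_equal(wl$p_value, refw$p.value, tolerance = 1e-10)

  expect_error(two_sample_t_from_summary(1, 1, 1, 2, 1, 10), "n >= 2")
  expect_error(two_sample_t_from_summary(1, 0, 5, 2, 1, 10), "positive")
})

test_that("2x2 chi-square reproduces the published gender comparison", {
  res <- chi_square_2x2(matrix(c(23, 25, 17, 16), 2))
  expect_equal(round(res$p_value, 2), 0.75)

  bal <- chi_square_2x2(matrix(c(20, 20, 20, 20), 2))
  expect_equal(bal$statistic, 0)
  expect_equal(bal$p_value, 1)

  # oracle: direct expected-count enumeration and chisq.test
  O <- matrix(c(23, 25, 17, 16), 2)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(res$statistic, sum((O - E)^2 / E), tolerance = 1e-12)
  ref <- chisq.test(O, correct = FALSE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)

  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2)), "marginal")
})

test_that("edgewise permutation test: identical cohorts, determinism, bounds", {
  cohort <- make_cohort(10, group = "patient", seed = 41)
  twin <- cohort
  twin$group <- "control"
  res <- edgewise_permutation_test(cohort, twin, n_permutations = 200, seed = 1)
  expect_equal(res$table$delta, rep(0, 91))
  expect_equal(res$table$p, rep(1, 91))   # add-one convention: p = 1
  expect_false(any(res$table$significant))

  a <- make_cohort(12, group = "patient", seed = 42)
  b <- make_cohort(13, group = "control", seed = 43)
  r1 <- edgewise_permutation_test(a, b, n_permutations = 300, seed = 7)
  r2 <- edgewise_permutation_test(a, b, n_permutations = 300, seed = 7)
  expect_identical(r1$table$p, r2$table$p)
  r3 <- edgewise_permutation_test(a, b, n_permutations = 300, seed = 8)
  expect_false(identical(r1$table$p, r3$table$p))
  # add-one lower bound
  expect_gte(min(r1$table$p), 1 / 301)
  expect_true(all(r1$table$p <= 1))
  expect_identical(r1$config$family_size, 91L)

  # swapping the groups negates every observed delta exactly
  sw <- edgewise_permutation_test(b, a, n_permutations = 10, seed = 7)
  expect_equal(sw$table$delta, -r1$table$delta, tolerance = 1e-12)

  expect_error(edgewise_permutation_test(a[1:2, ], b, n_permutations = 10),
               "at least 3")
  expect_error(edgewise_permutation_test(a, b, n_permutations = 0), ">= 1")
  expect_error(edgewise_permutation_test(a, b, fdr_q = 1.5,
                                         n_permutations = 10), "fdr_q")
})

test_that("planted edge effect is recovered in the raw edgewise statistics", {
  # strong planted difference (r 0.7 vs 0.1): the planted edge should carry
  # the most extreme observed delta and a raw p <= 0.05 in most replicates
  base <- default_base_correlation()
  base["PCG.L", "HIP.R"] <- base["HIP.R", "PCG.L"] <- 0.7
  hits_p <- 0L
  hits_rank <- 0L
  for (rep in 1:10) {
    spec <- simulation_spec(
      base_correlation = base,
      planted_edges = data.frame(voi_i = "HIP.R", voi_j = "PCG.L",
                                 delta_r = -0.6),
      noise_sd = 0, seed = 500 + rep)
    sim <- generate_cohorts(spec)
    res <- edgewise_permutation_test(sim$cohort_a, sim$cohort_b,
                                     n_permutations = 400, seed = rep)
    k <- which(res$table$edge == "PCG.L - HIP.R")
    if (res$table$p[k] <= 0.05) hits_p <- hits_p + 1L
    if (which.min(res$table$delta) == k) hits_rank <- hits_rank + 1L
    expect_lt(res$table$delta[k], 0)   # decreased in the patient group
  }
  expect_gte(hits_p, 8L)
  expect_gte(hits_rank, 8L)
})

test_that("edgewise type-I error is near nominal under the null (small scale)", {
  n_rep <- 60
  frac <- numeric(n_rep)
  for (rep in seq_len(n_rep)) {
    spec <- simulation_spec(n_a = 15, n_b = 15, seed = 9000 + rep)
    sim <- generate_cohorts(spec)
    res <- edgewise_permutation_test(sim$cohort_a, sim$cohort_b,
                                     n_permutations = 100, seed = rep)
    frac[rep] <- mean(res$table$p <= 0.05)
  }
  # attainable levels with 100 permutations: P(p <= 0.05) = 5/101 = 0.0495
  se <- sd(frac) / sqrt(n_rep)
  expect_lt(abs(mean(frac) - 5 / 101), max(4 * se, 0.02))
})

test_that("metric permutation test: trivial cases and directional power", {
  cohort <- make_cohort(10, group = "patient", seed = 51)
  twin <- cohort
  twin$group <- "control"
  for (m in c("global_efficiency", "nodal_efficiency")) {
    res <- metric_permutation_test(cohort, twin, metric = m,
                                   n_permutations = 100, seed = 2)
    expect_equal(res$table$delta, rep(0, nrow(res$table)))
    expect_equal(res$table$p, rep(1, nrow(res$table)))
  }

  # uniformly stronger correlations in group a -> higher global efficiency,
  # detected at a large effect
  strong <- default_base_correlation()
  weak <- matrix(0.15, 14, 14); diag(weak) <- 1
  dimnames(weak) <- dimnames(strong)
  spec <- simulation_spec(base_correlation = weak,
                          planted_edges = NULL, noise_sd = 0, seed = 61)
  sim_b <- generate_cohorts(spec)
  spec_a <- simulation_spec(base_correlation = strong, noise_sd = 0, seed = 62)
  sim_a <- generate_cohorts(spec_a)
  res <- metric_permutation_test(sim_a$cohort_a, sim_b$cohort_b,
                                 metric = "global_efficiency",
                                 n_permutations = 200, seed = 3)
  expect_gt(res$table$delta, 0)
  expect_lte(res$table$p, 0.05)
  expect_true(res$table$significant)   # global metrics: uncorrected alpha
  expect_true(is.na(res$table$q))

  # regional metric carries a 14-wide BH family
  reg <- metric_permutation_test(sim_a$cohort_a, sim_b$cohort_b,
                                 metric = "degree_centrality",
                                 n_permutations = 200, seed = 3)
  expect_identical(nrow(reg$table), 14L)
  expect_identical(reg$config$family_size, 14L)
  expect_true(all(reg$table$q >= reg$table$p - 1e-12))
})

test_that("permutation p-values under the null are uniform (KS sanity check)", {
  # one fixed edge across replicates -> i.i.d. p-values
  n_rep <- 120
  pvals <- numeric(n_rep)
  for (rep in seq_len(n_rep)) {
    spec <- simulation_spec(n_a = 12, n_b = 12, seed = 20000 + rep)
    sim <- generate_cohorts(spec)
    res <- edgewise_permutation_test(sim$cohort_a, sim$cohort_b,
                                     n_permutations = 99, seed = rep)
    pvals[rep] <- res$table$p[1]
  }
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("permutation results serialize to TSV and JSON", {
  a <- make_cohort(8, group = "patient", seed = 71)
  b <- make_cohort(9, group = "control", seed = 72)
  res <- edgewise_permutation_test(a, b, n_permutations = 50, seed = 1)
  dir <- tempfile()
  paths <- write_permutation_result(res, dir)
  expect_true(all(file.exists(paths)))
  tab <- read.delim(paths[1])
  expect_identical(nrow(tab), 91L)
  js <- jsonlite::read_json(paths[2], simplifyVector = TRUE)
  expect_equal(js$config$n_permutations, 50)
})
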