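# Group-comparison inference: edgewise Fisher-z permutation test with
# Benjamini-Hochberg FDR across the 91 edges, graph-metric permutation tests,
# and the demographic tests (two-sample t from summaries, 2x2 chi-square).
#
# Permutation scheme (shared by both tests): subjects are randomly reassigned
# to pseudo-groups of the original sizes, both group statistics are recomputed
# per permutation, and the observed difference is referred to the permuted
# difference distribution. p uses the add-one estimator
# p = (1 + #extreme) / (1 + n_permutations), so p is never 0 and the smallest
# attainable value is 1/(n_permutations + 1).

.sidedness_count <- function(null, obs, sidedness) {
  # null: permutations x k matrix; obs: length-k vector. Counts per column.
  switch(sidedness,
    two_sided = colSums(abs(null) >= rep(abs(obs), each = nrow(null))),
    less      = colSums(null <= rep(obs, each = nrow(null))),
    greater   = colSums(null >= rep(obs, each = nrow(null)))
  )
}

.null_summary <- function(null) {
  data.frame(
    null_mean = colMeans(null),
    null_sd = apply(null, 2L, stats::sd),
    null_q025 = apply(null, 2L, stats::quantile, probs = 0.025, names = FALSE),
    null_q975 = apply(null, 2L, stats::quantile, probs = 0.975, names = FALSE)
  )
}

# Lean correlation for the permutation inner loop: returns NULL instead of
# erroring when a pseudo-group column has zero variance, so the caller can
# redraw that permutation.
.safe_cor <- function(X, rows) {
  Xs <- X[rows, , drop = FALSE]
  n <- nrow(Xs)
  Xc <- Xs - rep(colMeans(Xs), each = n)
  s <- sqrt(colSums(Xc * Xc))
  if (any(s == 0)) return(NULL)
  R <- crossprod(Xc) / tcrossprod(s)
  R[R > 1] <- 1
  R[R < -1] <- -1
  diag(R) <- 1
  R
}

# Shared permutation engine: statfun(rows) returns the group statistic vector
# or NULL when the pseudo-group is degenerate (that permutation is redrawn,
# up to max_retries times in total per permutation).
.perm_null <- function(X, n_a, n_stats, n_permutations, statfun, max_retries) {
  n <- nrow(X)
  nm <- matrix(0, n_permutations, n_stats)
  retries <- 0L
  for (b in seq_len(n_permutations)) {
    da <- NULL
    for (try in seq_len(max_retries + 1L)) {
      idx <- sample.int(n)
      da <- statfun(idx[seq_len(n_a)])
      if (is.null(da)) next
      db <- statfun(idx[(n_a + 1L):n])
      if (is.null(db)) { da <- NULL; next }
      retries <- retries + (try - 1L)
      break
    }
    if (is.null(da)) {
      stop("could not draw a permutation without zero-variance columns after ",
           max_retries, " retries", call. = FALSE)
    }
    nm[b, ] <- da - db
  }
  if (retries > 0L) {
    warning("redrew ", retries, " permutation(s) with zero-variance columns",
            call. = FALSE)
  }
  attr(nm, "retries") <- retries
  nm
}

.check_perm_config <- function(n_permutations, fdr_q) {
  if (!is.numeric(n_permutations) || n_permutations < 1) {
    stop("n_permutations must be >= 1", call. = FALSE)
  }
  if (!is.numeric(fdr_q) || fdr_q <= 0 || fdr_q >= 1) {
    stop("fdr_q must lie in (0, 1)", call. = FALSE)
  }
}

.stack_cohorts <- function(cohort_a, cohort_b) {
  cohort_a <- as_cohort_table(cohort_a)
  cohort_b <- as_cohort_table(cohort_b)
  va <- attr(cohort_a, "voi_names")
  vb <- attr(cohort_b, "voi_names")
  if (!identical(va, vb)) {
    stop("cohorts have different VOI columns/order", call. = FALSE)
  }
  Xa <- uptake_matrix(cohort_a)
  Xb <- uptake_matrix(cohort_b)
  if (nrow(Xa) < 3L || nrow(Xb) < 3L) {
    stop("need at least 3 subjects per group", call. = FALSE)
  }
  list(X = rbind(Xa, Xb), n_a = nrow(Xa), n_b = nrow(Xb), vois = va,
       group_a = unique(cohort_a$group), group_b = unique(cohort_b$group))
}

#' Edgewise permutation test on Fisher-z connectivity differences
#'
#' For every VOI pair (91 edges with the 14-region atlas) the observed
#' statistic is `Delta_ij = z_a(ij) - z_b(ij)` on the unthresholded Fisher-z
#' matrices of the two groups. The null is built by permuting group labels:
#' subjects are reassigned to pseudo-groups of the original sizes, both
#' correlation matrices recomputed, and Delta recorded. Benjamini-Hochberg
#' FDR is applied across the edges.
#'
#' @param cohort_a,cohort_b `cohort_table`s for the two groups (each >= 3
#'   subjects, same VOI order). `cohort_a` is conventionally the patient
#'   group, so negative Delta means lower connectivity in patients.
#' @param n_permutations Number of label permutations (default 10000).
#' @param seed Integer seed for reproducibility; `NULL` uses the current RNG
#'   state.
#' @param sidedness `"two_sided"` (default), `"less"` (decreased in group a)
#'   or `"greater"`.
#' @param fdr_q FDR threshold (default 0.05).
#' @param max_retries Redraw budget for permutations hitting a zero-variance
#'   column (counted in the result).
#' @return A `permutation_result`: `$table` with one row per edge (`voi_a`,
#'   `voi_b`, `edge`, `z_a`, `z_b`, `delta`, `direction`, `p`, `q`,
#'   `significant`, null summaries) plus `$config` and `$n_retries`.
#' @export
edgewise_permutation_test <- function(cohort_a, cohort_b,
                                      n_permutations = 10000, seed = NULL,
                                      sidedness = c("two_sided", "less", "greater"),
                                      fdr_q = 0.05, max_retries = 100) {
  sidedness <- match.arg(sidedness)
  .check_perm_config(n_permutations, fdr_q)
  st <- .stack_cohorts(cohort_a, cohort_b)
  p_voi <- length(st$vois)
  ut <- upper_tri_index(p_voi)

  zvec <- function(rows) {
    R <- .safe_cor(st$X, rows)
    if (is.null(R)) return(NULL)
    atanh(R[ut$linear])
  }
  obs_a <- zvec(seq_len(st$n_a))
  obs_b <- zvec(st$n_a + seq_len(st$n_b))
  if (is.null(obs_a) || is.null(obs_b)) {
    stop("zero-variance VOI column in an observed group", call. = FALSE)
  }
  obs <- obs_a - obs_b

  null <- with_seed(seed,
    .perm_null(st$X, st$n_a, length(obs), n_permutations, zvec, max_retries))
  n_retries <- attr(null, "retries")

  pvals <- (1 + .sidedness_count(null, obs, sidedness)) / (1 + n_permutations)
  fdr <- bh_fdr(pvals, fdr_q)
  tab <- cbind(
    data.frame(
      voi_a = st$vois[ut$i], voi_b = st$vois[ut$j],
      edge = paste(st$vois[ut$i], "-", st$vois[ut$j]),
      z_a = obs_a, z_b = obs_b, delta = obs,
      direction = ifelse(obs < 0, "decreased", "increased"),
      p = pvals, q = fdr$qvalues, significant = fdr$significant,
      stringsAsFactors = FALSE
    ),
    .null_summary(null)
  )
  structure(
    list(
      table = tab,
      config = list(test = "edgewise", n_permutations = n_permutations,
                    seed = seed, sidedness = sidedness, fdr_q = fdr_q,
                    family_size = length(obs),
                    group_a = st$group_a, group_b = st$group_b,
                    n_a = st$n_a, n_b = st$n_b),
      n_retries = n_retries
    ),
    class = "permutation_result"
  )
}

#' Permutation test on a graph metric
#'
#' Same label-permutation scheme as [edgewise_permutation_test()], but the
#' statistic is a graph metric of each pseudo-group's thresholded weight
#' matrix. Per-node metrics (nodal efficiency, degree centrality) are
#' corrected by Benjamini-Hochberg FDR across the nodes; global metrics
#' (global efficiency, characteristic path length) are scalar and tested
#' uncorrected at `alpha`.
#'
#' @inheritParams edgewise_permutation_test
#' @param metric One of `"global_efficiency"`, `"characteristic_path_length"`,
#'   `"nodal_efficiency"`, `"degree_centrality"`.
#' @param weight_mode Correlation-to-weight mapping, see [threshold_weights()].
#' @param alpha Significance level for the (uncorrected) global metrics.
#' @return A `permutation_result`; `$table` has one row (global metric) or
#'   one row per node (regional metric).
#' @export
metric_permutation_test <- function(cohort_a, cohort_b,
                                    metric = c("global_efficiency",
                                               "characteristic_path_length",
                                               "nodal_efficiency",
                                               "degree_centrality"),
                                    n_permutations = 10000, seed = NULL,
                                    sidedness = c("two_sided", "less", "greater"),
                                    fdr_q = 0.05, alpha = 0.05,
                                    weight_mode = c("positive", "absolute"),
                                    max_retries = 100) {
  metric <- match.arg(metric)
  sidedness <- match.arg(sidedness)
  weight_mode <- match.arg(weight_mode)
  .check_perm_config(n_permutations, fdr_q)
  st <- .stack_cohorts(cohort_a, cohort_b)
  regional <- metric %in% c("nodal_efficiency", "degree_centrality")

  stat <- function(rows) {
    R <- .safe_cor(st$X, rows)
    if (is.null(R)) return(NULL)
    W <- threshold_weights(R, weight_mode)
    if (metric == "degree_centrality") return(degree_centrality(W))
    D <- shortest_path_distances(weight_to_length(W))
    switch(metric,
      global_efficiency = global_efficiency(D),
      characteristic_path_length = as.numeric(characteristic_path_length(D)),
      nodal_efficiency = nodal_efficiency(D)
    )
  }
  obs_a <- stat(seq_len(st$n_a))
  obs_b <- stat(st$n_a + seq_len(st$n_b))
  if (is.null(obs_a) || is.null(obs_b)) {
    stop("zero-variance VOI column in an observed group", call. = FALSE)
  }
  obs <- obs_a - obs_b

  null <- with_seed(seed,
    .perm_null(st$X, st$n_a, length(obs), n_permutations, stat, max_retries))
  n_retries <- attr(null, "retries")

  pvals <- (1 + .sidedness_count(null, obs, sidedness)) / (1 + n_permutations)
  if (regional) {
    fdr <- bh_fdr(pvals, fdr_q)
    qvals <- fdr$qvalues
    sig <- fdr$significant
  } else {
    qvals <- NA_real_
    sig <- pvals <= alpha
  }
  tab <- cbind(
    data.frame(
      node = if (regional) st$vois else metric,
      metric = metric,
      value_a = obs_a, value_b = obs_b, delta = obs,
      direction = ifelse(obs < 0, "decreased", "increased"),
      p = pvals, q = qvals, significant = sig,
      stringsAsFactors = FALSE
    ),
    .null_summary(null)
  )
  structure(
    list(
      table = tab,
      config = list(test = metric, n_permutations = n_permutations,
                    seed = seed, sidedness = sidedness,
                    fdr_q = if (regional) fdr_q else NA_real_,
                    alpha = if (regional) NA_real_ else alpha,
                    family_size = length(obs), weight_mode = weight_mode,
                    group_a = st$group_a, group_b = st$group_b,
                    n_a = st$n_a, n_b = st$n_b),
      n_retries = n_retries
    ),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<permutation_result> %s test, %d permutations, %s, family of %d\n",
    cfg$test, cfg$n_permutations, cfg$sidedness, cfg$family_size))
  nsig <- sum(x$table$significant)
  cat(sprintf("  %d significant of %d; min p = %.4g; retries = %d\n",
              nsig, nrow(x$table), min(x$table$p), x$n_retries))
  if (nsig > 0 && "edge" %in% names(x$table)) {
    cat("  significant edges:",
        paste(x$table$edge[x$table$significant], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Benjamini-Hochberg FDR step-up
#'
#' Sort p ascending; `q_(i) = min_{k >= i} m * p_(k) / k` (capped at 1);
#' flag significant where `q <= q_threshold`. Flags are invariant to the
#' input ordering.
#'
#' @param pvalues Numeric p-values in `(0, 1]`.
#' @param q Threshold (default 0.05).
#' @return List with `qvalues` and logical `significant`, in input order.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  p <- as.numeric(pvalues)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  m <- length(p)
  ord <- order(p)
  qs <- pmin(rev(cummin(rev(m * p[ord] / seq_len(m)))), 1)
  qvalues <- numeric(m)
  qvalues[ord] <- qs
  list(qvalues = qvalues, significant = qvalues <= q)
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance (Student) two-sample t-test computed from group means,
#' standard deviations and sizes, `df = n_a + n_b - 2`; the textbook
#' "independent two-sample t-test" used for demographic comparisons. Set
#' `var_equal = FALSE` for the Welch variant.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summaries (`n >= 2`,
#'   `sd > 0`).
#' @param var_equal Pool variances (default `TRUE`).
#' @return List with `statistic`, `df`, `p_value` (two-sided).
#' @export
two_sample_t_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                                      var_equal = TRUE) {
  if (n_a < 2 || n_b < 2) stop("need n >= 2 per group", call. = FALSE)
  if (sd_a <= 0 || sd_b <= 0) stop("sds must be positive", call. = FALSE)
  if (var_equal) {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  } else {
    va <- sd_a^2 / n_a
    vb <- sd_b^2 / n_b
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  }
  t <- (mean_a - mean_b) / se
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction, df = 1: `X^2 = sum (O - E)^2 / E` with
#' expected counts from the margins.
#'
#' @param counts 2x2 matrix (or coercible) of counts, rows = groups,
#'   columns = categories.
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_2x2 <- function(counts) {
  O <- matrix(as.numeric(counts), 2L, 2L)
  if (any(O < 0)) stop("counts must be non-negative", call. = FALSE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  if (any(E <= 0)) stop("zero marginal: expected counts must be positive",
                        call. = FALSE)
  x2 <- sum((O - E)^2 / E)
  list(statistic = x2, df = 1L,
       p_value = stats::pchisq(x2, df = 1L, lower.tail = FALSE),
       expected = E)
}

#' Write a permutation result as TSV and JSON
#'
#' @param result A `permutation_result`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Paths written, invisibly.
#' @export
write_permutation_result <- function(result, dir, prefix = result$config$test) {
  stopifnot(inherits(result, "permutation_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tp <- file.path(dir, paste0(prefix, ".tsv"))
  utils::write.table(result$table, tp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jp <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(
    list(config = result$config, n_retries = result$n_retries,
         table = result$table),
    jp, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(c(tp, jp))
}
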