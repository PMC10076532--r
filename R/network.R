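# Inter-subject correlation network construction: one weighted undirected
# network per group, where edge ij is the Pearson correlation between VOI i's
# and VOI j's uptake across that group's subjects.

#' Build a group's inter-subject correlation network
#'
#' Computes, across the subjects of ONE group, the Pearson correlation between
#' every pair of VOI uptake columns, yielding a symmetric correlation matrix R
#' with unit diagonal (14 x 14 with the packaged atlas). The Fisher transform
#' Z = atanh(R) (diagonal masked as `NA`) and the non-negative connection
#' weight matrix W (see [threshold_weights()]) are derived alongside.
#'
#' @param cohort A `cohort_table` whose rows all carry the same group label.
#' @param weight_mode `"positive"` (default; negative correlations clamped to
#'   zero) or `"absolute"` for the graph-analysis weights. Edgewise statistics
#'   always use the unthresholded Z, so no information is lost by clamping.
#' @return A `group_network`: list with `group`, `n_subjects`, `R`, `Z`, `W`,
#'   `weight_mode`.
#' @export
intersubject_correlation <- function(cohort, weight_mode = c("positive", "absolute")) {
  weight_mode <- match.arg(weight_mode)
  cohort <- as_cohort_table(cohort)
  grp <- unique(cohort$group)
  if (length(grp) != 1L) {
    stop("cohort mixes groups (", paste(grp, collapse = ", "),
         "); build one network per group", call. = FALSE)
  }
  X <- uptake_matrix(cohort)
  if (nrow(X) < 3L) stop("need at least 3 subjects per group", call. = FALSE)
  R <- fast_cor(X)
  structure(
    list(group = grp, n_subjects = nrow(X), R = R,
         Z = fisher_z(R, strict = FALSE),
         W = threshold_weights(R, weight_mode),
         weight_mode = weight_mode),
    class = "group_network"
  )
}

#' Fisher z transform of a correlation matrix
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`, the variance-stabilizing
#' transform used to compare correlations across groups. The diagonal is
#' masked as `NA` (self-correlation carries no information here).
#'
#' @param R Correlation matrix (or a single correlation value).
#' @param strict If `TRUE` (default), off-diagonal `|r| >= 1` is an error
#'   (degenerate data: the transform diverges); `FALSE` returns `Inf` with a
#'   warning instead, for exploratory use.
#' @return Matrix of z scores with `NA` diagonal (or a scalar for scalar
#'   input).
#' @export
fisher_z <- function(R, strict = TRUE) {
  if (is.matrix(R)) {
    off <- R[upper.tri(R) | lower.tri(R)]
    if (any(abs(off) >= 1)) {
      if (strict) {
        stop("off-diagonal |r| >= 1: Fisher transform diverges ",
             "(duplicate/degenerate VOI columns?)", call. = FALSE)
      }
      warning("off-diagonal |r| = 1: Fisher z is infinite", call. = FALSE)
    }
    Z <- atanh(R)
    diag(Z) <- NA_real_
    return(Z)
  }
  if (strict && any(abs(R) >= 1)) {
    stop("|r| >= 1: Fisher transform diverges", call. = FALSE)
  }
  atanh(R)
}

#' Map correlations to non-negative graph weights
#'
#' Shortest-path mathematics requires non-negative weights, but correlations
#' can be negative. `mode = "positive"` clamps negative correlations to zero;
#' `mode = "absolute"` uses `|r|`. The diagonal is structurally zero: self
#' connections are excluded from all graph computations.
#'
#' @param R Correlation matrix.
#' @param mode `"positive"` or `"absolute"`.
#' @return Symmetric non-negative weight matrix W with zero diagonal and
#'   entries in `[0, 1]`.
#' @export
threshold_weights <- function(R, mode = c("positive", "absolute")) {
  mode <- match.arg(mode)
  W <- if (mode == "positive") pmax(R, 0) else abs(R)
  diag(W) <- 0
  W
}

#' @export
print.group_network <- function(x, ...) {
  off <- x$R[upper.tri(x$R)]
  cat(sprintf(
    "<group_network> group '%s': %d subjects, %d VOIs, %d edges\n",
    x$group, x$n_subjects, nrow(x$R), length(off)))
  cat(sprintf("  r range %.3f..%.3f (median %.3f); weight mode '%s'\n",
              min(off), max(off), stats::median(off), x$weight_mode))
  invisible(x)
}

#' Write a group network's matrices and edge list
#'
#' Writes `R`, `Z`, `W` as square TSV matrices with VOI-abbreviation headers,
#' plus an edge-list CSV (`voi_a, voi_b, r, z, w`).
#'
#' @param network A `group_network`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix; defaults to the group label.
#' @return Paths of the files written, invisibly.
#' @export
write_group_network <- function(network, dir, prefix = network$group) {
  stopifnot(inherits(network, "group_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("R", "Z", "W")) {
    p <- file.path(dir, sprintf("%s_%s.tsv", prefix, nm))
    utils::write.table(round(network[[nm]], 10), p, sep = "\t", quote = FALSE,
                       col.names = NA)
    paths <- c(paths, p)
  }
  ut <- upper_tri_index(nrow(network$R))
  vois <- colnames(network$R)
  edges <- data.frame(
    voi_a = vois[ut$i], voi_b = vois[ut$j],
    r = network$R[ut$linear], z = network$Z[ut$linear],
    w = network$W[ut$linear]
  )
  p <- file.path(dir, sprintf("%s_edges.csv", prefix))
  utils::write.csv(edges, p, row.names = FALSE, quote = FALSE)
  invisible(c(paths, p))
}
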