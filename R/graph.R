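# Weighted graph metrics on the connectivity network: shortest-path distance
# matrix (Dijkstra), global/nodal efficiency, characteristic path length,
# degree centrality (strength). Conventions follow the weighted variants used
# by the standard brain-connectivity toolboxes: edge length = 1 / weight,
# efficiency terms 1/d with 1/Inf = 0.

#' Convert connection weights to edge lengths
#'
#' Strong connections are short: `l = 1/w` for `w > 0`, `Inf` for absent
#' edges, 0 on the diagonal.
#'
#' @param W Symmetric non-negative weight matrix with zero diagonal.
#' @return Length matrix of the same shape.
#' @export
weight_to_length <- function(W) {
  W <- as.matrix(W)
  if (any(W < 0)) stop("weights must be non-negative", call. = FALSE)
  L <- ifelse(W > 0, 1 / W, Inf)
  diag(L) <- 0
  L
}

#' All-pairs shortest-path distances
#'
#' Dijkstra's algorithm run from every source over the weighted length
#' matrix. Unreachable pairs get `Inf`.
#'
#' @param lengths Non-negative length matrix with zero diagonal (`Inf` =
#'   no direct edge), as produced by [weight_to_length()].
#' @return Symmetric distance matrix with zero diagonal.
#' @export
shortest_path_distances <- function(lengths) {
  L <- as.matrix(lengths)
  n <- nrow(L)
  stopifnot(ncol(L) == n)
  if (any(L[is.finite(L)] < 0)) stop("negative edge length", call. = FALSE)
  D <- matrix(Inf, n, n, dimnames = dimnames(L))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    done <- rep(FALSE, n)
    for (iter in seq_len(n)) {
      cand <- dist
      cand[done] <- Inf
      u <- which.min(cand)          # first index on ties
      if (!is.finite(cand[u])) break
      done[u] <- TRUE
      alt <- dist[u] + L[u, ]
      upd <- !done & alt < dist
      dist[upd] <- alt[upd]
    }
    D[s, ] <- dist
  }
  diag(D) <- 0
  D
}

#' Global efficiency
#'
#' Mean inverse shortest-path distance over all ordered node pairs,
#' `E_glob = 1/(n(n-1)) * sum_{i != j} 1/d_ij`, with `1/Inf = 0`. Values lie
#' in `[0, 1]` when all weights are at most 1.
#'
#' @param D Distance matrix from [shortest_path_distances()].
#' @return Scalar global efficiency.
#' @export
global_efficiency <- function(D) {
  n <- nrow(D)
  stopifnot(n >= 2L)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Characteristic path length
#'
#' Mean shortest-path distance over ordered pairs with finite distance.
#' Disconnected pairs are excluded rather than propagating `Inf`; their count
#' is attached as attribute `"n_infinite_pairs"` so partial disconnection is
#' visible, not hidden.
#'
#' @param D Distance matrix.
#' @return Scalar path length with attribute `n_infinite_pairs`; error if no
#'   finite off-diagonal distance exists.
#' @export
characteristic_path_length <- function(D) {
  n <- nrow(D)
  off <- D[row(D) != col(D)]
  fin <- is.finite(off)
  if (!any(fin)) {
    stop("no finite off-diagonal distances: graph fully disconnected",
         call. = FALSE)
  }
  structure(mean(off[fin]), n_infinite_pairs = sum(!fin))
}

#' Nodal efficiency
#'
#' `E_nodal(i) = 1/(n-1) * sum_{j != i} 1/d_ij` with `1/Inf = 0`: how
#' efficiently node i reaches the rest of the network. The mean of the nodal
#' efficiencies equals the global efficiency.
#'
#' @param D Distance matrix.
#' @param node Optional node index or name; default all nodes.
#' @return Named vector of nodal efficiencies (or a scalar for one node).
#' @export
nodal_efficiency <- function(D, node = NULL) {
  n <- nrow(D)
  stopifnot(n >= 2L)
  inv <- 1 / D
  diag(inv) <- 0
  eff <- rowSums(inv) / (n - 1)
  names(eff) <- rownames(D)
  if (is.null(node)) eff else eff[[node]]
}

#' Degree centrality (weighted strength)
#'
#' Sum of a node's incident edge weights, `s_i = sum_j w_ij`. No
#' binarization: the network is analyzed fully weighted.
#'
#' @param W Non-negative weight matrix with zero diagonal.
#' @param node Optional node index or name; default all nodes.
#' @return Named vector of strengths (or a scalar for one node).
#' @export
degree_centrality <- function(W, node = NULL) {
  if (any(W < 0)) stop("weights must be non-negative", call. = FALSE)
  s <- rowSums(W)
  names(s) <- rownames(W)
  if (is.null(node)) s else s[[node]]
}

#' Full graph-metric report for a network
#'
#' Computes the two global measures (global efficiency, characteristic path
#' length) and the two regional measures (nodal efficiency, degree
#' centrality) used to characterize the connectivity network.
#'
#' @param network A `group_network` or a non-negative weight matrix.
#' @return A `graph_metrics_report`: list with `global_efficiency`,
#'   `characteristic_path_length`, `n_infinite_pairs`, `nodal_efficiency`,
#'   `degree_centrality`, `weight_mode`, `length_mapping`.
#' @export
graph_metrics <- function(network) {
  if (inherits(network, "group_network")) {
    W <- network$W
    mode <- network$weight_mode
  } else {
    W <- as.matrix(network)
    mode <- "as_given"
  }
  D <- shortest_path_distances(weight_to_length(W))
  cpl <- characteristic_path_length(D)
  structure(
    list(
      global_efficiency = global_efficiency(D),
      characteristic_path_length = as.numeric(cpl),
      n_infinite_pairs = attr(cpl, "n_infinite_pairs"),
      nodal_efficiency = nodal_efficiency(D),
      degree_centrality = degree_centrality(W),
      weight_mode = mode,
      length_mapping = "reciprocal"
    ),
    class = "graph_metrics_report"
  )
}

#' @export
print.graph_metrics_report <- function(x, ...) {
  cat(sprintf("<graph_metrics_report> E_glob = %.4f, L = %.4f (%d pairs disconnected)\n",
              x$global_efficiency, x$characteristic_path_length,
              x$n_infinite_pairs))
  cat("  nodal efficiency:", paste(signif(x$nodal_efficiency, 3), collapse = " "),
      "\n  degree centrality:", paste(signif(x$degree_centrality, 3), collapse = " "),
      "\n")
  invisible(x)
}

#' Write a graph-metric report as JSON and TSV
#'
#' @param report A `graph_metrics_report`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Paths written, invisibly.
#' @export
write_graph_metrics <- function(report, dir, prefix = "metrics") {
  stopifnot(inherits(report, "graph_metrics_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jp <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(unclass(report), jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  tp <- file.path(dir, paste0(prefix, ".tsv"))
  nodal <- data.frame(
    voi = names(report$nodal_efficiency) %||%
      seq_along(report$nodal_efficiency),
    nodal_efficiency = as.numeric(report$nodal_efficiency),
    degree_centrality = as.numeric(report$degree_centrality)
  )
  con <- file(tp, "w")
  on.exit(close(con))
  writeLines(sprintf("# global_efficiency\t%.10g", report$global_efficiency), con)
  writeLines(sprintf("# characteristic_path_length\t%.10g",
                     report$characteristic_path_length), con)
  writeLines(sprintf("# n_infinite_pairs\t%d", report$n_infinite_pairs), con)
  utils::write.table(nodal, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(jp, tp))
}
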