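# Independent oracles and fixture builders. These deliberately avoid the
# package's own code paths: Floyd-Warshall vs Dijkstra, direct-formula
# Pearson vs the crossprod implementation, BFS vs weighted distances on
# binary graphs, brute-force convolution vs the separable filter.

# All-pairs shortest paths by Floyd-Warshall (min-plus relaxation).
oracle_floyd_warshall <- function(L) {
  n <- nrow(L)
  D <- L
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  }
  D
}

# Hop distances on a binary adjacency matrix by breadth-first search.
oracle_bfs_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    hop <- 0
    while (length(frontier)) {
      hop <- hop + 1
      nxt <- which(is.infinite(dist) & colSums(adj[frontier, , drop = FALSE]) > 0)
      dist[nxt] <- hop
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  diag(D) <- 0
  D
}

# Pearson correlation from the defining formula, one pair at a time.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    (sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2)))
}

# Random connected-ish weighted graph on n nodes: weights in (0, 1], a
# fraction of edges absent.
random_weight_matrix <- function(n, p_absent = 0.3) {
  W <- matrix(stats::runif(n * n, 0.05, 1), n, n)
  W[stats::runif(n * n) < p_absent] <- 0
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  diag(W) <- 0
  W
}

# Tiny brain volume on a diagonal affine for extraction tests.
make_volume <- function(data, voxel_size = c(2, 2, 2), origin = NULL,
                        subject_id = "s1", group = "control") {
  shape <- dim(data)
  if (is.null(origin)) origin <- -(shape - 1) / 2 * voxel_size
  affine <- diag(c(voxel_size, 1))
  affine[1:3, 4] <- origin
  brain_volume(data, affine, subject_id = subject_id, group = group)
}

# Small synthetic cohort table: n subjects x p VOI columns, one group.
make_cohort <- function(n, p = 14, group = "control", seed = 1,
                        vois = load_default_atlas()$abbreviation[seq_len(p)]) {
  set.seed(seed)
  X <- matrix(rnorm(n * p, mean = 1.2, sd = 0.12), n, p)
  colnames(X) <- vois
  as_cohort_table(cbind(
    data.frame(subject_id = sprintf("%s%02d", substr(group, 1, 3), seq_len(n)),
               group = group, stringsAsFactors = FALSE),
    as.data.frame(X)))
}

# Direct 3-D Gaussian convolution with nearest-edge replication (slow,
# index-by-index); the oracle for the separable filter.
oracle_gaussian_smooth <- function(arr, sigma_vox) {
  shape <- dim(arr)
  r <- pmax(1, ceiling(4 * sigma_vox))
  k <- lapply(1:3, function(ax) {
    w <- exp(-(-r[ax]:r[ax])^2 / (2 * sigma_vox[ax]^2))
    w / sum(w)
  })
  clamp <- function(i, n) pmin(pmax(i, 1), n)
  out <- array(0, shape)
  for (x in 1:shape[1]) for (y in 1:shape[2]) for (z in 1:shape[3]) {
    acc <- 0
    for (dx in -r[1]:r[1]) for (dy in -r[2]:r[2]) for (dz in -r[3]:r[3]) {
      acc <- acc + k[[1]][dx + r[1] + 1] * k[[2]][dy + r[2] + 1] *
        k[[3]][dz + r[3] + 1] *
        arr[clamp(x + dx, shape[1]), clamp(y + dy, shape[2]),
            clamp(z + dz, shape[3])]
    }
    out[x, y, z] <- acc
  }
  out
}
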