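# Construct a geom_graph directly from an adjacency matrix (unit-length
# edges, d = 1) so index solvers can be exercised on arbitrary graphs.
graph_from_adjacency <- function(adj, d = 1) {
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  idx <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  structure(
    list(n = nrow(adj), d = d, adj = adj,
         edges = matrix(as.integer(idx), ncol = 2,
                        dimnames = list(NULL, c("i", "j"))),
         edge_lengths = rep(1, nrow(idx)),
         dist = NULL, source = NULL),
    class = "geom_graph")
}

graph_from_points <- function(pts, d, R = 160) {
  build_graph(point_config(pts, R = R, delta = 0), d)
}

random_adjacency <- function(n, p) {
  A <- matrix(stats::runif(n * n) < p, n, n)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  diag(A) <- FALSE
  A
}

complete_adjacency <- function(n) {
  A <- matrix(TRUE, n, n)
  diag(A) <- FALSE
  A
}

cycle_adjacency <- function(n) {
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    A[i, j] <- A[j, i] <- TRUE
  }
  A
}

path_adjacency <- function(n) {
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- TRUE
  A
}

star_adjacency <- function(n) {
  A <- matrix(FALSE, n, n)
  A[1, -1] <- A[-1, 1] <- TRUE
  A
}

# ---- exhaustive-enumeration oracles (n small) --------------------------

subsets_of_size <- function(n, k) {
  if (k == 0) return(list(integer(0)))
  asplit(utils::combn(n, k), 2)
}

brute_clique_number <- function(adj) {
  n <- nrow(adj)
  for (k in n:1) {
    for (s in subsets_of_size(n, k)) {
      sub <- adj[s, s, drop = FALSE]
      if (all(sub[upper.tri(sub)])) return(k)
    }
  }
  1L
}

brute_independence_number <- function(adj) {
  n <- nrow(adj)
  for (k in n:1) {
    for (s in subsets_of_size(n, k)) {
      sub <- adj[s, s, drop = FALSE]
      if (!any(sub[upper.tri(sub)])) return(k)
    }
  }
  1L
}

brute_domination_number <- function(adj) {
  n <- nrow(adj)
  for (k in 1:n) {
    for (s in subsets_of_size(n, k)) {
      dominated <- rep(FALSE, n)
      dominated[s] <- TRUE
      for (v in s) dominated[adj[v, ]] <- TRUE
      if (all(dominated)) return(k)
    }
  }
  n
}

brute_components <- function(adj) {
  # transitive closure by repeated boolean multiplication
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  length(unique(apply(reach, 1, function(r) paste(which(r), collapse = ","))))
}

# Mean cover time of the complete graph K_n: after the start vertex, each
# step is uniform over the n-1 other vertices, so covering is a coupon
# collector over n-1 coupons with success probability u/(n-1):
# E[T] = (n-1) * H_{n-1}.
kn_cover_time <- function(n) (n - 1) * sum(1 / seq_len(n - 1))
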