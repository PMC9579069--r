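#' @useDynLib numgraph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' The eleven index names
#'
#' Display-order constants used throughout: OC occupancy, DN domination
#' number, IN independence number, CC connected components, LC local
#' clustering, GC global clustering, RW random-walk cover time, EG
#' eigenvector centrality, CL clique number, TD total degree, TL total
#' edge length.
#'
#' @format character vector of length 11.
#' @export
INDEX_NAMES <- c("OC", "DN", "IN", "CC", "LC", "GC", "RW", "EG", "CL", "TD", "TL")

#' Normalized graph indices of a geometric graph
#'
#' Each function returns a single dimensionless value. The seven
#' combinatorial indices (TD, CC, CL, DN, IN, LC, GC) lie in \[0, 1\]; TL
#' lies in \[0, 0.5\] under its printed normalization; the two stochastic
#' indices RW and EG are nonnegative and may exceed 1 on very small graphs
#' (no clamping is applied). The NP-hard indices (CL, DN, IN) are computed
#' exactly, never by a heuristic.
#'
#' @param g a [build_graph()] result.
#' @name graph_indices
NULL

#' @describeIn graph_indices Graph density: twice the edge count divided by
#'   \eqn{n(n-1)}, so the complete graph scores exactly 1. Requires
#'   \eqn{n \ge 2}.
#' @export
total_degree <- function(g) {
  stopifnot(inherits(g, "geom_graph"))
  if (g$n < 2) stop("total_degree is undefined for n < 2")
  2 * nrow(g$edges) / (g$n * (g$n - 1))
}

#' @describeIn graph_indices Sum of edge lengths divided by
#'   \eqn{2 d \cdot n(n-1)/2}, i.e. normalized by the largest value the sum
#'   can take (every one of the \eqn{n(n-1)/2} possible edges present at
#'   length `d`). Maximum 0.5; 0 for an edgeless graph.
#' @export
total_edge_length <- function(g) {
  stopifnot(inherits(g, "geom_graph"))
  if (nrow(g$edges) == 0L || g$d == 0) return(0)
  sum(g$edge_lengths) / (2 * g$d * g$n * (g$n - 1) / 2)
}

#' @describeIn graph_indices Number of connected components divided by `n`.
#' @export
connected_components_index <- function(g) {
  stopifnot(inherits(g, "geom_graph"))
  max(components_of(g)) / g$n
}

#' @describeIn graph_indices Clique number \eqn{\omega(G)/n}, exact.
#' @export
clique_number_index <- function(g) {
  stopifnot(inherits(g, "geom_graph"))
  igraph::clique_num(.gg_igraph(g)) / g$n
}

#' @describeIn graph_indices Domination number \eqn{\gamma(G)/n}, exact
#'   branch-and-bound (isolated vertices are necessarily members of every
#'   dominating set).
#' @export
domination_number_index <- function(g) {
  stopifnot(inherits(g, "geom_graph"))
  domination_number_cpp(g$adj) / g$n
}

#' @describeIn graph_indices Independence number \eqn{\alpha(G)/n}, exact
#'   (independent-vertex-set search on the graph itself).
#' @export
independence_number_index <- function(g) {
  stopifnot(inherits(g, "geom_graph"))
  igraph::ivs_size(.gg_igraph(g)) / g$n
}

#' @describeIn graph_indices Mean local clustering coefficient
#'   \eqn{\sum_v lc_v / n} with \eqn{lc_v = 2 e(N(v)) / (\deg v (\deg v - 1))}
#'   and the convention \eqn{lc_v = 0} for \eqn{\deg v < 2}.
#' @export
local_clustering_index <- function(g) {
  stopifnot(inherits(g, "geom_graph"))
  lc <- igraph::transitivity(.gg_igraph(g), type = "local", isolates = "zero")
  mean(lc)
}

#' @describeIn graph_indices Global clustering (transitivity):
#'   \eqn{3T / P_2} where \eqn{T} is the triangle count and
#'   \eqn{P_2 = \sum_v \binom{\deg v}{2}} the connected-triplet count; 0
#'   when there are no triplets.
#' @export
global_clustering_index <- function(g) {
  stopifnot(inherits(g, "geom_graph"))
  gc <- igraph::transitivity(.gg_igraph(g), type = "global")
  if (is.nan(gc)) 0 else gc
}

#' Random-walk cover-time index
#'
#' Simulates `walks` simple random walks, each starting at a uniformly
#' random vertex and hopping to a uniformly random neighbour until all `n`
#' vertices have been visited. With \eqn{\bar T} the mean number of steps,
#' the index is \eqn{n \ln n / \bar T}: the theoretical lower bound on the
#' cover time of a connected graph (of order \eqn{n \log n}) over the
#' observed mean. Disconnected graphs score 0 (their cover time is
#' infinite). The value may exceed 1 on very small graphs.
#'
#' @param g a [build_graph()] result.
#' @param walks number of walk replicates (study default 1000).
#' @param seed optional seed for the walk RNG.
#' @return index value with attribute `"mc_error"`, the standard error of
#'   the estimate propagated from the standard error of \eqn{\bar T}.
#' @export
random_walk_index <- function(g, walks = 1000, seed = NULL) {
  stopifnot(inherits(g, "geom_graph"), walks >= 1)
  if (g$n == 1L) return(structure(0, mc_error = 0))
  if (max(components_of(g)) > 1L) return(structure(0, mc_error = 0))
  if (!is.null(seed)) set.seed(seed)
  adj <- apply(g$adj, 1, function(row) as.integer(which(row) - 1L),
               simplify = FALSE)
  steps <- cover_times_cpp(adj, as.integer(walks))
  tbar <- mean(steps)
  se_t <- stats::sd(steps) / sqrt(walks)
  val <- g$n * log(g$n) / tbar
  structure(val, mc_error = val * se_t / tbar)
}

#' Eigenvector-centrality index
#'
#' Power iteration on the adjacency matrix starting from the degree
#' sequence, renormalized to unit Euclidean length after every
#' multiplication. On convergence (successive iterates within `tol` in
#' max-norm) the index is the mean of the components of the unit dominant
#' eigenvector; if the iteration does not converge within `max_iters`
#' (e.g. the edgeless graph, whose degree start is the zero vector) the
#' value is 0. EG is only defined for connected graphs: on a disconnected
#' graph the dominant eigenvector lives on one component and says nothing
#' about the rest of the pattern, so the index is returned as missing
#' (`NA`) and excluded from downstream standard deviations and pairwise
#' correlations. Set `connected_only = FALSE` to run the iteration on the
#' whole graph anyway and obtain the dominant component's value. On any
#' connected vertex-transitive graph the value is \eqn{1/\sqrt n}.
#'
#' @param g a [build_graph()] result.
#' @param max_iters iteration cap (study default 1000).
#' @param tol convergence tolerance in max-norm.
#' @param connected_only return `NA` for disconnected graphs (default).
#' @return index value (0 if the iteration fails to converge, `NA` for a
#'   disconnected graph under the default gating).
#' @export
eigenvector_centrality_index <- function(g, max_iters = 1000, tol = 1e-6,
                                         connected_only = TRUE) {
  stopifnot(inherits(g, "geom_graph"), max_iters >= 1, tol > 0)
  if (connected_only && g$n > 1L && max(components_of(g)) > 1L)
    return(structure(NA_real_, note = "disconnected graph: EG undefined"))
  A <- g$adj * 1
  x <- as.numeric(colSums(A))          # degree sequence start
  nx <- sqrt(sum(x^2))
  if (nx == 0) return(0)
  x <- x / nx
  for (it in seq_len(max_iters)) {
    y <- as.numeric(A %*% x)
    ny <- sqrt(sum(y^2))
    if (ny == 0) return(0)
    y <- y / ny
    if (max(abs(y - x)) < tol) return(mean(y))
    x <- y
  }
  0
}

#' Compute a set of indices on one graph
#'
#' Evaluates the requested indices with shared settings. Per-index
#' failures are captured, not propagated: a failed cell carries `NA` and
#' the error message in the `note` column.
#'
#' @param g a [build_graph()] result.
#' @param indices character vector drawn from
#'   `c("TD","TL","RW","EG","CC","CL","DN","IN","LC","GC","OC")`.
#' @param walks random-walk replicates for RW.
#' @param eg_iters,eg_tol power-iteration settings for EG.
#' @param seed seed applied before each stochastic index.
#' @return data.frame with columns `index`, `value`, `mc_error`, `note`.
#' @export
compute_indices <- function(g, indices = INDEX_NAMES, walks = 1000,
                            eg_iters = 1000, eg_tol = 1e-6, seed = NULL) {
  stopifnot(inherits(g, "geom_graph"))
  indices <- match.arg(indices, INDEX_NAMES, several.ok = TRUE)
  one <- function(idx) {
    v <- tryCatch(switch(idx,
      TD = total_degree(g),
      TL = total_edge_length(g),
      RW = random_walk_index(g, walks = walks, seed = seed),
      EG = eigenvector_centrality_index(g, max_iters = eg_iters, tol = eg_tol),
      CC = connected_components_index(g),
      CL = clique_number_index(g),
      DN = domination_number_index(g),
      IN = independence_number_index(g),
      LC = local_clustering_index(g),
      GC = global_clustering_index(g),
      OC = occupancy_analytic(g$source, g$d)$value),
      error = function(e) structure(NA_real_, note = conditionMessage(e)))
    data.frame(index = idx, value = as.numeric(v),
               mc_error = if (!is.null(attr(v, "mc_error")))
                 as.numeric(attr(v, "mc_error")) else NA_real_,
               note = if (!is.null(attr(v, "note")))
                 as.character(attr(v, "note")) else NA_character_)
  }
  out <- do.call(rbind, lapply(indices, one))
  rownames(out) <- NULL
  out
}
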