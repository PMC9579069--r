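#' Random geometric graph on a dot configuration
#'
#' Two dots are joined by an edge iff their Euclidean distance is at most
#' the connectivity distance `d` (closed threshold; for continuous
#' coordinates the boundary case has probability zero, and the closed rule
#' matches the tangency convention of the occupancy model, where `d` is
#' twice the influence radius). Distances are computed once in double
#' precision; no spatial indexing is used, as patterns have at most a few
#' hundred points.
#'
#' @param config a [point_config()].
#' @param d connectivity distance in pixels (>= 0).
#' @return An object of class `geom_graph` with elements `n`, `d`, `adj`
#'   (symmetric logical adjacency matrix, no self-loops), `edges` (m x 2
#'   integer matrix, i < j), `edge_lengths`, and `source` (the input
#'   configuration).
#' @export
build_graph <- function(config, d) {
  stopifnot(inherits(config, "point_config"), d >= 0)
  n <- config$n
  D <- as.matrix(stats::dist(config$points))
  adj <- D <= d
  diag(adj) <- FALSE
  idx <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  structure(
    list(n = n, d = d, adj = adj,
         edges = matrix(as.integer(idx), ncol = 2,
                        dimnames = list(NULL, c("i", "j"))),
         edge_lengths = D[upper.tri(D)][adj[upper.tri(adj)]],
         dist = D, source = config),
    class = "geom_graph")
}

#' @export
print.geom_graph <- function(x, ...) {
  cat(sprintf("geom_graph on %d vertices, d = %g px, %d edges\n",
              x$n, x$d, nrow(x$edges)))
  invisible(x)
}

## igraph view of a geom_graph; the standard graph machinery (components,
## cliques, clustering coefficients) is delegated to igraph.
.gg_igraph <- function(g) {
  if (nrow(g$edges) == 0L) return(igraph::make_empty_graph(g$n, directed = FALSE))
  ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
  if (igraph::vcount(ig) < g$n) ig <- igraph::add_vertices(ig, g$n - igraph::vcount(ig))
  ig
}

#' Degree sequence
#'
#' @param g a [build_graph()] result.
#' @return integer vector of per-vertex degrees; its sum is twice the edge
#'   count.
#' @export
degree_sequence <- function(g) {
  stopifnot(inherits(g, "geom_graph"))
  as.integer(colSums(g$adj))
}

#' Connected components
#'
#' @param g a [build_graph()] result.
#' @return integer vector of component membership labels (1-based); the
#'   number of components is `max()` of it.
#' @export
components_of <- function(g) {
  stopifnot(inherits(g, "geom_graph"))
  igraph::components(.gg_igraph(g))$membership
}

#' Edge list export
#'
#' Writes the edges of a geometric graph as CSV
#' (`pattern_id, d, i, j, length`).
#'
#' @param g a [build_graph()] result.
#' @param file path.
#' @export
write_edges_csv <- function(g, file) {
  stopifnot(inherits(g, "geom_graph"))
  df <- data.frame(pattern_id = g$source$pattern_id, d = g$d,
                   i = g$edges[, 1], j = g$edges[, 2],
                   length = g$edge_lengths)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
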