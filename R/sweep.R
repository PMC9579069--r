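#' The study distance grid
#'
#' The default connectivity-distance grid runs from the minimum spacing
#' `delta` to the aperture diameter `2R` in the given step (study defaults:
#' 10 to 320 in steps of 5; the scaled-down mode uses a step of 10).
#'
#' @param R aperture radius.
#' @param delta minimum spacing (grid start).
#' @param step grid step in pixels.
#' @return strictly increasing numeric vector.
#' @export
d_grid_default <- function(R = 160, delta = R / 16, step = 5) {
  seq(delta, 2 * R, by = step)
}

#' Sweep indices over a connectivity-distance grid
#'
#' Evaluates the requested indices for every configuration at every grid
#' distance, producing a long-format index table, the substrate of the
#' max-SD selection, the correlation matrices and the PCA. Stochastic
#' indices get a per-(pattern, d) seed derived from the master seed so the
#' whole sweep is a pure function of (configs, grid, settings, seed).
#' Per-cell failures are flagged in the `note` column, never dropped.
#'
#' @param configs list of [point_config()], all with the same numerosity.
#' @param d_grid strictly increasing distances in pixels.
#' @param indices index names (default all eleven).
#' @param walks,eg_iters,eg_tol stochastic-index settings.
#' @param seed master seed for the stochastic indices.
#' @param progress print a line per configuration.
#' @return data.frame of class `index_table` with columns `pattern_id`,
#'   `n`, `d`, `index`, `value`, `mc_error`, `note`; attributes `d_grid`
#'   and `provenance`.
#' @export
sweep_indices <- function(configs, d_grid = d_grid_default(),
                          indices = INDEX_NAMES, walks = 1000,
                          eg_iters = 1000, eg_tol = 1e-6, seed = 1,
                          progress = FALSE) {
  if (inherits(configs, "point_config")) configs <- list(configs)
  stopifnot(length(configs) >= 1, length(d_grid) >= 1,
            all(diff(d_grid) > 0))
  ns <- vapply(configs, function(cf) cf$n, 0)
  if (length(unique(ns)) != 1L)
    stop("all configurations in one sweep must share the same numerosity")
  indices <- match.arg(indices, INDEX_NAMES, several.ok = TRUE)
  out <- vector("list", length(configs))
  for (ci in seq_along(configs)) {
    cf <- configs[[ci]]
    rows <- vector("list", length(d_grid))
    for (di in seq_along(d_grid)) {
      g <- build_graph(cf, d_grid[di])
      cell <- compute_indices(g, indices = indices, walks = walks,
                              eg_iters = eg_iters, eg_tol = eg_tol,
                              seed = derive_seed(seed, ci, di))
      cell$pattern_id <- cf$pattern_id
      cell$n <- cf$n
      cell$d <- d_grid[di]
      rows[[di]] <- cell
    }
    out[[ci]] <- do.call(rbind, rows)
    if (progress) message(sprintf("swept %s (%d/%d)", cf$pattern_id, ci,
                                  length(configs)))
  }
  tab <- do.call(rbind, out)
  tab <- tab[, c("pattern_id", "n", "d", "index", "value", "mc_error", "note")]
  structure(tab, class = c("index_table", "data.frame"),
            d_grid = d_grid,
            provenance = list(seed = seed, walks = walks,
                              eg_iters = eg_iters, eg_tol = eg_tol,
                              n_patterns = length(configs)))
}

## values matrix (patterns x grid) for one index; pattern order follows
## first appearance in the table so columns align across indices
.index_matrix <- function(table, index) {
  sub <- table[table$index == index, ]
  pat <- factor(sub$pattern_id, levels = unique(table$pattern_id))
  dd <- factor(sub$d, levels = sort(unique(sub$d)))
  tapply(sub$value, list(pattern_id = pat, d = dd), mean)
}

#' Maximum-standard-deviation distance of an index
#'
#' Finds the grid distance at which an index varies most across patterns:
#' the smallest grid `d` attaining the maximal across-pattern sample
#' standard deviation. This is the distance at which the index is most
#' informative about a pattern, and the basis of the max-SD dataset.
#'
#' @param table an [sweep_indices()] result with at least 2 patterns.
#' @param index index name.
#' @return list with `index`, `d_m`, `sigma_max`, `values_at_dm` (named by
#'   pattern), and `sigma_by_d`.
#' @export
max_sd_distance <- function(table, index) {
  stopifnot(inherits(table, "index_table"))
  M <- .index_matrix(table, index)
  if (nrow(M) < 2) stop("max_sd_distance needs at least 2 patterns")
  sds <- apply(M, 2, stats::sd, na.rm = TRUE)  # flagged-missing cells excluded
  sds[colSums(!is.na(M)) < 2] <- NA
  if (all(sds == 0 | is.na(sds)))
    stop(structure(class = c("numgraph_degenerate_variance_error", "error",
                             "condition"),
                   list(message = sprintf(
                     "index %s has zero across-pattern variance at every grid distance",
                     index), call = sys.call(-1))))
  dm_i <- which.max(sds)              # ties break to the smallest d
  d_vals <- as.numeric(colnames(M))
  list(index = index, d_m = d_vals[dm_i], sigma_max = sds[[dm_i]],
       values_at_dm = M[, dm_i], sigma_by_d = stats::setNames(sds, colnames(M)))
}

#' Max-SD selection for a set of indices
#'
#' @param table an [sweep_indices()] result.
#' @param indices index names (default: all present in the table).
#' @return object of class `max_sd_selection`: a named list of
#'   [max_sd_distance()] entries with a `values` matrix attribute
#'   (patterns x indices, each column taken at its own \eqn{d_m}).
#' @export
max_sd_selection <- function(table, indices = NULL) {
  stopifnot(inherits(table, "index_table"))
  if (is.null(indices)) indices <- unique(table$index)
  sel <- lapply(indices, function(ix) max_sd_distance(table, ix))
  names(sel) <- indices
  vals <- do.call(cbind, lapply(sel, `[[`, "values_at_dm"))
  colnames(vals) <- indices
  structure(sel, class = "max_sd_selection", values = vals,
            n = table$n[1], R = attr(table, "provenance")$R)
}

#' Tabulate a max-SD selection
#'
#' @param sel a [max_sd_selection()].
#' @param R aperture radius used to express \eqn{d_m} in units of R.
#' @return data.frame with columns `index`, `d_m`, `d_m_over_R`, `sigma`.
#' @export
max_sd_table <- function(sel, R = 160) {
  stopifnot(inherits(sel, "max_sd_selection"))
  data.frame(index = names(sel),
             d_m = vapply(sel, `[[`, 0, "d_m"),
             d_m_over_R = vapply(sel, `[[`, 0, "d_m") / R,
             sigma = vapply(sel, `[[`, 0, "sigma_max"),
             row.names = NULL)
}

#' Smallest grid distance connecting every pattern
#'
#' For each configuration the minimal connecting distance equals the
#' longest edge of the Euclidean minimum spanning tree of its points; the
#' graph \eqn{G_d} is connected iff `d` is at least that value. The
#' threshold is the smallest grid distance no smaller than the maximum of
#' these over all configurations. Above it the variance of the CC index is
#' zero.
#'
#' @param configs list of [point_config()].
#' @param d_grid candidate distances.
#' @return the threshold distance, or `NA` if no grid value connects every
#'   pattern.
#' @export
connectivity_threshold <- function(configs, d_grid = d_grid_default()) {
  if (inherits(configs, "point_config")) configs <- list(configs)
  stopifnot(length(configs) >= 1, length(d_grid) >= 1)
  crit <- vapply(configs, function(cf) {
    if (cf$n == 1) return(0)
    D <- as.matrix(stats::dist(cf$points))
    ig <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                              weighted = TRUE, diag = FALSE)
    max(igraph::E(igraph::mst(ig))$weight)
  }, 0)
  need <- max(crit)
  ok <- d_grid[d_grid >= need]
  if (length(ok) == 0L) NA_real_ else ok[1]
}

#' Distance at which an index's variance saturates to zero
#'
#' The smallest grid distance at and beyond which the across-pattern
#' variance of the index is zero — the saturation (threshold) distance
#' used to exclude degenerate correlations. For CC this coincides with
#' [connectivity_threshold()] of the same patterns.
#'
#' @param table an [sweep_indices()] result.
#' @param index index name.
#' @return saturation distance, or `NA` if the index never saturates on
#'   the grid.
#' @export
index_floor_distance <- function(table, index) {
  stopifnot(inherits(table, "index_table"))
  M <- .index_matrix(table, index)
  sds <- apply(M, 2, stats::sd)
  zero <- sds < 1e-12
  if (!zero[length(zero)]) return(NA_real_)
  run <- rev(cumprod(rev(zero)))       # 1 where zero from here to the end
  as.numeric(colnames(M))[which(run == 1)[1]]
}

#' Index-table I/O
#'
#' The table is persisted as tidy CSV (`pattern_id, n, d, index, value,
#' mc_error, note`) plus a JSON sidecar carrying the grid and the
#' generator/stochastic settings.
#'
#' @param table an [sweep_indices()] result.
#' @param file CSV path; the sidecar is written next to it as
#'   `<file>.provenance.json`.
#' @name index_table_io
NULL

#' @rdname index_table_io
#' @export
write_index_table <- function(table, file) {
  stopifnot(inherits(table, "index_table"))
  utils::write.csv(as.data.frame(table), file, row.names = FALSE)
  jsonlite::write_json(
    list(d_grid = attr(table, "d_grid"),
         provenance = attr(table, "provenance")),
    paste0(file, ".provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname index_table_io
#' @export
read_index_table <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  side <- paste0(file, ".provenance.json")
  dg <- sort(unique(df$d))
  prov <- NULL
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    dg <- meta$d_grid
    prov <- meta$provenance
  }
  structure(df, class = c("index_table", "data.frame"),
            d_grid = dg, provenance = prov)
}
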