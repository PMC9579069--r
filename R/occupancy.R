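#' Occupancy: normalized area of the union of influence disks
#'
#' The occupancy model assigns each dot a circular region of influence of
#' radius \eqn{r = d/2}; the index is the area of the union of these disks
#' divided by its maximum possible value \eqn{n \pi (d/2)^2} (n disjoint
#' disks). It equals 1 exactly when all pairwise distances are at least
#' `d`, and decreases as regions overlap. Disks are not clipped to the
#' aperture circle.
#'
#' Two methods are provided. `occupancy_analytic()` computes the exact
#' union area by decomposing each disk boundary into the arcs not covered
#' by any other disk and integrating Green's theorem along them (holes in
#' the union are handled automatically by the arc orientation).
#' `occupancy_raster()` mirrors a screen-capture procedure: it draws each
#' disk on a shared pixel grid, counts covered cells (a cell counts when
#' its centre lies inside some disk) and multiplies by the cell area. The
#' raster value converges to the analytic one as the resolution grows,
#' with error bounded by a constant times the union perimeter times the
#' cell size.
#'
#' @param config a [point_config()].
#' @param d centre-to-centre distance parameter in pixels (> 0); the
#'   influence radius is `d/2`.
#' @return An object of class `occupancy_result`: a list with `value`,
#'   `d`, `method`, `pattern_id` (and `resolution` for the raster method).
#' @name occupancy
NULL

## Union area of n equal disks, exact.
## For each circle, angular intervals covered by each overlapping
## neighbour are merged; the uncovered arcs contribute
## (1/2) \int (x dy - y dx) along the circle. Coincident duplicates are
## dropped (their disk adds nothing to the union).
disk_union_area <- function(centers, r) {
  n <- nrow(centers)
  if (n == 0L) return(0)
  D <- as.matrix(stats::dist(centers))
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (i > 1L && any(keep[seq_len(i - 1L)] & D[i, seq_len(i - 1L)] < 1e-12))
      keep[i] <- FALSE
  }
  centers <- centers[keep, , drop = FALSE]
  D <- D[keep, keep, drop = FALSE]
  n <- nrow(centers)
  total <- 0
  for (i in seq_len(n)) {
    nbr <- which(D[i, ] > 0 & D[i, ] < 2 * r)
    if (length(nbr) == 0L) {
      total <- total + pi * r^2
      next
    }
    # covered angular intervals on circle i
    dx <- centers[nbr, 1] - centers[i, 1]
    dy <- centers[nbr, 2] - centers[i, 2]
    alpha <- atan2(dy, dx)
    beta <- acos(pmin(1, D[i, nbr] / (2 * r)))
    lo <- alpha - beta
    hi <- alpha + beta
    # normalize to [0, 2pi), split wrap-around intervals
    lo <- lo %% (2 * pi)
    hi <- hi %% (2 * pi)
    wrap <- hi < lo
    ivl <- rbind(
      if (any(!wrap)) cbind(lo[!wrap], hi[!wrap]),
      if (any(wrap)) cbind(lo[wrap], rep(2 * pi, sum(wrap))),
      if (any(wrap)) cbind(rep(0, sum(wrap)), hi[wrap]))
    ivl <- ivl[order(ivl[, 1]), , drop = FALSE]
    # merge
    merged <- matrix(numeric(0), 0, 2)
    cur <- ivl[1, ]
    for (k in seq_len(nrow(ivl))[-1]) {
      if (ivl[k, 1] <= cur[2] + 1e-14) {
        cur[2] <- max(cur[2], ivl[k, 2])
      } else {
        merged <- rbind(merged, cur)
        cur <- ivl[k, ]
      }
    }
    merged <- rbind(merged, cur)
    # complement = uncovered arcs
    arcs <- matrix(numeric(0), 0, 2)
    if (merged[1, 1] > 0) arcs <- rbind(arcs, c(0, merged[1, 1]))
    if (nrow(merged) > 1) {
      for (k in seq_len(nrow(merged) - 1))
        arcs <- rbind(arcs, c(merged[k, 2], merged[k + 1, 1]))
    }
    if (merged[nrow(merged), 2] < 2 * pi)
      arcs <- rbind(arcs, c(merged[nrow(merged), 2], 2 * pi))
    if (nrow(arcs) == 0L) next   # boundary fully covered: contributes 0
    th1 <- arcs[, 1]; th2 <- arcs[, 2]
    cx <- centers[i, 1]; cy <- centers[i, 2]
    total <- total + 0.5 * sum(
      r^2 * (th2 - th1) +
        r * cx * (sin(th2) - sin(th1)) -
        r * cy * (cos(th2) - cos(th1)))
  }
  total
}

#' @rdname occupancy
#' @export
occupancy_analytic <- function(config, d) {
  stopifnot(inherits(config, "point_config"), d > 0)
  r <- d / 2
  area <- disk_union_area(config$points, r)
  structure(list(value = area / (config$n * pi * r^2), d = d,
                 method = "analytic", pattern_id = config$pattern_id),
            class = "occupancy_result")
}

#' @rdname occupancy
#' @param resolution raster resolution in cells per pixel (default 1: cell
#'   centres on the integer pixel grid, mimicking a screen capture).
#' @param max_cells guard on the grid size; exceeding it signals a
#'   resolution-overflow error.
#' @export
occupancy_raster <- function(config, d, resolution = 1, max_cells = 5e7) {
  stopifnot(inherits(config, "point_config"), d > 0, resolution >= 1e-6)
  r <- d / 2
  h <- 1 / resolution
  pts <- config$points
  ky <- floor(min(pts[, 2] - r) / h):ceiling(max(pts[, 2] + r) / h)
  nx <- (max(pts[, 1] + r) - min(pts[, 1] - r)) / h + 2
  if (nx * length(ky) > max_cells) {
    stop(structure(class = c("numgraph_resolution_error", "error", "condition"),
                   list(message = sprintf(
                     "raster grid of %g cells exceeds max_cells = %g",
                     nx * length(ky), max_cells), call = sys.call(-1))))
  }
  # row sweep: on each grid row, covered cells form a union of x-intervals;
  # integer-lattice points (scaled by h) inside that union are counted
  count <- 0
  for (ycell in ky * h) {
    dy2 <- r^2 - (ycell - pts[, 2])^2
    hit <- dy2 >= 0
    if (!any(hit)) next
    half <- sqrt(dy2[hit])
    lo <- (pts[hit, 1] - half) / h
    hi <- (pts[hit, 1] + half) / h
    o <- order(lo)
    lo <- lo[o]; hi <- hi[o]
    cur_lo <- lo[1]; cur_hi <- hi[1]
    for (k in seq_along(lo)[-1]) {
      if (lo[k] <= cur_hi) {
        cur_hi <- max(cur_hi, hi[k])
      } else {
        count <- count + max(0, floor(cur_hi) - ceiling(cur_lo) + 1)
        cur_lo <- lo[k]; cur_hi <- hi[k]
      }
    }
    count <- count + max(0, floor(cur_hi) - ceiling(cur_lo) + 1)
  }
  area <- count * h^2
  structure(list(value = area / (config$n * pi * r^2), d = d,
                 method = "raster", resolution = resolution,
                 pattern_id = config$pattern_id),
            class = "occupancy_result")
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat(sprintf("occupancy (%s) '%s': d = %g px, value = %.6f\n",
              x$method, x$pattern_id, x$d, x$value))
  invisible(x)
}
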