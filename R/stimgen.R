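#' Random dot configurations in a circular aperture
#'
#' A `point_config` holds an ordered set of 2D points (pixel units), the
#' aperture radius `R`, the minimum pairwise spacing `delta` enforced at
#' generation time, the seed it was generated from (or `NA` for externally
#' loaded patterns) and a `pattern_id` label. The origin is the aperture
#' centre and y increases upward.
#'
#' @param points numeric n x 2 matrix of (x, y) coordinates.
#' @param R aperture radius in pixels.
#' @param delta minimum pairwise spacing in pixels.
#' @param seed integer seed or `NA`.
#' @param pattern_id character label.
#' @return An object of class `point_config`.
#' @export
point_config <- function(points, R, delta, seed = NA_integer_,
                         pattern_id = "pattern") {
  points <- as.matrix(points)
  stopifnot(is.numeric(points), ncol(points) == 2, nrow(points) >= 1)
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(
    list(points = points, n = nrow(points), R = R, delta = delta,
         seed = seed, pattern_id = as.character(pattern_id)),
    class = "point_config")
}

#' @export
print.point_config <- function(x, ...) {
  cat(sprintf("point_config '%s': n = %d, R = %g px, delta = %g px, seed = %s\n",
              x$pattern_id, x$n, x$R, x$delta,
              ifelse(is.na(x$seed), "<none>", as.character(x$seed))))
  invisible(x)
}

#' Minimum pairwise distance of a configuration
#'
#' @param config a [point_config()].
#' @return smallest pairwise Euclidean distance (``Inf`` for n = 1).
#' @export
min_spacing <- function(config) {
  if (config$n < 2) return(Inf)
  min(stats::dist(config$points))
}

#' Derive a reproducible sub-seed from a master seed
#'
#' A small multiplicative congruential scramble modulo the Mersenne prime
#' \eqn{2^{31} - 1}: each additional key folds into the state, so any
#' single pattern (or any stochastic sweep cell) can be regenerated from
#' the master seed and its indices alone, without touching the rest of the
#' study. Always returns a positive integer below \eqn{2^{31}}.
#'
#' @param master integer master seed.
#' @param ... integer keys (numerosity, replicate index, ...).
#' @return a positive integer seed.
#' @export
derive_seed <- function(master, ...) {
  p <- 2147483647
  x <- as.numeric(master) %% p
  for (k in as.numeric(c(...))) {
    x <- (x * 48271 + (k %% p) + 1) %% p
  }
  as.integer(x %% (p - 1) + 1)
}

#' Generate one random dot pattern by rejection sampling
#'
#' Candidate points are drawn uniformly in the bounding square
#' \eqn{[-R, R]^2} and accepted only if they fall inside the circular
#' aperture of radius `R` and are at distance at least `delta` from every
#' previously accepted point. Identical `(n, R, delta, seed)` reproduce
#' identical coordinates.
#'
#' @param n number of dots (>= 1).
#' @param R aperture radius in pixels (default 160, i.e. about 5 degrees of
#'   visual angle on a typical display at 57 cm).
#' @param delta minimum pairwise spacing in pixels (default `R/16`).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param max_attempts cap on candidate draws for the whole pattern; if it
#'   is exhausted before `n` points are placed a `numgraph_packing_error`
#'   is signalled (the requested n/delta/R combination is too tight).
#' @param pattern_id label stored on the result.
#' @return A [point_config()].
#' @export
generate_pattern <- function(n, R = 160, delta = R / 16, seed = NULL,
                             max_attempts = 1e5, pattern_id = "pattern") {
  stopifnot(n >= 1, delta >= 0, R > 0, max_attempts >= n)
  if (!is.null(seed)) set.seed(seed)
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  attempts <- 0L
  d2min <- delta^2
  while (placed < n) {
    if (attempts >= max_attempts) {
      stop(structure(
        class = c("numgraph_packing_error", "error", "condition"),
        list(message = sprintf(
          "failed to place %d points (placed %d) within %d candidate draws; n = %d, delta = %g, R = %g is likely infeasible",
          n, placed, as.integer(max_attempts), n, delta, R),
          call = sys.call(-1))))
    }
    attempts <- attempts + 1L
    x <- stats::runif(1, -R, R)
    y <- stats::runif(1, -R, R)
    if (x * x + y * y > R * R) next
    if (placed > 0L && delta > 0) {
      dx <- pts[seq_len(placed), 1L] - x
      dy <- pts[seq_len(placed), 2L] - y
      if (min(dx * dx + dy * dy) < d2min) next
    }
    placed <- placed + 1L
    pts[placed, ] <- c(x, y)
  }
  point_config(pts, R = R, delta = delta,
               seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
               pattern_id = pattern_id)
}

#' Generate the full study set of patterns
#'
#' Produces `patterns_per_n` independently seeded configurations for each
#' numerosity. Every pattern's sub-seed is derived deterministically from
#' the master seed, its numerosity and its replicate index, so any single
#' pattern can be regenerated in isolation.
#'
#' @param numerosities integer vector of dot counts (study default
#'   `c(22, 28, 34, 40)`).
#' @param patterns_per_n replicates per numerosity (study default 1000).
#' @inheritParams generate_pattern
#' @param seed master seed.
#' @return list of [point_config()]; `pattern_id` is `"n<k>_r<i>"`.
#' @export
generate_study_set <- function(numerosities = c(22, 28, 34, 40),
                               patterns_per_n = 1000,
                               R = 160, delta = R / 16, seed = 1,
                               max_attempts = 1e5) {
  stopifnot(length(numerosities) >= 1, patterns_per_n >= 1)
  out <- vector("list", length(numerosities) * patterns_per_n)
  k <- 0L
  for (n in numerosities) {
    for (i in seq_len(patterns_per_n)) {
      k <- k + 1L
      out[[k]] <- generate_pattern(
        n = n, R = R, delta = delta,
        seed = derive_seed(seed, n, i),
        max_attempts = max_attempts,
        pattern_id = sprintf("n%d_r%04d", n, i))
    }
  }
  out
}

#' Monte-Carlo estimate of the close-pair probability
#'
#' Estimates \eqn{P(\|U - V\| \le \delta)} for two independent points drawn
#' uniformly on the disk of radius `R`. At the study parameters
#' (`R = 160`, `delta = R/16`) this probability is about 0.0038, which is
#' what makes the spacing rejection cheap.
#'
#' @param R disk radius.
#' @param delta distance threshold, `0 < delta <= 2R`.
#' @param n_samples number of point pairs.
#' @param seed optional seed.
#' @return estimated probability, with attribute `"se"` holding the
#'   binomial standard error.
#' @export
pair_proximity_probability <- function(R = 160, delta = R / 16,
                                       n_samples = 1e6, seed = NULL) {
  stopifnot(delta > 0, delta <= 2 * R, n_samples >= 1)
  if (!is.null(seed)) set.seed(seed)
  hits <- 0
  remaining <- n_samples
  batch <- 250000L
  while (remaining > 0) {
    m <- min(batch, remaining)
    r1 <- R * sqrt(stats::runif(m)); t1 <- stats::runif(m, 0, 2 * pi)
    r2 <- R * sqrt(stats::runif(m)); t2 <- stats::runif(m, 0, 2 * pi)
    dx <- r1 * cos(t1) - r2 * cos(t2)
    dy <- r1 * sin(t1) - r2 * sin(t2)
    hits <- hits + sum(dx * dx + dy * dy <= delta^2)
    remaining <- remaining - m
  }
  p <- hits / n_samples
  attr(p, "se") <- sqrt(p * (1 - p) / n_samples)
  p
}

#' Read and write pattern files
#'
#' Patterns are exchanged as flat CSV (`pattern_id, n, x, y`, one row per
#' point) or as JSON records that keep the full metadata
#' (`pattern_id, n, R, delta, seed, points`).
#'
#' @param configs list of [point_config()] (or a single one).
#' @param file path.
#' @name pattern_io
NULL

#' @rdname pattern_io
#' @export
write_patterns_csv <- function(configs, file) {
  if (inherits(configs, "point_config")) configs <- list(configs)
  rows <- do.call(rbind, lapply(configs, function(cf) {
    data.frame(pattern_id = cf$pattern_id, n = cf$n,
               x = cf$points[, 1], y = cf$points[, 2])
  }))
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}

#' @rdname pattern_io
#' @param R,delta aperture radius and spacing to attach to patterns read
#'   from CSV (the flat format does not store them).
#' @export
read_patterns_csv <- function(file, R = 160, delta = R / 16) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("pattern_id", "x", "y") %in% names(df)))
  lapply(split(df, factor(df$pattern_id, levels = unique(df$pattern_id))),
         function(g) point_config(cbind(g$x, g$y), R = R, delta = delta,
                                  pattern_id = g$pattern_id[1]))
}

#' @rdname pattern_io
#' @export
write_patterns_json <- function(configs, file) {
  if (inherits(configs, "point_config")) configs <- list(configs)
  recs <- lapply(configs, function(cf) {
    list(pattern_id = cf$pattern_id, n = cf$n, R = cf$R, delta = cf$delta,
         seed = if (is.na(cf$seed)) NULL else cf$seed,
         points = unname(apply(cf$points, 1, as.numeric, simplify = FALSE)))
  })
  jsonlite::write_json(recs, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname pattern_io
#' @export
read_patterns_json <- function(file) {
  recs <- jsonlite::read_json(file)
  lapply(recs, function(r) {
    pts <- do.call(rbind, lapply(r$points, as.numeric))
    point_config(pts, R = r$R, delta = r$delta,
                 seed = if (is.null(r$seed)) NA_integer_ else as.integer(r$seed),
                 pattern_id = r$pattern_id)
  })
}
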