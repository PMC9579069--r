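#' Pearson correlation matrix with significance masking
#'
#' Pairwise Pearson coefficients with two-tailed p-values from the
#' t-distribution on \eqn{n_{pair} - 2} degrees of freedom, where
#' \eqn{n_{pair}} is the number of complete observation pairs for that
#' entry (missing values, e.g. EG on disconnected graphs, are excluded
#' pairwise). Entries with `p > alpha` are flagged in the mask (they are
#' reported, not deleted). A column with zero variance is an error naming
#' the offending index: saturated indices must be caught explicitly, not
#' silently correlated.
#'
#' @param data numeric matrix or data.frame, observations x indices.
#' @param alpha significance level for the mask (default 0.05).
#' @return object of class `cor_mask`: list with `labels`, `r`, `p`,
#'   `mask`, `n_obs`, `alpha`, `context`.
#' @param context free-form label (e.g. the numerosity and distance).
#' @export
pearson_with_mask <- function(data, alpha = 0.05, context = NULL) {
  X <- as.matrix(data)
  stopifnot(is.numeric(X), nrow(X) >= 3, ncol(X) >= 2)
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0 | is.na(sds))) {
    bad <- colnames(X)[sds == 0 | is.na(sds)]
    stop(structure(class = c("numgraph_zero_variance_error", "error",
                             "condition"),
                   list(message = sprintf(
                     "zero-variance column(s): %s (saturated index cannot be correlated)",
                     paste(bad, collapse = ", ")), call = sys.call(-1))))
  }
  ok <- (!is.na(X)) * 1
  npair <- crossprod(ok)               # complete pairs per entry
  r <- stats::cor(X, use = "pairwise.complete.obs")
  r[r > 1] <- 1; r[r < -1] <- -1
  df <- pmax(npair - 2, 1)
  tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = df)
  p[abs(r) >= 1 - 1e-15] <- 0
  diag(p) <- 0
  structure(list(labels = colnames(X), r = r, p = p, mask = p > alpha,
                 n_obs = nrow(X), n_pair = npair, alpha = alpha,
                 context = context),
            class = "cor_mask")
}

#' @export
print.cor_mask <- function(x, digits = 2, ...) {
  cat(sprintf("Pearson correlations (%d observations%s); '.' = p > %g\n",
              x$n_obs,
              if (is.null(x$context)) "" else paste0(", ", x$context),
              x$alpha))
  disp <- formatC(x$r, format = "f", digits = digits, width = digits + 4)
  disp[x$mask] <- format(".", width = digits + 4)
  dimnames(disp) <- dimnames(x$r)
  print(disp, quote = FALSE)
  invisible(x)
}

#' Max-SD correlation matrix
#'
#' Correlates the per-pattern index values taken at each index's own
#' maximum-standard-deviation distance (each column comes from a
#' different \eqn{G_{d_m}}, but from the same patterns).
#'
#' @param sel a [max_sd_selection()].
#' @inheritParams pearson_with_mask
#' @return a `cor_mask`.
#' @export
max_sd_correlations <- function(sel, alpha = 0.05) {
  stopifnot(inherits(sel, "max_sd_selection"))
  pearson_with_mask(attr(sel, "values"), alpha = alpha, context = "max-SD")
}

#' PCA with varimax rotation of the max-SD dataset
#'
#' Eigendecomposition of the correlation matrix of the (standardized)
#' max-SD index values, followed by varimax rotation of the retained
#' components with Kaiser row normalization. The random-walk index is
#' excluded by default — it correlates with nothing and only adds noise to
#' the rotation. Loadings with magnitude at or below the suppression
#' threshold are flagged for display but kept at full precision. Each
#' rotated component is oriented so that its largest-magnitude loading is
#' positive.
#'
#' @param sel a [max_sd_selection()] or a plain observations x variables
#'   matrix.
#' @param n_components components to retain and rotate (default 2).
#' @param exclude indices dropped before the PCA (default `"RW"`).
#' @param use_correlation if `FALSE`, decompose the covariance matrix of
#'   the raw values instead (the indices then enter on unequal scales).
#' @param suppression_threshold display cut for small loadings
#'   (default 0.3).
#' @return object of class `pca_varimax`: list with `eigenvalues`,
#'   `cumulative_variance` (percent), `loadings_rotated`,
#'   `loadings_unrotated`, `rotation_matrix`, `included_indices`,
#'   `n_components`, `suppression_threshold`, `suppressed` (logical
#'   matrix).
#' @export
pca_varimax <- function(sel, n_components = 2, exclude = "RW",
                        use_correlation = TRUE,
                        suppression_threshold = 0.3) {
  X <- if (inherits(sel, "max_sd_selection")) attr(sel, "values") else as.matrix(sel)
  X <- X[, setdiff(colnames(X), exclude), drop = FALSE]
  stopifnot(n_components >= 2, ncol(X) > n_components,
            nrow(X) > ncol(X))
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0 | is.na(sds)))
    stop(structure(class = c("numgraph_zero_variance_error", "error",
                             "condition"),
                   list(message = sprintf(
                     "zero-variance variable(s): %s",
                     paste(colnames(X)[sds == 0 | is.na(sds)], collapse = ", ")),
                     call = sys.call(-1))))
  S <- if (use_correlation) stats::cor(X, use = "pairwise.complete.obs")
       else stats::cov(X, use = "pairwise.complete.obs")
  eig <- eigen(S, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  cumvar <- 100 * cumsum(ev) / sum(ev)
  L <- eig$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(n_components)]), n_components)
  rownames(L) <- colnames(X)
  vm <- stats::varimax(L, normalize = TRUE)   # Kaiser row normalization
  Lr <- unclass(vm$loadings)
  # orient: largest-magnitude loading of each component positive
  for (j in seq_len(ncol(Lr))) {
    k <- which.max(abs(Lr[, j]))
    if (Lr[k, j] < 0) Lr[, j] <- -Lr[, j]
  }
  colnames(Lr) <- paste0("PC", seq_len(n_components))
  structure(list(eigenvalues = ev,
                 cumulative_variance = cumvar,
                 loadings_rotated = Lr,
                 loadings_unrotated = L,
                 rotation_matrix = vm$rotmat,
                 included_indices = colnames(X),
                 n_components = n_components,
                 suppression_threshold = suppression_threshold,
                 suppressed = abs(Lr) <= suppression_threshold),
            class = "pca_varimax")
}

#' @export
print.pca_varimax <- function(x, digits = 2, ...) {
  k <- x$n_components
  cat(sprintf("PCA (varimax, %d components of %d variables)\n",
              k, length(x$included_indices)))
  cat("eigenvalues:", paste(formatC(x$eigenvalues, format = "f", digits = 2),
                            collapse = " "), "\n")
  cat(sprintf("cumulative variance at %d components: %.1f%%\n",
              k, x$cumulative_variance[k]))
  disp <- formatC(x$loadings_rotated, format = "f", digits = digits,
                  width = digits + 5)
  disp[x$suppressed] <- format("", width = digits + 5)
  print(disp, quote = FALSE)
  invisible(x)
}

#' Export a correlation matrix as CSV and heatmap image
#'
#' Writes the coefficients, p-values and mask to CSV at full precision,
#' and renders a heatmap with masked (non-significant) cells greyed out.
#'
#' @param cm a `cor_mask`.
#' @param file_csv CSV path (mask written next to it as
#'   `<file>.mask.csv`).
#' @param file_image optional PNG path; skipped when `NULL`.
#' @export
heatmap_export <- function(cm, file_csv, file_image = NULL) {
  stopifnot(inherits(cm, "cor_mask"))
  utils::write.csv(as.data.frame(cm$r), file_csv, row.names = TRUE)
  utils::write.csv(as.data.frame(cm$mask),
                   paste0(file_csv, ".mask.csv"), row.names = TRUE)
  if (!is.null(file_image)) {
    k <- length(cm$labels)
    grDevices::png(file_image, width = 640, height = 640)
    on.exit(grDevices::dev.off(), add = TRUE)
    z <- cm$r
    z[cm$mask] <- NA      # masked cells rendered as background grey
    graphics::par(mar = c(5, 5, 2, 1))
    graphics::image(seq_len(k), seq_len(k), t(z[k:1, , drop = FALSE]),
                    zlim = c(-1, 1), axes = FALSE, xlab = "", ylab = "",
                    col = grDevices::hcl.colors(64, "Blue-Red 3"),
                    useRaster = FALSE)
    graphics::rect(0.5, 0.5, k + 0.5, k + 0.5, col = NA, border = "grey40")
    graphics::axis(1, at = seq_len(k), labels = cm$labels, las = 2)
    graphics::axis(2, at = seq_len(k), labels = rev(cm$labels), las = 1)
  }
  invisible(file_csv)
}

#' Re-read an exported correlation matrix
#'
#' @param file_csv path written by [heatmap_export()].
#' @return numeric matrix of coefficients.
#' @export
read_correlation_csv <- function(file_csv) {
  df <- utils::read.csv(file_csv, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
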