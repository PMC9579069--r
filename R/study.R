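#' Run the full distance-sweep study for one numerosity
#'
#' Generates patterns, sweeps the requested indices over the distance
#' grid, selects the per-index maximum-standard-deviation distances,
#' computes the max-SD correlation matrix and the varimax PCA. The
#' scaled-down mode (default) uses 200 patterns and a grid step of 10 px;
#' the full mode uses 1000 patterns and a step of 5 px.
#'
#' The random-walk index is excluded by default: its simulation cost
#' dominates a full sweep, it is zero wherever the graph is disconnected,
#' and the PCA omits it in any case. Include `"RW"` in `indices` to sweep
#' it too.
#'
#' @param n numerosity (dots per pattern).
#' @param patterns_per_n replicates (200 scaled-down, 1000 full).
#' @param R aperture radius in pixels.
#' @param delta minimum spacing in pixels.
#' @param step grid step in pixels.
#' @param indices index names to sweep.
#' @param seed master seed for generation and stochastic indices.
#' @param walks random-walk replicates (only used if RW is swept).
#' @param full if `TRUE`, use the full study size (1000 patterns, step 5);
#'   overrides `patterns_per_n` and `step`.
#' @param progress report progress while sweeping.
#' @return list with `configs`, `table` (index table), `selection`
#'   (max-SD), `maxsd_table`, `correlations` (`cor_mask`), `pca`
#'   (`pca_varimax`), `connectivity_threshold`.
#' @export
run_study <- function(n = 22, patterns_per_n = 200, R = 160,
                      delta = R / 16, step = 10,
                      indices = setdiff(INDEX_NAMES, "RW"),
                      seed = 1, walks = 1000, full = FALSE,
                      progress = FALSE) {
  if (full) { patterns_per_n <- 1000; step <- 5 }
  configs <- generate_study_set(n, patterns_per_n, R = R, delta = delta,
                                seed = seed)
  grid <- d_grid_default(R = R, delta = delta, step = step)
  table <- sweep_indices(configs, grid, indices = indices, walks = walks,
                         seed = derive_seed(seed, 7L), progress = progress)
  sel <- max_sd_selection(table)
  cm <- max_sd_correlations(sel)
  pca <- pca_varimax(sel)
  list(configs = configs, table = table, selection = sel,
       maxsd_table = max_sd_table(sel, R = R), correlations = cm,
       pca = pca,
       connectivity_threshold = connectivity_threshold(configs, grid))
}

#' Write the study result tables
#'
#' Emits `maxsd.csv` (index, d_m, d_m/R, sigma), `eigen.csv` (component,
#' eigenvalue, cumulative percent), `loadings.csv` (index, component,
#' loading, suppressed flag) and the correlation heatmap files into
#' `outdir`.
#'
#' @param study a [run_study()] result.
#' @param outdir output directory (created if needed).
#' @export
write_study_tables <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$maxsd_table, file.path(outdir, "maxsd.csv"),
                   row.names = FALSE)
  pca <- study$pca
  utils::write.csv(
    data.frame(component = seq_along(pca$eigenvalues),
               eigenvalue = pca$eigenvalues,
               cumulative_pct = pca$cumulative_variance),
    file.path(outdir, "eigen.csv"), row.names = FALSE)
  L <- pca$loadings_rotated
  utils::write.csv(
    data.frame(index = rep(rownames(L), ncol(L)),
               component = rep(colnames(L), each = nrow(L)),
               loading = as.vector(L),
               suppressed = as.vector(pca$suppressed)),
    file.path(outdir, "loadings.csv"), row.names = FALSE)
  heatmap_export(study$correlations, file.path(outdir, "maxsd_cor.csv"),
                 file.path(outdir, "maxsd_cor.png"))
  invisible(outdir)
}
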