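#' Pipeline configuration
#'
#' Collects every tunable parameter of the trajectory pipeline in one
#' validated list. Defaults reproduce the analysis conditions the pipeline
#' was designed around: hourly imaging over four days, a 20,000-object
#' geometric sketch, graph clustering with 40 nearest neighbours, and the
#' published sequence-filtering rules.
#'
#' @param imaging_interval_h Hours between consecutive frames (default 1).
#' @param max_time_h Data beyond this time are discarded during filtering
#'   (default 96 h; later frames are dominated by object merging).
#' @param feature_subset Character vector of non-redundant feature columns
#'   used for state identification: size (`Area`), shape (Zernike moments)
#'   and movement (`Displacement`, `DistanceTraveled`, `IntegratedDistance`,
#'   `Linearity`).
#' @param sketch_size Number of objects retained by geometric sketching
#'   before state clustering (default 20000).
#' @param knn_k Nearest-neighbour count for graph community detection
#'   (default 40), used both for states and trajectories.
#' @param mca_dims Number of multiple-correspondence-analysis dimensions
#'   kept for sequence clustering (default 50).
#' @param min_presence_time_h Sequences without an observed record at this
#'   time are excluded (default 20 h).
#' @param max_consecutive_missing Longest tolerated run of missing states in
#'   a retained sequence (default 2 frames).
#' @param motif_interval_h Width of the time bins used for motifs and for
#'   aggregated transition tables (default 12 h).
#' @param transition_window_h Width of the sliding window over which
#'   state-to-state transitions are counted (default 2 h).
#' @param transition_min_freq Transitions below this within-interval
#'   proportion are dropped from transition tables (default 0.02).
#' @param n_nearest_outlines Number of group members, nearest the group mean
#'   in feature space, whose outlines compete to represent the group
#'   (default 30).
#' @param outline_match_tol_px Centroid-matching tolerance when linking
#'   outlines to table records (default 5 px).
#' @param boundary_points Number of equidistant arc-length points used to
#'   resample an outline before its power spectrum is taken (default 128).
#' @param community_method `"louvain"` (default) or `"leiden"` modularity
#'   community detection on the Jaccard-weighted neighbour graph.
#' @param rng_seed Seed applied before every stochastic step.
#'
#' @return A named list with class `"pt_config"`.
#' @export
pipeline_config <- function(imaging_interval_h = 1,
                            max_time_h = 96,
                            feature_subset = pt_default_features(),
                            sketch_size = 20000,
                            knn_k = 40,
                            mca_dims = 50,
                            min_presence_time_h = 20,
                            max_consecutive_missing = 2,
                            motif_interval_h = 12,
                            transition_window_h = 2,
                            transition_min_freq = 0.02,
                            n_nearest_outlines = 30,
                            outline_match_tol_px = 5,
                            boundary_points = 128,
                            community_method = c("louvain", "leiden"),
                            rng_seed = 1L) {
  cfg <- list(
    imaging_interval_h = imaging_interval_h,
    max_time_h = max_time_h,
    feature_subset = feature_subset,
    sketch_size = as.integer(sketch_size),
    knn_k = as.integer(knn_k),
    mca_dims = as.integer(mca_dims),
    min_presence_time_h = min_presence_time_h,
    max_consecutive_missing = as.integer(max_consecutive_missing),
    motif_interval_h = motif_interval_h,
    transition_window_h = transition_window_h,
    transition_min_freq = transition_min_freq,
    n_nearest_outlines = as.integer(n_nearest_outlines),
    outline_match_tol_px = outline_match_tol_px,
    boundary_points = as.integer(boundary_points),
    community_method = match.arg(community_method),
    rng_seed = as.integer(rng_seed)
  )
  num <- c("imaging_interval_h", "max_time_h", "sketch_size", "knn_k",
           "mca_dims", "min_presence_time_h", "motif_interval_h",
           "transition_window_h", "n_nearest_outlines", "boundary_points")
  for (nm in num) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0) {
      stop("config field '", nm, "' must be a single positive number")
    }
  }
  if (cfg$transition_min_freq < 0 || cfg$transition_min_freq >= 1) {
    stop("transition_min_freq must lie in [0, 1)")
  }
  if (cfg$max_consecutive_missing < 0) {
    stop("max_consecutive_missing must be non-negative")
  }
  structure(cfg, class = "pt_config")
}

#' @export
print.pt_config <- function(x, ...) {
  cat("phenotraject pipeline configuration\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-24s %s\n", nm, paste(val, collapse = ", ")))
  }
  invisible(x)
}
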