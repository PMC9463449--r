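#' Geometric sketching: density-equalising subsampling
#'
#' Selects a subset of records that covers the occupied volume of feature
#' space evenly rather than proportionally to density, so rare morphologies
#' survive subsampling. The standardised features are projected by PCA, the
#' projection is partitioned into equal-volume hypercubes, and points are
#' drawn uniformly across the occupied cubes (one per cube per round, in
#' random cube order) until the sketch is full.
#'
#' @param records Track table with z-scored features ([zscore_features()]).
#' @param feature_subset Feature columns defining the space.
#' @param sketch_size Number of records to retain.
#' @param seed RNG seed; fixed seed gives an identical index set.
#' @param n_pcs Number of principal components used for the covering
#'   (default: all, capped at 10).
#' @return Sorted integer vector of row indices into `records`.
#' @export
geometric_sketch <- function(records, feature_subset, sketch_size,
                             seed = 1L, n_pcs = 10L) {
  X <- feature_matrix(records, feature_subset)
  ok <- which(complete.cases(X))
  n <- length(ok)
  if (sketch_size >= n) {
    if (sketch_size > n) warning("sketch_size exceeds usable record count; returning all")
    return(ok)
  }
  Xo <- X[ok, , drop = FALSE]
  npc <- min(ncol(Xo), n_pcs, n - 1)
  pc <- prcomp(Xo, center = TRUE, scale. = FALSE)$x[, seq_len(npc), drop = FALSE]
  rng <- apply(pc, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  maxspan <- max(span)

  occupied_cells <- function(b) {
    side <- maxspan / b
    idx <- floor(sweep(pc, 2, rng[1, ], "-") / side)
    # points exactly on the upper boundary fall into the last cell
    idx <- pmin(idx, matrix(floor(span / side), nrow(idx), ncol(idx), byrow = TRUE))
    do.call(paste, c(as.data.frame(idx), sep = "|"))
  }
  # smallest resolution whose occupied-cube count reaches the sketch size
  lo <- 1L; hi <- 2L
  while (length(unique(occupied_cells(hi))) < sketch_size && hi < 2^20) hi <- hi * 2L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (length(unique(occupied_cells(mid))) >= sketch_size) hi <- mid else lo <- mid + 1L
  }
  cells <- occupied_cells(lo)
  set.seed(seed)
  by_cell <- split(seq_len(n), cells)
  by_cell <- lapply(by_cell, function(v) if (length(v) > 1) sample(v) else v)
  by_cell <- by_cell[sample(length(by_cell))]
  picked <- integer(0)
  round <- 1L
  while (length(picked) < sketch_size) {
    layer <- unlist(lapply(by_cell, function(v)
      if (length(v) >= round) v[round] else NULL), use.names = FALSE)
    need <- sketch_size - length(picked)
    picked <- c(picked, layer[seq_len(min(need, length(layer)))])
    round <- round + 1L
  }
  sort(ok[picked])
}

make_state_labels <- function(n) {
  if (n <= 26) return(LETTERS[seq_len(n)])
  c(LETTERS, as.vector(t(outer(LETTERS, LETTERS, paste0))))[seq_len(n)]
}

# Community detection on a Jaccard-weighted k-nearest-neighbour graph:
# Euclidean kNN -> shared-neighbour Jaccard edge weights -> modularity
# optimisation (Louvain by default). Returns an integer community id per row.
knn_communities <- function(X, k, seed = 1L, method = c("louvain", "leiden")) {
  method <- match.arg(method)
  n <- nrow(X)
  if (n < k + 1) stop("need at least k + 1 = ", k + 1, " points, got ", n)
  nn <- .knn_brute(X, X, as.integer(k), TRUE)
  ed <- .jaccard_edges(nn)
  ed <- ed[ed$weight > 0, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    ed, directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  set.seed(seed)
  com <- if (method == "leiden") {
    igraph::cluster_leiden(g, objective_function = "modularity",
                           weights = igraph::E(g)$weight, n_iterations = 5)
  } else {
    igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  }
  as.integer(igraph::membership(com))
}

#' Identify morphological states on the sketched records
#'
#' Clusters the standardised feature vectors of the (sketched) records with
#' the shared-nearest-neighbour graph approach used for cytometry
#' phenotyping: a Euclidean k-nearest-neighbour graph is reweighted by the
#' Jaccard overlap of neighbour sets and partitioned by modularity
#' (Louvain) community detection. Communities are renamed A, B, C, ... by
#' decreasing size so runs are comparable.
#'
#' @param records Track table rows to cluster (typically the sketch).
#' @param feature_subset Feature columns (z-scored versions are used).
#' @param knn_k Neighbour count (default 40).
#' @param seed RNG seed.
#' @param method `"louvain"` (default) or `"leiden"`.
#' @return Factor of state labels, one per row of `records`.
#' @export
cluster_states <- function(records, feature_subset, knn_k = 40, seed = 1L,
                           method = "louvain") {
  X <- feature_matrix(records, feature_subset)
  if (anyNA(X)) stop("records with missing features cannot be clustered")
  memb <- knn_communities(X, knn_k, seed, method)
  relabel_by_size(memb, make_state_labels)
}

# rename integer communities by decreasing size using a label generator
relabel_by_size <- function(memb, labeller) {
  sizes <- sort(table(memb), decreasing = TRUE)
  new <- labeller(length(sizes))
  map <- setNames(new, names(sizes))
  factor(map[as.character(memb)], levels = new)
}

#' Propagate state labels from the sketch to every record
#'
#' Each unsketched record takes the majority state among its `knn_k`
#' nearest sketched neighbours (Euclidean distance on the standardised
#' feature subset); ties resolve toward the alphabetically smaller state.
#' Sketched records keep their cluster labels. Records with missing
#' features receive NA.
#'
#' @param records Full track table.
#' @param sketch_indices Row indices of the sketch.
#' @param sketch_labels Factor of state labels for the sketch rows.
#' @param feature_subset Feature columns.
#' @param knn_k Neighbour count for the vote.
#' @return Factor of state labels for every row of `records`.
#' @export
assign_remaining <- function(records, sketch_indices, sketch_labels,
                             feature_subset, knn_k = 40) {
  stopifnot(length(sketch_indices) == length(sketch_labels))
  X <- feature_matrix(records, feature_subset)
  lev <- levels(sketch_labels)
  out <- factor(rep(NA_character_, nrow(X)), levels = lev)
  out[sketch_indices] <- sketch_labels
  rest <- setdiff(which(complete.cases(X)), sketch_indices)
  if (length(rest) == 0) return(out)
  k <- min(knn_k, length(sketch_indices))
  nn <- .knn_brute(X[rest, , drop = FALSE],
                   X[sketch_indices, , drop = FALSE], as.integer(k), FALSE)
  lab_int <- as.integer(sketch_labels)
  votes <- matrix(lab_int[nn], nrow = nrow(nn))
  nlev <- length(lev)
  win <- apply(votes, 1, function(v) which.max(tabulate(v, nbins = nlev)))
  out[rest] <- factor(lev[win], levels = lev)
  out
}

#' Summarise states: per-state feature means and a 2-D centroid layout
#'
#' Computes the mean of every numeric feature per state, a PCA layout of
#' the state centroids (standardised feature space) for arranging states in
#' two dimensions, and per-state mean size (Area) and mean motility (mean
#' of the movement features) used to order and colour representative
#' outlines.
#'
#' @param records Track table.
#' @param state_labels Factor of per-record state labels.
#' @param feature_subset Feature columns used for centroids/layout.
#' @return List with `means` (tibble: state, n, one column per numeric
#'   feature, mean_area, mean_motility) and `layout` (tibble: state, PC1,
#'   PC2).
#' @export
summarize_states <- function(records, state_labels, feature_subset) {
  keep <- !is.na(state_labels)
  rec <- records[keep, , drop = FALSE]
  lab <- droplevels(state_labels[keep])
  num_cols <- names(rec)[vapply(rec, is.numeric, TRUE)]
  num_cols <- setdiff(num_cols, c("frame", "raw_track_label", "track_id",
                                  "replicate"))
  means <- do.call(rbind, lapply(levels(lab), function(s) {
    sub <- rec[lab == s, num_cols, drop = FALSE]
    cbind(data.frame(state = s, n = nrow(sub)),
          as.data.frame(t(colMeans(sub, na.rm = TRUE))))
  }))
  movement <- intersect(c("Displacement", "DistanceTraveled",
                          "IntegratedDistance", "Linearity"), num_cols)
  means$mean_area <- if ("Area" %in% num_cols) means$Area else NA_real_
  means$mean_motility <- if (length(movement)) {
    rowMeans(means[, movement, drop = FALSE])
  } else NA_real_
  cen <- t(vapply(levels(lab), function(s) {
    colMeans(feature_matrix(rec[lab == s, , drop = FALSE], feature_subset),
             na.rm = TRUE)
  }, numeric(length(feature_subset))))
  layout <- data.frame(state = levels(lab), PC1 = 0, PC2 = 0)
  if (nrow(cen) >= 2) {
    pc <- prcomp(cen, center = TRUE, scale. = FALSE)$x
    layout$PC1 <- pc[, 1]
    layout$PC2 <- if (ncol(pc) >= 2) pc[, 2] else 0
  }
  list(means = tibble::as_tibble(means), layout = tibble::as_tibble(layout))
}

#' Full state-identification stage
#'
#' Convenience wrapper running [geometric_sketch()], [cluster_states()],
#' [assign_remaining()] and [summarize_states()] under one configuration.
#'
#' @param records Track table with z-scored features.
#' @param config [pipeline_config()].
#' @return A `pt_state_model` list: `sketch_indices`, `state_labels`
#'   (per record), `n_states`, `summary`, `layout`, `knn_k`,
#'   `feature_subset`.
#' @export
fit_states <- function(records, config = pipeline_config()) {
  idx <- geometric_sketch(records, config$feature_subset,
                          config$sketch_size, seed = config$rng_seed)
  sk_lab <- cluster_states(records[idx, , drop = FALSE],
                           config$feature_subset, config$knn_k,
                           seed = config$rng_seed,
                           method = config$community_method)
  all_lab <- assign_remaining(records, idx, sk_lab, config$feature_subset,
                              config$knn_k)
  sm <- summarize_states(records, all_lab, config$feature_subset)
  structure(list(sketch_indices = idx, state_labels = all_lab,
                 n_states = nlevels(droplevels(sk_lab)),
                 summary = sm$means, layout = sm$layout,
                 knn_k = config$knn_k,
                 feature_subset = config$feature_subset),
            class = "pt_state_model")
}

#' @export
print.pt_state_model <- function(x, ...) {
  cat("State model:", x$n_states, "states over",
      length(x$state_labels), "records (sketch",
      length(x$sketch_indices), ", k =", x$knn_k, ")\n")
  print(table(x$state_labels))
  invisible(x)
}
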