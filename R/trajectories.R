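#' Rebuild per-track temporal state sequences
#'
#' Restores the temporal order of the per-record state labels: one ordered
#' sequence per corrected track, indexed by frame from 0 to the latest
#' frame present; frames without a record are missing entries.
#'
#' @param records Track table with corrected `track_id`.
#' @param state_labels Factor of per-record state labels (same length as
#'   `records`).
#' @param n_frames Sequence length; defaults to `max(frame) + 1`.
#' @return A `pt_sequences` object: list with `states` (character matrix,
#'   tracks x frames, NA = missing), `keys` (tibble of track keys) and
#'   `state_levels`.
#' @export
build_sequences <- function(records, state_labels, n_frames = NULL) {
  stopifnot(nrow(records) == length(state_labels))
  if (is.null(n_frames)) n_frames <- max(records$frame) + 1L
  key <- paste(records$experiment_id, records$well, records$position,
               records$track_id, sep = "\r")
  ukey <- unique(key)
  M <- matrix(NA_character_, length(ukey), n_frames,
              dimnames = list(ukey, NULL))
  M[cbind(match(key, ukey), records$frame + 1L)] <- as.character(state_labels)
  parts <- do.call(rbind, strsplit(ukey, "\r", fixed = TRUE))
  keys <- tibble::tibble(experiment_id = parts[, 1], well = parts[, 2],
                         position = parts[, 3],
                         track_id = as.integer(parts[, 4]))
  structure(list(states = M, keys = keys,
                 state_levels = levels(state_labels)),
            class = "pt_sequences")
}

#' @export
print.pt_sequences <- function(x, ...) {
  cat("State sequences:", nrow(x$states), "tracks x", ncol(x$states),
      "frames;", sum(is.na(x$states)), "missing entries\n")
  invisible(x)
}

subset_sequences <- function(seqs, rows = NULL, frames = NULL) {
  if (!is.null(rows)) {
    seqs$states <- seqs$states[rows, , drop = FALSE]
    seqs$keys <- seqs$keys[rows, , drop = FALSE]
  }
  if (!is.null(frames)) seqs$states <- seqs$states[, frames, drop = FALSE]
  seqs
}

longest_na_run <- function(v) {
  r <- rle(is.na(v))
  runs <- r$lengths[r$values]
  if (length(runs)) max(runs) else 0L
}

#' Filter and trim state sequences
#'
#' Applies the three sequence-quality rules, in order: (1) drop sequences
#' with no observed state at the frame corresponding to
#' `min_presence_time_h` (objects must exist early in imaging); (2) trim
#' all sequences at the point at which tracking has ceased for half of the
#' surviving objects — the retained length is the last frame at which more
#' than 50% of sequences still have an observation at or after it; (3)
#' drop sequences containing a run of more than `max_consecutive_missing`
#' missing entries within the trimmed window.
#'
#' @param seqs A `pt_sequences` object.
#' @param min_presence_time_h Required presence time (default 20 h).
#' @param max_consecutive_missing Longest tolerated missing run (default 2).
#' @param imaging_interval_h Hours per frame (default 1).
#' @return Trimmed `pt_sequences`; attribute `"filter_report"` carries the
#'   counts dropped at each rule and the trim length.
#' @export
filter_and_trim <- function(seqs, min_presence_time_h = 20,
                            max_consecutive_missing = 2,
                            imaging_interval_h = 1) {
  M <- seqs$states
  presence_frame <- as.integer(round(min_presence_time_h / imaging_interval_h)) + 1L
  if (presence_frame > ncol(M)) {
    stop("presence frame ", presence_frame - 1L, " beyond sequence length")
  }
  keep1 <- !is.na(M[, presence_frame])
  n_drop_presence <- sum(!keep1)
  M1 <- M[keep1, , drop = FALSE]
  if (nrow(M1) == 0) {
    stop("no sequences observed at t = ", min_presence_time_h, " h (",
         n_drop_presence, " dropped)")
  }
  last_obs <- apply(M1, 1, function(v) max(which(!is.na(v))))  # 1-based
  frac_alive <- vapply(seq_len(ncol(M1)),
                       function(f) mean(last_obs >= f), 0)
  alive <- which(frac_alive > 0.5)
  trim_to <- if (length(alive)) max(alive) else 1L
  M2 <- M1[, seq_len(trim_to), drop = FALSE]
  runs <- apply(M2, 1, longest_na_run)
  keep3 <- runs <= max_consecutive_missing
  n_drop_gaps <- sum(!keep3)
  if (!any(keep3)) {
    stop("no sequences survive filtering: ", n_drop_presence,
         " dropped at presence rule, ", n_drop_gaps, " at missing-run rule")
  }
  out <- subset_sequences(seqs, rows = which(keep1)[keep3],
                          frames = seq_len(trim_to))
  attr(out, "filter_report") <- list(
    n_in = nrow(M), n_dropped_presence = n_drop_presence,
    trim_length_frames = trim_to, n_dropped_missing_runs = n_drop_gaps,
    n_out = nrow(out$states))
  out
}

#' Impute missing sequence entries by reverse LOCF
#'
#' Each missing entry takes the value of the nearest subsequent observed
#' entry (next observation carried backward). A trailing gap with no later
#' observation is filled forward from the last observed state and logged;
#' such gaps cannot occur when trimming precedes imputation.
#'
#' @param seqs A `pt_sequences` object.
#' @return `pt_sequences` with no missing entries.
#' @export
impute_sequences <- function(seqs) {
  M <- seqs$states
  n_forward <- 0L
  for (i in seq_len(nrow(M))) {
    v <- M[i, ]
    if (all(is.na(v))) stop("sequence ", i, " is entirely missing")
    obs <- which(!is.na(v))
    # reverse LOCF: index of the next observation at or after each frame
    nxt <- obs[findInterval(seq_along(v), obs, left.open = TRUE) + 1L]
    filled <- v[ifelse(is.na(nxt), NA, nxt)]
    trailing <- is.na(filled)
    if (any(trailing)) {
      n_forward <- n_forward + 1L
      filled[trailing] <- v[max(obs)]
    }
    M[i, ] <- filled
  }
  if (n_forward > 0) {
    message("impute_sequences: ", n_forward,
            " trailing gap(s) filled forward from the last observation")
  }
  seqs$states <- M
  seqs
}

#' Multiple correspondence analysis of state sequences
#'
#' Converts the categorical sequences into numeric coordinates: each frame
#' is one categorical variable (levels = states observed at that frame),
#' the one-hot indicator matrix is built, and correspondence analysis is
#' performed on it (SVD of the standardised residuals of the indicator
#' table). Returns the principal row coordinates on the first `mca_dims`
#' axes; axes beyond the matrix rank are zero-padded so the width is fixed.
#'
#' @param seqs Complete (imputed) `pt_sequences`.
#' @param mca_dims Number of dimensions to keep (default 50).
#' @return Numeric matrix (sequences x mca_dims); attribute `"eig"` holds
#'   the principal inertias (squared singular values).
#' @export
mca_embed <- function(seqs, mca_dims = 50) {
  M <- seqs$states
  if (anyNA(M)) stop("sequences must be imputed before MCA")
  n <- nrow(M)
  if (n < 2) stop("need at least 2 sequences")
  # one-hot indicator matrix, one block per frame
  blocks <- lapply(seq_len(ncol(M)), function(j) {
    lev <- sort(unique(M[, j]))
    Z <- matrix(0L, n, length(lev),
                dimnames = list(NULL, paste0("f", j - 1, ".", lev)))
    Z[cbind(seq_len(n), match(M[, j], lev))] <- 1L
    Z
  })
  Z <- do.call(cbind, blocks)
  P <- Z / sum(Z)
  r <- rowSums(P); cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  sv <- svd(S)
  pos <- sv$d > 1e-12
  if (!any(pos)) {
    warning("all sequences identical: zero-variance MCA, returning zeros")
    out <- matrix(0, n, mca_dims)
    attr(out, "eig") <- numeric(0)
    return(out)
  }
  ndim <- min(mca_dims, sum(pos))
  coords <- (sv$u[, seq_len(ndim), drop = FALSE] *
               rep(sv$d[seq_len(ndim)], each = n)) / sqrt(r)
  out <- matrix(0, n, mca_dims)
  out[, seq_len(ndim)] <- coords
  attr(out, "eig") <- sv$d[pos]^2
  out
}

#' Cluster sequences into trajectories
#'
#' Applies the same Jaccard-weighted k-nearest-neighbour community
#' detection used for state identification to the MCA coordinates;
#' communities are renamed 1, 2, ... by decreasing size.
#'
#' @param coords Matrix from [mca_embed()].
#' @param knn_k Neighbour count (default 40).
#' @param seed RNG seed.
#' @param method `"louvain"` (default) or `"leiden"`.
#' @return Factor of trajectory labels (levels "1", "2", ...).
#' @export
cluster_trajectories <- function(coords, knn_k = 40, seed = 1L,
                                 method = "louvain") {
  memb <- knn_communities(coords, knn_k, seed, method)
  relabel_by_size(memb, function(n) as.character(seq_len(n)))
}

#' Full trajectory-identification stage
#'
#' Runs [filter_and_trim()], [impute_sequences()], [mca_embed()] and
#' [cluster_trajectories()] under one configuration and computes each
#' trajectory's consensus sequence.
#'
#' @param seqs `pt_sequences` from [build_sequences()].
#' @param config [pipeline_config()].
#' @return A `pt_trajectory_model` list: `sequences` (imputed
#'   `pt_sequences`), `raw_sequences` (trimmed, pre-imputation), `coords`,
#'   `trajectory_labels`, `consensus` (list of per-frame consensus state
#'   vectors), `filter_report`.
#' @export
fit_trajectories <- function(seqs, config = pipeline_config()) {
  trimmed <- filter_and_trim(seqs, config$min_presence_time_h,
                             config$max_consecutive_missing,
                             config$imaging_interval_h)
  report <- attr(trimmed, "filter_report")
  imputed <- impute_sequences(trimmed)
  coords <- mca_embed(imputed, config$mca_dims)
  lab <- cluster_trajectories(coords, config$knn_k, seed = config$rng_seed,
                              method = config$community_method)
  cons <- lapply(levels(lab), function(tr) {
    consensus_sequence(imputed$states[lab == tr, , drop = FALSE])
  })
  names(cons) <- levels(lab)
  structure(list(sequences = imputed, raw_sequences = trimmed,
                 coords = coords, trajectory_labels = lab,
                 consensus = cons, filter_report = report),
            class = "pt_trajectory_model")
}

#' @export
print.pt_trajectory_model <- function(x, ...) {
  cat("Trajectory model:", nlevels(x$trajectory_labels), "trajectories over",
      length(x$trajectory_labels), "sequences of length",
      ncol(x$sequences$states), "\n")
  print(table(x$trajectory_labels))
  invisible(x)
}
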