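#' Per-frame consensus state of a set of sequences
#'
#' The consensus is the most frequent state at each frame, ties resolved
#' toward the lexicographically smaller state label.
#'
#' @param states Character matrix (sequences x frames), NA allowed.
#' @return Character vector of length `ncol(states)`.
#' @export
consensus_sequence <- function(states) {
  apply(states, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(NA_character_)
    tb <- table(col)                      # names sorted, so first max wins
    names(tb)[which.max(tb)]
  })
}

interval_of <- function(frame0, imaging_interval_h, interval_h) {
  floor(frame0 * imaging_interval_h / interval_h)
}

#' Trajectory motifs: state frequencies per time interval
#'
#' For each trajectory and each time interval (default 12 h), computes the
#' frequency of every state among the member observations falling in the
#' interval (frequencies within an interval sum to 1) and the most frequent
#' state (lexicographic tie-break) — the sequence-logo representation of a
#' trajectory.
#'
#' @param seqs `pt_sequences` (imputed or raw; NA entries are ignored).
#' @param trajectory_labels Factor, one label per sequence.
#' @param motif_interval_h Interval width in hours (default 12).
#' @param imaging_interval_h Hours per frame (default 1).
#' @return List with `frequencies` (tibble: trajectory, interval_start_h,
#'   interval_end_h, state, frequency) and `top_states` (tibble:
#'   trajectory, interval_start_h, state).
#' @export
motif <- function(seqs, trajectory_labels, motif_interval_h = 12,
                  imaging_interval_h = 1) {
  M <- seqs$states
  stopifnot(nrow(M) == length(trajectory_labels))
  iv <- interval_of(seq_len(ncol(M)) - 1L, imaging_interval_h,
                    motif_interval_h)
  freq_rows <- list(); top_rows <- list()
  for (tr in levels(trajectory_labels)) {
    sub <- M[trajectory_labels == tr, , drop = FALSE]
    if (nrow(sub) == 0) stop("trajectory ", tr, " has no members")
    for (k in sort(unique(iv))) {
      vals <- as.vector(sub[, iv == k, drop = FALSE])
      vals <- vals[!is.na(vals)]
      if (!length(vals)) next
      tb <- table(vals) / length(vals)
      freq_rows[[length(freq_rows) + 1]] <- tibble::tibble(
        trajectory = tr, interval_start_h = k * motif_interval_h,
        interval_end_h = (k + 1) * motif_interval_h,
        state = names(tb), frequency = as.numeric(tb))
      top_rows[[length(top_rows) + 1]] <- tibble::tibble(
        trajectory = tr, interval_start_h = k * motif_interval_h,
        state = names(tb)[which.max(tb)])
    }
  }
  list(frequencies = dplyr::bind_rows(freq_rows),
       top_states = dplyr::bind_rows(top_rows))
}

#' State-transition proportions per time interval
#'
#' Counts ordered (state at t, state at t + 1 frame) pairs — including
#' self-pairs, i.e. state maintenance — within a sliding window (default
#' 2 h wide, stepping one frame), aggregates window counts into wider
#' intervals (default 12 h, by window start time), converts each
#' interval's counts to proportions, and drops entries below
#' `transition_min_freq`. Interior frame pairs are covered by several
#' windows; the per-interval normalisation makes the proportions invariant
#' to that multiplicity except at interval boundaries.
#'
#' @param seqs Complete `pt_sequences` (imputed).
#' @param trajectory_labels Factor, one label per sequence (use a constant
#'   factor for a global table).
#' @param transition_window_h Sliding-window width in hours (default 2).
#' @param motif_interval_h Aggregation interval in hours (default 12).
#' @param transition_min_freq Minimum within-interval proportion retained
#'   (default 0.02).
#' @param imaging_interval_h Hours per frame (default 1).
#' @return Tibble: trajectory, interval_start_h, from, to, proportion.
#' @export
transitions <- function(seqs, trajectory_labels, transition_window_h = 2,
                        motif_interval_h = 12, transition_min_freq = 0.02,
                        imaging_interval_h = 1) {
  M <- seqs$states
  if (anyNA(M)) stop("transition counting needs complete (imputed) sequences")
  L <- ncol(M)
  wf <- max(1L, as.integer(round(transition_window_h / imaging_interval_h)))
  if (L < 2) stop("sequences too short for transitions")
  lev <- sort(unique(as.vector(M)))
  S <- length(lev)
  out <- list()
  for (tr in levels(trajectory_labels)) {
    sub <- M[trajectory_labels == tr, , drop = FALSE]
    if (nrow(sub) == 0) next
    # pair counts at each frame step f: (state at f, state at f+1)
    pair_counts <- lapply(seq_len(L - 1), function(f) {
      tb <- table(factor(sub[, f], levels = lev),
                  factor(sub[, f + 1], levels = lev))
      matrix(tb, S, S)
    })
    acc <- list()
    for (s in 0:(L - 1 - wf)) {
      k <- interval_of(s, imaging_interval_h, motif_interval_h)
      key <- as.character(k)
      if (is.null(acc[[key]])) acc[[key]] <- matrix(0, S, S)
      for (f in (s + 1):(s + wf)) acc[[key]] <- acc[[key]] + pair_counts[[f]]
    }
    for (key in names(acc)) {
      cnt <- acc[[key]]
      tot <- sum(cnt)
      if (tot == 0) next
      prop <- cnt / tot
      keep <- which(prop >= transition_min_freq, arr.ind = TRUE)
      if (nrow(keep) == 0) next
      out[[length(out) + 1]] <- tibble::tibble(
        trajectory = tr,
        interval_start_h = as.numeric(key) * motif_interval_h,
        from = lev[keep[, 1]], to = lev[keep[, 2]],
        proportion = prop[keep])
    }
  }
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, trajectory, interval_start_h, from, to)
}

# map state labels onto single characters so edit distance can use strings
state_alphabet <- function(levels) {
  pool <- c(LETTERS, letters, as.character(0:9))
  if (length(levels) > length(pool)) stop("too many states for encoding")
  setNames(pool[seq_along(levels)], levels)
}

encode_seq <- function(v, alphabet) paste(alphabet[v], collapse = "")

#' Select the representative object of each trajectory
#'
#' The consensus sequence (per-frame most frequent state, computed on the
#' complete imputed sequences) defines the trajectory archetype. Each
#' member's raw sequence, with missing-classification frames removed, is
#' compared to the consensus by generalized Levenshtein edit distance
#' (unit costs, via [utils::adist()]); the member with the smallest
#' distance (highest inverse-distance score) represents the trajectory.
#' Ties resolve toward the lowest track key.
#'
#' @param model `pt_trajectory_model` from [fit_trajectories()].
#' @return Tibble: trajectory, experiment_id, well, position, track_id,
#'   edit_distance.
#' @export
representative_spheroid <- function(model) {
  lab <- model$trajectory_labels
  raw <- model$raw_sequences$states
  keys <- model$raw_sequences$keys
  alphabet <- state_alphabet(sort(unique(c(as.vector(raw),
                                           unlist(model$consensus)))))
  rows <- lapply(levels(lab), function(tr) {
    idx <- which(lab == tr)
    if (!length(idx)) stop("trajectory ", tr, " has no members")
    cons_str <- encode_seq(model$consensus[[tr]], alphabet)
    member_str <- vapply(idx, function(i) {
      v <- raw[i, ]
      encode_seq(v[!is.na(v)], alphabet)
    }, "")
    d <- as.vector(adist(member_str, cons_str))
    ord <- order(d, keys$experiment_id[idx], keys$well[idx],
                 keys$position[idx], keys$track_id[idx])
    best <- idx[ord[1]]
    tibble::tibble(trajectory = tr,
                   experiment_id = keys$experiment_id[best],
                   well = keys$well[best], position = keys$position[best],
                   track_id = keys$track_id[best],
                   edit_distance = min(d))
  })
  dplyr::bind_rows(rows)
}

#' Count class membership per sample and replicate
#'
#' Tabulates how many objects of each sample/replicate fall in each class
#' (a user-defined phenotype, a data-driven state, or a trajectory), the
#' basis for replicate-stratified enrichment tests. An optional time
#' interval stratifies the counts by `interval_start_h`.
#'
#' @param df Data frame with one row per counted unit (object-frame for
#'   states, track for trajectories) carrying `sample` and `replicate`
#'   columns.
#' @param class_col Name of the class column.
#' @param interval_h Optional interval width; requires a `time_h` column.
#' @return Tibble: (interval_start_h,) class, sample, replicate, n_in,
#'   n_total, proportion. `n_total` counts all classified units of that
#'   sample/replicate (and interval).
#' @export
quantify_classes <- function(df, class_col, interval_h = NULL) {
  stopifnot(all(c("sample", "replicate", class_col) %in% names(df)))
  df <- df[!is.na(df[[class_col]]), , drop = FALSE]
  df$..class <- as.character(df[[class_col]])
  if (!is.null(interval_h)) {
    stopifnot("time_h" %in% names(df))
    df$interval_start_h <- floor(df$time_h / interval_h) * interval_h
    grp <- c("interval_start_h", "sample", "replicate")
  } else {
    grp <- c("sample", "replicate")
  }
  totals <- dplyr::summarise(dplyr::group_by_at(df, grp),
                             n_total = dplyr::n(), .groups = "drop")
  counts <- dplyr::summarise(dplyr::group_by_at(df, c(grp, "..class")),
                             n_in = dplyr::n(), .groups = "drop")
  # complete the grid so absent classes count zero
  grid <- merge(unique(df[, grp, drop = FALSE]),
                data.frame(..class = sort(unique(df$..class))))
  out <- dplyr::left_join(grid, counts, by = c(grp, "..class"))
  out$n_in[is.na(out$n_in)] <- 0L
  out <- dplyr::left_join(out, totals, by = grp)
  out$proportion <- out$n_in / out$n_total
  names(out)[names(out) == "..class"] <- "class"
  tibble::as_tibble(out[do.call(order, out[, c(grp, "class")]), ])
}

#' Assemble a replicate-stratified 2x2xK table for one class
#'
#' Builds the contingency array feeding the stratified tests: rows = in
#' class / not in class, columns = comparison / reference sample, one
#' stratum per replicate.
#'
#' @param counts Output of [quantify_classes()] (non-interval form).
#' @param class Class to test.
#' @param comparison,reference Sample names.
#' @return 2 x 2 x K integer array with dimnames.
#' @export
stratified_table <- function(counts, class, comparison, reference) {
  reps <- sort(unique(counts$replicate[counts$sample %in%
                                         c(comparison, reference)]))
  arr <- array(0L, c(2, 2, length(reps)),
               dimnames = list(c("in_class", "not_in_class"),
                               c(comparison, reference),
                               as.character(reps)))
  for (ki in seq_along(reps)) {
    for (si in 1:2) {
      smp <- c(comparison, reference)[si]
      sub <- counts[counts$sample == smp & counts$replicate == reps[ki], ]
      n_in <- sum(sub$n_in[sub$class == class])
      n_tot <- if (nrow(sub)) sub$n_total[1] else 0L
      arr[1, si, ki] <- n_in
      arr[2, si, ki] <- n_tot - n_in
    }
  }
  arr
}
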