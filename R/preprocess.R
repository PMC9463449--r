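#' Filter records by time, track lifetime and sample
#'
#' @param records Track table.
#' @param max_time_h Keep records with `time_h <= max_time_h` (late frames
#'   are dominated by object merging). `Inf` disables.
#' @param min_lifetime Minimum number of frames a track must appear on (the
#'   track's lifetime) for its records to be kept. Applied after the time
#'   cut, using corrected `track_id` when present, raw labels otherwise.
#' @param samples Optional allow-list of sample names.
#' @return Filtered track table.
#' @export
filter_records <- function(records, max_time_h = 96, min_lifetime = 0,
                           samples = NULL) {
  out <- records[records$time_h <= max_time_h, , drop = FALSE]
  if (!is.null(samples)) {
    out <- out[out$sample %in% samples, , drop = FALSE]
  }
  if (min_lifetime > 0 && nrow(out) > 0) {
    idc <- if ("track_id" %in% names(out)) "track_id" else "raw_track_label"
    key <- paste(out$experiment_id, out$well, out$position, out[[idc]], sep = "\r")
    life <- table(key)
    out <- out[key %in% names(life)[life >= min_lifetime], , drop = FALSE]
  }
  if (nrow(out) == 0) message("filter_records: no records remain")
  out
}

#' Collapse binary classification columns into one class label
#'
#' Classifier exports carry one 0/1 column per user-defined class. Rows
#' with exactly one column set take that column's name as `user_class`;
#' rows with none or several set are left unclassified and counted.
#'
#' @param records Track table containing the listed binary columns.
#' @param class_columns Ordered character vector of class column names; the
#'   name becomes the class label.
#' @return `records` with a `user_class` column (NA where unresolvable).
#' @export
parse_user_classes <- function(records, class_columns) {
  miss <- setdiff(class_columns, names(records))
  if (length(miss)) stop("class column(s) absent: ", paste(miss, collapse = ", "))
  m <- as.matrix(records[, class_columns, drop = FALSE])
  if (!all(m %in% c(0, 1, NA))) stop("class columns must be binary 0/1")
  hits <- rowSums(m == 1, na.rm = TRUE)
  cls <- rep(NA_character_, nrow(records))
  one <- which(hits == 1)
  if (length(one)) {
    cls[one] <- class_columns[max.col(m[one, , drop = FALSE], ties.method = "first")]
  }
  n_bad <- sum(hits != 1)
  if (n_bad > 0) {
    message("parse_user_classes: ", n_bad,
            " row(s) with zero or multiple set classes left unclassified")
  }
  records$user_class <- cls
  records
}

#' Correct tracking labels at object splits
#'
#' Trackers hand the parent's label to every daughter when an object splits,
#' so one label can cover several concurrent objects. This pass assigns a
#' corrected `track_id` per lineage branch: within each (well, position),
#' when k > 1 records share a raw label at one frame, the largest-area
#' record keeps the parent's id and each other record receives a fresh id,
#' which then follows that branch through all later frames. Branch
#' continuity across frames is resolved by nearest centroid (greedy); area
#' ties at a split keep the parent id on the earlier row.
#'
#' @param records Track table with `raw_track_label`, `Area`, `center_x`,
#'   `center_y`.
#' @return `records` with a `track_id` column; row count and order are
#'   preserved. After correction each (well, position, track_id, frame)
#'   holds at most one record.
#' @export
correct_tracks <- function(records) {
  n <- nrow(records)
  records$track_id <- NA_integer_
  if (n == 0) return(records)
  grp <- paste(records$experiment_id, records$well, records$position, sep = "\r")
  n_splits <- 0L
  for (g in unique(grp)) {
    gi <- which(grp == g)
    sub <- records[gi, ]
    next_id <- max(sub$raw_track_label, na.rm = TRUE)
    ids <- rep(NA_integer_, length(gi))
    for (lab in unique(sub$raw_track_label)) {
      li <- which(sub$raw_track_label == lab)
      frames <- sort(unique(sub$frame[li]))
      # active branches: corrected id -> last known centroid
      active_id <- integer(0); last_x <- numeric(0); last_y <- numeric(0)
      for (f in frames) {
        ri <- li[sub$frame[li] == f]
        ri <- ri[order(ri)]                       # stable record order
        k <- length(ri)
        assigned <- rep(NA_integer_, k)
        if (length(active_id) == 0) {
          # first appearance of this raw label
          keep <- if (k > 1) which.max(sub$Area[ri]) else 1L
          assigned[keep] <- lab
          if (k > 1) n_splits <- n_splits + 1L
          for (j in setdiff(seq_len(k), keep)) {
            next_id <- next_id + 1L
            assigned[j] <- next_id
          }
        } else if (length(active_id) == 1 && k > 1) {
          # split event: largest area inherits the parent id
          keep <- which.max(sub$Area[ri])
          assigned[keep] <- active_id
          n_splits <- n_splits + 1L
          for (j in setdiff(seq_len(k), keep)) {
            next_id <- next_id + 1L
            assigned[j] <- next_id
          }
        } else {
          # continuity: greedy nearest-centroid matching to active branches
          dx <- outer(sub$center_x[ri], last_x, "-")
          dy <- outer(sub$center_y[ri], last_y, "-")
          d <- sqrt(dx^2 + dy^2)
          if (anyNA(d)) d[is.na(d)] <- 0
          ord <- order(d)
          used_r <- rep(FALSE, k); used_a <- rep(FALSE, length(active_id))
          for (o in ord) {
            r <- (o - 1) %% k + 1
            a <- (o - 1) %/% k + 1
            if (used_r[r] || used_a[a]) next
            assigned[r] <- active_id[a]
            used_r[r] <- TRUE; used_a[a] <- TRUE
          }
          extra <- which(!used_r)
          if (length(extra)) {
            n_splits <- n_splits + 1L
            for (j in extra) {
              next_id <- next_id + 1L
              assigned[j] <- next_id
            }
          }
        }
        ids[ri] <- assigned
        active_id <- assigned
        last_x <- sub$center_x[ri]; last_y <- sub$center_y[ri]
      }
    }
    records$track_id[gi] <- ids
  }
  if (n_splits > 0) {
    message("correct_tracks: resolved ", n_splits, " split event(s)")
  }
  stopifnot(nrow(records) == n)
  records
}

#' Add the bounding-box aspect ratio feature
#'
#' AspectRatio = Length / Width (>= 1 for length >= width). A zero or
#' missing width yields a missing value.
#'
#' @param records Track table with `Length` and `Width` columns.
#' @return `records` with an `AspectRatio` column.
#' @export
derive_features <- function(records) {
  if (!all(c("Length", "Width") %in% names(records))) {
    stop("derive_features needs Length and Width columns")
  }
  w <- records$Width
  bad <- !is.na(w) & w == 0
  ar <- records$Length / w
  ar[bad] <- NA_real_
  if (any(bad)) message("derive_features: ", sum(bad), " zero-width record(s)")
  records$AspectRatio <- ar
  records
}

#' Z-score measurement columns over the merged dataset
#'
#' Each listed column is standardised to (x - mean) / sd computed across
#' the whole table (all experiments pooled, so states stay comparable
#' across samples), with the sample (n - 1) standard deviation. Original
#' columns are retained; standardised values are written to `<name>_z`.
#'
#' @param records Track table.
#' @param feature_subset Columns to standardise.
#' @return `records` with added `<feature>_z` columns.
#' @export
zscore_features <- function(records, feature_subset) {
  miss <- setdiff(feature_subset, names(records))
  if (length(miss)) stop("feature column(s) absent: ", paste(miss, collapse = ", "))
  for (cn in feature_subset) {
    x <- records[[cn]]
    mu <- mean(x, na.rm = TRUE)
    s <- sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) {
      warning("zero-variance feature column: ", cn)
      z <- ifelse(is.na(x), NA_real_, 0)
    } else {
      z <- (x - mu) / s
    }
    records[[paste0(cn, "_z")]] <- z
  }
  records
}

zcols <- function(feature_subset) paste0(feature_subset, "_z")

# dense numeric matrix of the z-scored feature subset, rows = records
feature_matrix <- function(records, feature_subset, standardized = TRUE) {
  cols <- if (standardized) zcols(feature_subset) else feature_subset
  miss <- setdiff(cols, names(records))
  if (length(miss)) {
    stop("missing feature column(s): ", paste(miss, collapse = ", "),
         if (standardized) " (run zscore_features first)" else "")
  }
  as.matrix(records[, cols, drop = FALSE])
}
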