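#' Column-name dialect for measurement tables
#'
#' Tracked-object exports use versioned physical column names (for example
#' `AreaShape_Area` or `TrackObjects_Label_50` in CellProfiler 3.x output).
#' A dialect maps each canonical (semantic) column the pipeline needs to the
#' physical header it appears under. Entries whose physical column is absent
#' from a given file are simply skipped for the optional fields; required
#' fields must resolve.
#'
#' @param ... Named overrides, canonical name = physical name. Canonical
#'   names: `experiment_id`, `well`, `position`, `frame`,
#'   `raw_track_label`, `center_x`, `center_y`, plus any feature name
#'   (e.g. `Area = "AreaShape_Area"`).
#' @return Named character vector mapping canonical to physical names.
#' @export
cellprofiler_dialect <- function(...) {
  d <- c(
    experiment_id = "Metadata_Experiment",
    well = "Metadata_Well",
    position = "Metadata_Site",
    frame = "Metadata_Frame",
    raw_track_label = "TrackObjects_Label_50",
    center_x = "Location_Center_X",
    center_y = "Location_Center_Y",
    Area = "AreaShape_Area",
    Length = "AreaShape_MajorAxisLength",
    Width = "AreaShape_MinorAxisLength",
    Displacement = "TrackObjects_Displacement_50",
    DistanceTraveled = "TrackObjects_DistanceTraveled_50",
    IntegratedDistance = "TrackObjects_IntegratedDistance_50",
    Linearity = "TrackObjects_Linearity_50",
    Zernike_0_0 = "AreaShape_Zernike_0_0",
    Zernike_1_1 = "AreaShape_Zernike_1_1",
    Zernike_2_0 = "AreaShape_Zernike_2_0"
  )
  ov <- c(...)
  d[names(ov)] <- ov
  d
}

#' Identity dialect for tables already in canonical column names
#' @param ... Named overrides as in [cellprofiler_dialect()].
#' @return Named character vector.
#' @export
canonical_dialect <- function(...) {
  nms <- c(pt_meta_cols(), pt_default_features(), "Length", "Width")
  d <- setNames(nms, nms)
  ov <- c(...)
  d[names(ov)] <- ov
  d
}

#' Read a tracked-object measurement table
#'
#' Reads a long-format per-object per-timepoint table (one row per tracked
#' object per frame) and renames its columns to the canonical names via a
#' dialect. Numeric cells that fail to parse become missing values rather
#' than errors; the number of such cells is reported.
#'
#' @param path CSV file path (comma separated, header row, UTF-8).
#' @param dialect Named mapping canonical -> physical column names; see
#'   [cellprofiler_dialect()] and [canonical_dialect()].
#' @param imaging_interval_h Hours per frame, used to derive `time_h`.
#' @param frame_base Value of the first frame in the file (0 or 1); frames
#'   are shifted to 0-based.
#' @param class_columns Optional physical names of binary user-defined
#'   classification columns to carry through unchanged.
#' @return A tibble of object records: metadata columns `experiment_id`,
#'   `well`, `position`, `frame`, `time_h`, `raw_track_label`, `center_x`,
#'   `center_y`, plus every feature the dialect resolved and any
#'   classification columns.
#' @export
read_measurements <- function(path, dialect = cellprofiler_dialect(),
                              imaging_interval_h = 1, frame_base = 0,
                              class_columns = character()) {
  if (!file.exists(path)) stop("measurement file not found: ", path)
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) {
    warning("empty measurement file: ", path)
  }
  required <- c("well", "frame", "raw_track_label", "Area")
  for (cn in required) {
    phys <- dialect[[cn]]
    if (is.null(phys) || !phys %in% names(raw)) {
      stop("required column '", cn, "' (physical name '",
           if (is.null(phys)) "<unmapped>" else phys,
           "') absent from ", path)
    }
  }
  out <- tibble::tibble(.rows = nrow(raw))
  meta_chr <- c("experiment_id", "well", "position")
  n_bad <- 0L
  for (cn in names(dialect)) {
    phys <- dialect[[cn]]
    if (!phys %in% names(raw)) next
    col <- raw[[phys]]
    if (cn %in% meta_chr) {
      out[[cn]] <- as.character(col)
    } else {
      parsed <- suppressWarnings(as.numeric(col))
      n_bad <- n_bad + sum(is.na(parsed) & !is.na(col) &
                             !(trimws(as.character(col)) %in% c("", "NA")))
      out[[cn]] <- parsed
    }
  }
  if (!"experiment_id" %in% names(out)) out$experiment_id <- "exp1"
  if (!"position" %in% names(out)) out$position <- "1"
  out$frame <- as.integer(out$frame - frame_base)
  out$raw_track_label <- as.integer(out$raw_track_label)
  out$time_h <- out$frame * imaging_interval_h
  for (cc in class_columns) {
    if (!cc %in% names(raw)) stop("classification column '", cc,
                                  "' absent from ", path)
    out[[cc]] <- suppressWarnings(as.numeric(raw[[cc]]))
  }
  if (n_bad > 0) {
    message(n_bad, " unparseable numeric cell(s) set to missing in ", path)
  }
  front <- intersect(c(pt_meta_cols()[1:5], "time_h"), names(out))
  dplyr::relocate(out, dplyr::all_of(front))
}

#' Attach sample and replicate labels from an experimental key
#'
#' Joins each record's (experiment, well) onto a key table so every well is
#' labelled with its sample (treatment / cell line) and replicate index.
#' The operation is idempotent and leaves row count and order unchanged.
#'
#' @param records Tibble of object records (see [read_measurements()]).
#' @param key Tibble with columns `experiment_id`, `well`, `sample`,
#'   `replicate` (plus any covariates, carried through).
#' @return `records` with `sample`, `replicate` (and covariates) attached.
#' @export
merge_key <- function(records, key) {
  need <- c("experiment_id", "well", "sample", "replicate")
  miss <- setdiff(need, names(key))
  if (length(miss)) stop("key is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(key[, c("experiment_id", "well")])) {
    stop("key has duplicate (experiment_id, well) rows")
  }
  present <- unique(records[, c("experiment_id", "well")])
  keyed <- paste(key$experiment_id, key$well, sep = "\r")
  orphan <- present[!paste(present$experiment_id, present$well, sep = "\r") %in% keyed, ]
  if (nrow(orphan) > 0) {
    stop("well(s) absent from experimental key: ",
         paste(sprintf("%s/%s", orphan$experiment_id, orphan$well), collapse = ", "))
  }
  # drop any stale key columns so re-merging is idempotent
  drop <- setdiff(names(key), c("experiment_id", "well"))
  records <- records[, setdiff(names(records), drop)]
  out <- dplyr::left_join(records, key, by = c("experiment_id", "well"))
  stopifnot(nrow(out) == nrow(records))
  out
}

#' Write / read the canonical track table
#'
#' The track table is the pipeline's central artifact: one CSV row per
#' object per frame, canonical column names, corrected `track_id` once
#' preprocessing has run. Values round-trip bit-identically at the printed
#' precision (15 significant digits).
#'
#' @param records Track-table tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly (write); the tibble (read).
#' @export
write_track_table <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_track_table
#' @export
read_track_table <- function(path) {
  out <- tibble::as_tibble(read.csv(path, check.names = FALSE,
                                    stringsAsFactors = FALSE))
  for (cn in intersect(c("frame", "raw_track_label", "track_id", "replicate"),
                       names(out))) {
    out[[cn]] <- as.integer(out[[cn]])
  }
  for (cn in intersect(c("experiment_id", "well", "position"), names(out))) {
    out[[cn]] <- as.character(out[[cn]])
  }
  out
}

# ---- outlines ---------------------------------------------------------------

polygon_centroid <- function(xy) {
  # area-weighted centroid of a simple polygon; falls back to the vertex
  # mean for (near-)degenerate rings
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  if (all(xy[1, ] == xy[n, ])) { x <- x[-n]; y <- y[-n]; n <- n - 1L }
  j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-9) return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

#' Read object outlines and link them to table records
#'
#' Outlines come either as a polygon table (CSV or data frame with one
#' vertex per row) or as a binary mask image in which each connected white
#' component is one outline. Each polygon is linked to the record of the
#' same (well, position, frame) whose centroid lies nearest the polygon
#' centroid, within a tolerance; equally near records are resolved toward
#' the lower `track_id`.
#'
#' @param source Data frame / CSV path with columns `well`, `position`,
#'   `frame`, `outline_id`, `x`, `y` (vertices in order), or a binary image
#'   file (PNG/TIFF, requires the EBImage package) together with
#'   `image_meta`.
#' @param records Track table used for centroid linkage; may be `NULL` to
#'   return unlinked polygons.
#' @param tol_px Maximum centroid distance for a link (default 5 px).
#' @param image_meta For image input, a one-row data frame giving the
#'   `well`, `position`, `frame` the image belongs to.
#' @return Tibble with one row per polygon: `well`, `position`, `frame`,
#'   `outline_id`, `track_id` (NA when unlinked), `centroid_x`,
#'   `centroid_y`, and a `vertices` list-column of n x 2 matrices.
#' @export
read_outlines <- function(source, records = NULL, tol_px = 5,
                          image_meta = NULL) {
  if (is.character(source) && length(source) == 1 &&
      grepl("\\.(png|tif|tiff)$", tolower(source))) {
    polys <- outlines_from_image(source, image_meta)
  } else {
    tab <- if (is.character(source)) read.csv(source, stringsAsFactors = FALSE) else source
    need <- c("well", "position", "frame", "outline_id", "x", "y")
    miss <- setdiff(need, names(tab))
    if (length(miss)) stop("polygon table missing column(s): ",
                           paste(miss, collapse = ", "))
    sp <- split(tab, list(tab$well, tab$position, tab$frame, tab$outline_id),
                drop = TRUE)
    polys <- lapply(sp, function(g) {
      list(well = as.character(g$well[1]), position = as.character(g$position[1]),
           frame = as.integer(g$frame[1]), outline_id = g$outline_id[1],
           vertices = cbind(g$x, g$y))
    })
  }
  polys <- polys[order(vapply(polys, function(p)
    sprintf("%s|%s|%09d|%s", p$well, p$position, p$frame, p$outline_id), ""))]
  out <- tibble::tibble(
    well = vapply(polys, `[[`, "", "well"),
    position = vapply(polys, `[[`, "", "position"),
    frame = vapply(polys, function(p) as.integer(p$frame), 0L),
    outline_id = vapply(polys, function(p) as.character(p$outline_id), ""),
    track_id = NA_integer_,
    centroid_x = NA_real_, centroid_y = NA_real_,
    vertices = lapply(polys, `[[`, "vertices")
  )
  for (i in seq_len(nrow(out))) {
    cen <- polygon_centroid(out$vertices[[i]])
    out$centroid_x[i] <- cen[1]; out$centroid_y[i] <- cen[2]
  }
  if (!is.null(records)) {
    idc <- if ("track_id" %in% names(records)) "track_id" else "raw_track_label"
    for (i in seq_len(nrow(out))) {
      cand <- records[records$well == out$well[i] &
                        records$position == out$position[i] &
                        records$frame == out$frame[i], ]
      if (nrow(cand) == 0) next
      d <- sqrt((cand$center_x - out$centroid_x[i])^2 +
                  (cand$center_y - out$centroid_y[i])^2)
      ok <- which(d <= tol_px)
      if (length(ok) == 0) next
      best <- ok[order(d[ok], cand[[idc]][ok])][1]
      if (sum(abs(d[ok] - d[best]) < 1e-9) > 1) {
        message("ambiguous outline link at ", out$well[i], "/", out$position[i],
                "/frame ", out$frame[i], ": nearest of ties by lower track id")
      }
      out$track_id[i] <- as.integer(cand[[idc]][best])
    }
  }
  out
}

outlines_from_image <- function(path, image_meta) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("reading outline images requires the EBImage package")
  }
  if (is.null(image_meta)) stop("image input requires image_meta (well, position, frame)")
  img <- EBImage::readImage(path)
  if (length(dim(img)) > 2) img <- img[, , 1]
  lab <- EBImage::bwlabel(img > 0.5)
  ocs <- EBImage::ocontour(lab)
  lapply(seq_along(ocs), function(i) {
    list(well = as.character(image_meta$well[1]),
         position = as.character(image_meta$position[1]),
         frame = as.integer(image_meta$frame[1]),
         outline_id = as.character(i),
         vertices = ocs[[i]])
  })
}

#' Write polygons to a vertex-per-row CSV
#' @param outlines Tibble as returned by [read_outlines()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_outlines <- function(outlines, path) {
  rows <- lapply(seq_len(nrow(outlines)), function(i) {
    v <- outlines$vertices[[i]]
    data.frame(well = outlines$well[i], position = outlines$position[i],
               frame = outlines$frame[i], outline_id = outlines$outline_id[i],
               track_id = outlines$track_id[i], x = v[, 1], y = v[, 2])
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
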