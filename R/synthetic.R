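#' Specification for a synthetic tracked-object dataset
#'
#' Describes a planted-ground-truth experiment emulating multi-day
#' time-lapse tracking of 3D objects: morphological states are Gaussian
#' modes in feature space, each track follows one of a set of trajectory
#' archetypes (state sequences over the imaging window), frames go missing
#' in short runs, objects occasionally split with all children inheriting
#' the parent's raw tracking label, and one archetype may be planted at a
#' chosen odds ratio in a non-reference sample.
#'
#' @param n_states Number of morphological states (default 8).
#' @param n_archetypes Number of trajectory archetypes (default 5).
#' @param n_frames Imaging frames per track (default 96, hourly).
#' @param imaging_interval_h Hours per frame (default 1).
#' @param n_tracks Tracks per (sample, replicate) (default 200).
#' @param samples Sample names; the first is the reference (default
#'   control/treated).
#' @param n_replicates Experimental replicates K (default 3).
#' @param state_separation Pairwise distance between state centroids in
#'   units of the within-state feature standard deviation (default 6).
#' @param feature_sd Within-state standard deviation (default 1).
#' @param label_noise Per-frame probability that a realised state deviates
#'   from the archetype template (default 0.05).
#' @param missing_rate Per-frame missingness probability (default 0.05);
#'   runs longer than `max_missing_run` are truncated.
#' @param max_missing_run Longest missing run injected (default 2).
#' @param split_prob Per-track-frame probability of a split event
#'   (default 0).
#' @param min_archetype_diff Minimum fraction of frames at which any two
#'   archetype templates differ (default 0.25).
#' @param motion_model `"derived"` (default): Area, shape and Displacement
#'   are drawn from the state Gaussian and the remaining movement features
#'   are derived from the centroid walk so internal relations match real
#'   tracker output; `"gaussian"`: every subset feature is drawn
#'   independently from the state Gaussian (planted-Gaussian-state
#'   benchmark).
#' @param enrichment Optional list `(sample, archetype, or, base_prob)`
#'   planting the archetype at odds ratio `or` (scalar, or one value per
#'   replicate for a heterogeneous effect) in `sample` relative to the
#'   reference; `base_prob` is the archetype's reference probability
#'   (default `1/n_archetypes`).
#' @param seed RNG seed; the full output is a deterministic function of the
#'   spec.
#' @return A validated list with class `"pt_sim_spec"`.
#' @export
simulation_spec <- function(n_states = 8, n_archetypes = 5, n_frames = 96,
                            imaging_interval_h = 1, n_tracks = 200,
                            samples = c("control", "treated"),
                            n_replicates = 3, state_separation = 6,
                            feature_sd = 1, label_noise = 0.05,
                            missing_rate = 0.05, max_missing_run = 2,
                            split_prob = 0, min_archetype_diff = 0.25,
                            motion_model = c("derived", "gaussian"),
                            enrichment = NULL, seed = 1L) {
  spec <- list(n_states = as.integer(n_states),
               n_archetypes = as.integer(n_archetypes),
               n_frames = as.integer(n_frames),
               imaging_interval_h = imaging_interval_h,
               n_tracks = as.integer(n_tracks), samples = samples,
               n_replicates = as.integer(n_replicates),
               state_separation = state_separation,
               feature_sd = feature_sd, label_noise = label_noise,
               missing_rate = missing_rate,
               max_missing_run = as.integer(max_missing_run),
               split_prob = split_prob,
               min_archetype_diff = min_archetype_diff,
               motion_model = match.arg(motion_model),
               enrichment = enrichment, seed = as.integer(seed))
  probs <- c("label_noise", "missing_rate", "split_prob")
  for (nm in probs) {
    if (spec[[nm]] < 0 || spec[[nm]] > 1) stop(nm, " must be in [0, 1]")
  }
  if (spec$max_missing_run >= spec$n_frames) {
    stop("max_missing_run must be smaller than n_frames")
  }
  if (spec$n_states < 2 || spec$n_archetypes < 1 || spec$n_frames < 2) {
    stop("need at least 2 states, 1 archetype and 2 frames")
  }
  if (!is.null(enrichment)) {
    stopifnot(enrichment$sample %in% samples[-1],
              enrichment$archetype %in% seq_len(spec$n_archetypes),
              all(enrichment$or > 0))
    if (is.null(enrichment$base_prob)) {
      spec$enrichment$base_prob <- 1 / spec$n_archetypes
    }
  }
  structure(spec, class = "pt_sim_spec")
}

# state centroids with exact pairwise separation >= sep: axis j holds
# states at (2m - 1) * sep / sqrt(2); any two distinct centroids are at
# least sep apart (same axis: >= sep * sqrt(2); different axes: sep)
state_centroids <- function(n_states, d, sep) {
  cen <- matrix(0, n_states, d)
  for (j in seq_len(n_states)) {
    axis <- (j - 1) %% d + 1
    m <- (j - 1) %/% d + 1
    cen[j, axis] <- (2 * m - 1) * sep / sqrt(2)
  }
  cen
}

# archetype templates: piecewise-constant state sequences (segment dwell
# 8-24 frames), regenerated until every pair differs in >= min_diff of
# frames
archetype_templates <- function(n_archetypes, n_states, n_frames, min_diff) {
  make_one <- function() {
    out <- integer(0)
    while (length(out) < n_frames) {
      out <- c(out, rep(sample.int(n_states, 1), sample(8:24, 1)))
    }
    out[seq_len(n_frames)]
  }
  templates <- list()
  guard <- 0L
  while (length(templates) < n_archetypes) {
    cand <- make_one()
    ok <- all(vapply(templates, function(t)
      mean(t != cand) >= min_diff, TRUE))
    if (ok) templates[[length(templates) + 1]] <- cand
    guard <- guard + 1L
    if (guard > 1000L * n_archetypes) {
      stop("could not generate sufficiently distinct archetypes")
    }
  }
  templates
}

# archetype sampling probabilities per (sample, replicate) honouring a
# planted odds ratio on one archetype
archetype_probs <- function(spec, smp, rep_k) {
  p <- rep(1 / spec$n_archetypes, spec$n_archetypes)
  en <- spec$enrichment
  if (!is.null(en)) {
    base <- en$base_prob
    p[en$archetype] <- base
    p[-en$archetype] <- (1 - base) / (spec$n_archetypes - 1)
    if (smp == en$sample) {
      or <- if (length(en$or) > 1) en$or[rep_k] else en$or
      odds <- or * base / (1 - base)
      q <- odds / (1 + odds)
      p[en$archetype] <- q
      p[-en$archetype] <- (1 - q) / (spec$n_archetypes - 1)
    }
  }
  p
}

# missingness mask with iid rate, runs truncated to max_run
missing_mask <- function(n, rate, max_run) {
  m <- runif(n) < rate
  if (!any(m) || max_run == 0) return(m & (max_run > 0))
  r <- rle(m)
  over <- which(r$values & r$lengths > max_run)
  if (length(over)) {
    ends <- cumsum(r$lengths)
    for (i in over) {
      keep_from <- ends[i] - r$lengths[i] + 1L + max_run
      m[keep_from:ends[i]] <- FALSE
    }
  }
  m
}

#' Generate a synthetic tracked-object dataset with planted ground truth
#'
#' Realises a [simulation_spec()]: draws each track's archetype, perturbs
#' the template with label noise, draws per-frame features from the
#' realised state's Gaussian, derives movement features from a centroid
#' walk (under the default motion model), injects missing frames and split
#' events (children inherit the parent's raw tracking label), and returns
#' the measurement table alongside the ground truth.
#'
#' @param spec A [simulation_spec()].
#' @return List: `measurements` (track table in canonical column names,
#'   raw labels only), `key` (experiment key), `truth` (list with
#'   `records` — per-row true state and track id — and `tracks` — per-track
#'   archetype, sample, replicate), `templates`, `centroids`, `spec`.
#' @export
simulate_tracked_data <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "pt_sim_spec"))
  set.seed(spec$seed)
  feats <- pt_default_features()
  drawn <- if (spec$motion_model == "gaussian") feats else
    c("Area", "Zernike_0_0", "Zernike_1_1", "Zernike_2_0", "Displacement")
  cen <- state_centroids(spec$n_states, length(drawn), spec$state_separation)
  colnames(cen) <- drawn
  # offsets keep physical features positive without touching separations
  offsets <- setNames(rep(0, length(drawn)), drawn)
  offsets["Area"] <- 400
  if ("Displacement" %in% drawn) offsets["Displacement"] <- 30
  templates <- archetype_templates(spec$n_archetypes, spec$n_states,
                                   spec$n_frames, spec$min_archetype_diff)
  wells <- sprintf("%s%d", rep(LETTERS[seq_along(spec$samples)],
                               each = spec$n_replicates),
                   rep(seq_len(spec$n_replicates), length(spec$samples)))
  key <- tibble::tibble(
    experiment_id = "sim",
    well = wells,
    sample = rep(spec$samples, each = spec$n_replicates),
    replicate = rep(seq_len(spec$n_replicates), length(spec$samples)))

  rec_rows <- list(); track_rows <- list()
  for (w in seq_len(nrow(key))) {
    smp <- key$sample[w]; rep_k <- key$replicate[w]
    p_arch <- archetype_probs(spec, smp, rep_k)
    next_true_id <- spec$n_tracks
    for (tr in seq_len(spec$n_tracks)) {
      arch <- sample.int(spec$n_archetypes, 1, prob = p_arch)
      states <- templates[[arch]]
      noisy <- runif(spec$n_frames) < spec$label_noise
      if (any(noisy)) {
        states[noisy] <- vapply(states[noisy], function(s)
          sample(setdiff(seq_len(spec$n_states), s), 1), 0L)
      }
      miss <- missing_mask(spec$n_frames, spec$missing_rate,
                           spec$max_missing_run)
      lineages <- list(list(true_id = tr, start = 1L, scale = 1,
                            x0 = runif(1, 0, 1000), y0 = runif(1, 0, 1000)))
      if (spec$split_prob > 0) {
        split_frames <- which(runif(spec$n_frames) < spec$split_prob)
        split_frames <- split_frames[split_frames > 1]
        for (sf in split_frames) {
          next_true_id <- next_true_id + 1L
          lineages[[length(lineages) + 1]] <-
            list(true_id = next_true_id, start = sf, scale = 0.6,
                 x0 = runif(1, 0, 1000), y0 = runif(1, 0, 1000))
        }
      }
      for (ln in lineages) {
        fr <- ln$start:spec$n_frames
        fr <- fr[!miss[fr]]
        if (!length(fr)) next
        nf <- length(fr)
        F <- matrix(rnorm(nf * length(drawn), sd = spec$feature_sd), nf,
                    dimnames = list(NULL, drawn))
        F <- F + cen[states[fr], , drop = FALSE] +
          matrix(offsets, nf, length(drawn), byrow = TRUE)
        F[, "Area"] <- pmax(F[, "Area"], 1)
        if (spec$motion_model == "derived") {
          step <- pmax(F[, "Displacement"], 0)
          step[1] <- 0
          theta <- runif(nf, 0, 2 * pi)
          x <- ln$x0 + cumsum(step * cos(theta))
          y <- ln$y0 + cumsum(step * sin(theta))
          integ <- cumsum(step)
          net <- sqrt((x - x[1])^2 + (y - y[1])^2)
          lin <- ifelse(integ > 0, pmin(net / integ, 1), 1)
          mov <- cbind(Displacement = step, DistanceTraveled = net,
                       IntegratedDistance = integ, Linearity = lin)
        } else {
          theta <- runif(nf, 0, 2 * pi)
          x <- ln$x0 + cumsum(5 * cos(theta))
          y <- ln$y0 + cumsum(5 * sin(theta))
          mov <- cbind(Displacement = F[, "Displacement"],
                       DistanceTraveled = F[, "DistanceTraveled"],
                       IntegratedDistance = F[, "IntegratedDistance"],
                       Linearity = F[, "Linearity"])
        }
        area <- F[, "Area"] * ln$scale
        aspect <- exp(rnorm(nf, 0, 0.1)) + 0.2
        width <- sqrt(area / aspect)
        rec_rows[[length(rec_rows) + 1]] <- list(
          well = rep(key$well[w], nf), frame = fr - 1L,
          raw_track_label = rep(tr, nf), Area = area,
          Zernike_0_0 = unname(F[, "Zernike_0_0"]),
          Zernike_1_1 = unname(F[, "Zernike_1_1"]),
          Zernike_2_0 = unname(F[, "Zernike_2_0"]),
          Displacement = unname(mov[, "Displacement"]),
          DistanceTraveled = unname(mov[, "DistanceTraveled"]),
          IntegratedDistance = unname(mov[, "IntegratedDistance"]),
          Linearity = unname(mov[, "Linearity"]),
          Length = aspect * width, Width = width,
          center_x = x, center_y = y,
          true_state = states[fr],
          true_track_id = rep(ln$true_id, nf))
        track_rows[[length(track_rows) + 1]] <- list(
          well = key$well[w], raw_track_label = tr,
          true_track_id = ln$true_id, sample = smp, replicate = rep_k,
          archetype = arch, is_split_child = ln$scale < 1)
      }
    }
  }
  col <- function(rows, nm) unlist(lapply(rows, `[[`, nm), use.names = FALSE)
  meas <- tibble::tibble(
    experiment_id = "sim", well = col(rec_rows, "well"), position = "1",
    frame = as.integer(col(rec_rows, "frame")))
  meas$time_h <- meas$frame * spec$imaging_interval_h
  meas$raw_track_label <- as.integer(col(rec_rows, "raw_track_label"))
  for (nm in c("Area", "Zernike_0_0", "Zernike_1_1", "Zernike_2_0",
               "Displacement", "DistanceTraveled", "IntegratedDistance",
               "Linearity", "Length", "Width", "center_x", "center_y")) {
    meas[[nm]] <- col(rec_rows, nm)
  }
  truth_records <- tibble::tibble(
    experiment_id = "sim", well = meas$well, position = "1",
    frame = meas$frame, raw_track_label = meas$raw_track_label,
    true_state = as.integer(col(rec_rows, "true_state")),
    true_track_id = as.integer(col(rec_rows, "true_track_id")))
  tracks <- tibble::tibble(
    experiment_id = "sim", well = col(track_rows, "well"), position = "1",
    raw_track_label = as.integer(col(track_rows, "raw_track_label")),
    true_track_id = as.integer(col(track_rows, "true_track_id")),
    sample = col(track_rows, "sample"),
    replicate = as.integer(col(track_rows, "replicate")),
    archetype = as.integer(col(track_rows, "archetype")),
    is_split_child = col(track_rows, "is_split_child"))
  list(measurements = meas, key = key,
       truth = list(records = truth_records, tracks = tracks),
       templates = templates, centroids = cen, spec = spec)
}

# ---- analytic polygon fixtures ---------------------------------------------

#' Analytic polygon fixtures with known spectra
#'
#' Constructors for closed polygons used to validate the boundary-spectrum
#' machinery: circles (single dominant non-DC frequency), axis-aligned
#' ellipses of chosen aspect ratio, squares, and star shapes.
#'
#' @param radius,a,b,side,r_outer,r_inner Shape dimensions in px.
#' @param n_vertices Number of boundary vertices.
#' @param center Centre (x, y).
#' @param n_points Number of star points.
#' @return n x 2 vertex matrix (open ring; closure is implicit).
#' @export
polygon_circle <- function(radius, n_vertices = 128, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[seq_len(n_vertices)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

#' @rdname polygon_circle
#' @export
polygon_ellipse <- function(a, b, n_vertices = 128, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[seq_len(n_vertices)]
  cbind(center[1] + a * cos(th), center[2] + b * sin(th))
}

#' @rdname polygon_circle
#' @export
polygon_square <- function(side, n_vertices = 128, center = c(0, 0)) {
  per_edge <- ceiling(n_vertices / 4)
  t <- seq(0, 1, length.out = per_edge + 1)[seq_len(per_edge)]
  h <- side / 2
  v <- rbind(cbind(-h + side * t, -h), cbind(h, -h + side * t),
             cbind(h - side * t, h), cbind(-h, h - side * t))
  sweep(v, 2, center, "+")
}

#' @rdname polygon_circle
#' @export
polygon_star <- function(r_outer, r_inner, n_points = 5, n_vertices = 128) {
  k <- 2 * n_points
  th <- seq(0, 2 * pi, length.out = k + 1)[seq_len(k)]
  r <- rep(c(r_outer, r_inner), n_points)
  base <- cbind(r * cos(th), r * sin(th))
  resample_boundary(base, n_vertices)
}
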