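toy_records <- function(frames, labels, areas, well = "A1", pos = "1",
                        x = NULL, y = NULL) {
  n <- length(frames)
  tibble::tibble(experiment_id = "e", well = well, position = pos,
                 frame = as.integer(frames), time_h = as.numeric(frames),
                 raw_track_label = as.integer(labels), Area = areas,
                 center_x = if (is.null(x)) seq_len(n) else x,
                 center_y = if (is.null(y)) rep(0, n) else y)
}

test_that("time, lifetime and sample filters apply the stated rules", {
  rec <- toy_records(0:120, rep(1, 121), rep(10, 121))
  out <- filter_records(rec, max_time_h = 96)
  expect_equal(max(out$time_h), 96)
  expect_equal(nrow(out), 97)

  # min_lifetime = 0 is the identity
  expect_equal(filter_records(rec, max_time_h = Inf, min_lifetime = 0), rec)

  # tracks with lifetimes 5 / 50 / 96 frames against a 48-frame cut
  rec3 <- dplyr::bind_rows(
    toy_records(0:4, rep(1, 5), rep(1, 5)),
    toy_records(0:49, rep(2, 50), rep(1, 50)),
    toy_records(0:95, rep(3, 96), rep(1, 96)))
  out3 <- filter_records(rec3, max_time_h = Inf, min_lifetime = 48)
  expect_setequal(unique(out3$raw_track_label), c(2L, 3L))

  rec$sample <- "ctrl"
  expect_equal(nrow(filter_records(rec, samples = "drug")), 0)
})

test_that("binary classification columns collapse to a single class", {
  rec <- tibble::tibble(Round = c(1, 0, 0, 1), Spread = c(0, 1, 0, 1),
                        Spindle = c(0, 0, 0, 0))
  out <- suppressMessages(parse_user_classes(rec, c("Round", "Spread", "Spindle")))
  expect_equal(out$user_class, c("Round", "Spread", NA, NA))
  expect_message(parse_user_classes(rec, c("Round", "Spread", "Spindle")),
                 "2 row")
  expect_error(parse_user_classes(tibble::tibble(Round = 2), "Round"),
               "binary")
})

test_that("the largest-area child inherits the parent label at a split", {
  # track 7 runs frames 0-9, splits at frame 10 into areas 120 and 80
  rec <- dplyr::bind_rows(
    toy_records(0:9, rep(7, 10), rep(100, 10), x = rep(0, 10)),
    toy_records(c(10, 10, 11, 11), rep(7, 4), c(120, 80, 121, 81),
                x = c(0, 5, 0, 5)))
  out <- suppressMessages(correct_tracks(rec))
  expect_equal(out$track_id[1:10], rep(7L, 10))
  expect_equal(out$track_id[out$frame == 10 & out$Area == 120], 7L)
  new_id <- out$track_id[out$frame == 10 & out$Area == 80]
  expect_false(new_id == 7L)
  # the child lineage keeps its fresh id downstream
  expect_equal(out$track_id[out$frame == 11 & out$Area == 81], new_id)
  expect_equal(out$track_id[out$frame == 11 & out$Area == 121], 7L)
})

test_that("three-way splits issue one fresh id per extra child", {
  rec <- dplyr::bind_rows(
    toy_records(0:4, rep(3, 5), rep(70, 5), x = rep(10, 5)),
    toy_records(c(5, 5, 5, 6, 6, 6), rep(3, 6), c(50, 90, 60, 51, 91, 61),
                x = c(0, 10, 20, 0, 10, 20)))
  out <- suppressMessages(correct_tracks(rec))
  expect_equal(out$track_id[out$Area %in% c(90, 91)], c(3L, 3L))
  ids5 <- out$track_id[out$frame == 5]
  expect_equal(length(unique(ids5)), 3)
  # downstream frames follow their own child (matched by centroid)
  id50 <- out$track_id[out$Area == 50]
  expect_equal(out$track_id[out$Area == 51], id50)
  # per-frame uniqueness
  key <- paste(out$well, out$position, out$track_id, out$frame)
  expect_equal(anyDuplicated(key), 0L)
})

test_that("correction without splits is the identity on labels", {
  rec <- dplyr::bind_rows(toy_records(0:9, rep(1, 10), rep(10, 10)),
                          toy_records(0:9, rep(2, 10), rep(20, 10)))
  out <- correct_tracks(rec)
  expect_equal(out$track_id, out$raw_track_label)
  expect_equal(nrow(out), nrow(rec))
})

test_that("correction conserves records and first appearances on split data", {
  spec <- simulation_spec(n_states = 3, n_archetypes = 2, n_frames = 30,
                          n_tracks = 50, samples = "s", n_replicates = 2,
                          split_prob = 0.02, seed = 3)
  sim <- simulate_tracked_data(spec)
  out <- suppressMessages(correct_tracks(sim$measurements))
  expect_equal(nrow(out), nrow(sim$measurements))
  key <- paste(out$well, out$position, out$track_id, out$frame)
  expect_equal(anyDuplicated(key), 0L)
  # earliest frame of each raw label is unchanged by relabelling
  first_raw <- tapply(sim$measurements$frame,
                      paste(sim$measurements$well, sim$measurements$raw_track_label),
                      min)
  first_out <- tapply(out$frame, paste(out$well, out$raw_track_label), min)
  expect_equal(first_out, first_raw)
})

test_that("aspect ratio derives from the bounding box", {
  rec <- tibble::tibble(Length = c(10, 4, 3), Width = c(5, 4, 0))
  out <- suppressMessages(derive_features(rec))
  expect_equal(out$AspectRatio, c(2, 1, NA))
})

test_that("z-scoring centres and scales with the sample sd convention", {
  rec <- tibble::tibble(a = c(1, 2, 3), b = c(5, 5, 5))
  out <- suppressWarnings(zscore_features(rec, c("a", "b")))
  expect_equal(out$a_z, c(-1, 0, 1))           # sd = 1 with n-1 convention
  expect_equal(out$b_z, c(0, 0, 0))
  expect_warning(zscore_features(rec, "b"), "zero-variance")

  # mean 0 / sd 1 property and idempotence on re-standardised data
  x <- rnorm(200, 5, 3); x[7] <- NA
  rec2 <- tibble::tibble(v = x)
  z1 <- zscore_features(rec2, "v")$v_z
  expect_lt(abs(mean(z1, na.rm = TRUE)), 1e-9)
  expect_lt(abs(sd(z1, na.rm = TRUE) - 1), 1e-9)
  z2 <- zscore_features(tibble::tibble(v = z1), "v")$v_z
  expect_equal(z2, z1, tolerance = 1e-12)
})
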