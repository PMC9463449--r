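test_that("sequences rebuild temporal order with explicit missing entries", {
  rec <- tibble::tibble(
    experiment_id = "e", well = "w", position = "1",
    track_id = c(rep(1L, 3), rep(2L, 2)),
    frame = c(0L, 1L, 2L, 0L, 2L))
  st <- factor(c("A", "B", "A", "C", "C"))
  seqs <- build_sequences(rec, st)
  expect_equal(dim(seqs$states), c(2, 3))
  expect_equal(unname(seqs$states[1, ]), c("A", "B", "A"))
  expect_equal(unname(seqs$states[2, ]), c("C", NA, "C"))

  # track observed over every frame yields a gap-free sequence
  full <- build_sequences(rec[1:3, ], st[1:3])
  expect_false(anyNA(full$states))
  # conservation: one sequence per track
  expect_equal(nrow(seqs$keys), 2)
})

test_that("the 50% trim rule reproduces the hand-counted fixture", {
  # ten 96-frame sequences whose observations stop at positions
  # 30,40,...,90,96,96,96 (all observed from the start)
  last <- c(30, 40, 50, 60, 70, 80, 90, 96, 96, 96)
  M <- matrix(NA_character_, 10, 96)
  for (i in 1:10) M[i, 1:last[i]] <- "A"
  seqs <- make_seqs(M)
  out <- filter_and_trim(seqs, min_presence_time_h = 20,
                         imaging_interval_h = 1)
  rep <- attr(out, "filter_report")
  expect_equal(rep$trim_length_frames, 70)
  expect_equal(ncol(out$states), 70)
  # sequences ending before the trim point carry trailing missing runs
  # longer than 2 and fall to the missing-run rule
  expect_equal(nrow(out$states), 6)
  expect_equal(rep$n_dropped_missing_runs, 4)
})

test_that("missing-run filtering removes >2 runs and keeps 2-runs", {
  M <- rbind(c("A", NA, NA, NA, "B", "A", "A", "A"),   # 3-run: removed
             c("A", NA, NA, "B", "A", "A", "A", "A"),  # 2-run: retained
             c("A", "A", "A", "A", "B", "B", "B", "B"))
  seqs <- make_seqs(M)
  out <- filter_and_trim(seqs, min_presence_time_h = 0,
                         max_consecutive_missing = 2)
  expect_equal(nrow(out$states), 2)
  expect_equal(out$keys$track_id, c(2L, 3L))
  rep <- attr(out, "filter_report")
  expect_equal(rep$n_dropped_missing_runs, 1)

  # the presence rule drops sequences unobserved at the anchor frame
  M2 <- rbind(c("A", NA, "A"), c("A", "A", "A"))
  out2 <- filter_and_trim(make_seqs(M2), min_presence_time_h = 1,
                          imaging_interval_h = 1)
  expect_equal(nrow(out2$states), 1)
  expect_error(filter_and_trim(make_seqs(M2[1, , drop = FALSE]),
                               min_presence_time_h = 1),
               "no sequences")
})

test_that("reverse LOCF pulls the next observation backward", {
  expect_equal(unname(impute_sequences(make_seqs(rbind(c("A", NA, "B"))))$states[1, ]),
               c("A", "B", "B"))
  expect_equal(unname(impute_sequences(make_seqs(rbind(c(NA, "A", "B"))))$states[1, ]),
               c("A", "A", "B"))
  M <- rbind(c("A", "B", "A"))
  expect_equal(impute_sequences(make_seqs(M))$states, make_seqs(M)$states)
  # trailing gap falls back to forward fill, with a message
  expect_message(
    out <- impute_sequences(make_seqs(rbind(c("A", "B", NA)))),
    "trailing")
  expect_equal(unname(out$states[1, ]), c("A", "B", "B"))
  expect_error(impute_sequences(make_seqs(rbind(c(NA_character_, NA)),
                                          levels = "A")),
               "entirely missing")
})

test_that("MCA separates two pure sequence groups with the analytic geometry", {
  # n_A all-A and n_B all-B sequences: a single inertia axis with
  # singular value 1; principal coordinates sqrt(n_B/n_A) and
  # -sqrt(n_A/n_B) (sign arbitrary)
  M <- rbind(matrix("A", 6, 5), matrix("B", 4, 5))
  co <- mca_embed(make_seqs(M), mca_dims = 10)
  expect_equal(dim(co), c(10, 10))
  d1 <- co[, 1]
  expect_lt(max(abs(d1[1:6] - d1[1])), 1e-10)     # zero within-group variance
  expect_lt(max(abs(d1[7:10] - d1[7])), 1e-10)
  vals <- sort(abs(c(d1[1], d1[7])))
  expect_equal(vals, sort(c(sqrt(4 / 6), sqrt(6 / 4))), tolerance = 1e-10)
  expect_equal(sign(d1[1]) * sign(d1[7]), -1)
  expect_equal(attr(co, "eig")[1], 1, tolerance = 1e-10)
  # axes beyond the single informative one are zero-padded
  expect_lt(max(abs(co[, 2:10])), 1e-10)

  expect_warning(mca_embed(make_seqs(matrix("A", 5, 4)), 5), "identical")
})

test_that("planted sequence archetypes cluster into the right trajectories", {
  set.seed(8)
  L <- 96
  tmplA <- rep(c("A", "B"), length.out = L)
  tmplB <- rep(c("C", "C", "A", "A"), length.out = L)
  noisy <- function(tmpl) {
    v <- tmpl
    flip <- runif(L) < 0.05
    v[flip] <- sample(c("A", "B", "C"), sum(flip), replace = TRUE)
    v
  }
  M <- rbind(t(replicate(200, noisy(tmplA))), t(replicate(200, noisy(tmplB))))
  seqs <- make_seqs(M)
  co <- mca_embed(seqs, 20)
  lab <- cluster_trajectories(co, knn_k = 40, seed = 1)
  expect_equal(nlevels(lab), 2)
  expect_gte(ari(lab, rep(1:2, each = 200)), 0.95)
  # labels are numbered by decreasing size
  expect_identical(levels(lab), c("1", "2"))

  # degenerate: identical sequences collapse to a single trajectory
  one <- cluster_trajectories(
    suppressWarnings(mca_embed(make_seqs(matrix("A", 100, 30)), 10)),
    knn_k = 40, seed = 1)
  expect_equal(nlevels(one), 1)
})

test_that("the full trajectory stage leaves no gaps and labels every sequence", {
  spec <- simulation_spec(n_states = 4, n_archetypes = 2, n_frames = 40,
                          n_tracks = 120, samples = "s", n_replicates = 1,
                          seed = 12)
  sim <- simulate_tracked_data(spec)
  rec <- sim$measurements
  rec$track_id <- rec$raw_track_label
  seqs <- build_sequences(rec, factor(LETTERS[sim$truth$records$true_state]))
  cfg <- pipeline_config(knn_k = 20, mca_dims = 20, sketch_size = 1000)
  tm <- suppressMessages(fit_trajectories(seqs, cfg))
  expect_false(anyNA(tm$sequences$states))
  expect_equal(length(tm$trajectory_labels), nrow(tm$sequences$states))
  lens <- vapply(tm$consensus, length, 0L)
  expect_true(all(lens == ncol(tm$sequences$states)))
})
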