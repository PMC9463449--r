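test_that("consensus takes the per-frame majority with lexicographic ties", {
  M <- rbind(c("B", "A", "C"),
             c("B", "B", "C"),
             c("A", "A", "B"),
             c("C", "B", "A"))
  expect_equal(consensus_sequence(M), c("B", "A", "C"))
  # 2-2 tie in column 2 between A and B resolves to A; NA are ignored
  M2 <- rbind(c("A", NA), c("B", "B"))
  expect_equal(consensus_sequence(M2), c("A", "B"))
})

test_that("motif frequencies match hand enumeration and sum to one", {
  # 4 members, 4 frames, 2-h intervals at 1 h/frame -> 2 intervals
  M <- rbind(c("A", "A", "B", "B"),
             c("A", "B", "B", "B"),
             c("A", "A", "C", "B"),
             c("C", "A", "B", "B"))
  seqs <- make_seqs(M)
  lab <- factor(rep("1", 4))
  mo <- motif(seqs, lab, motif_interval_h = 2, imaging_interval_h = 1)
  f1 <- mo$frequencies[mo$frequencies$interval_start_h == 0, ]
  # interval 1 holds 8 member-frames: A x6, B x1, C x1
  expect_equal(f1$frequency[f1$state == "A"], 6 / 8)
  expect_equal(f1$frequency[f1$state == "B"], 1 / 8)
  expect_equal(f1$frequency[f1$state == "C"], 1 / 8)
  sums <- tapply(mo$frequencies$frequency,
                 mo$frequencies$interval_start_h, sum)
  expect_equal(as.numeric(sums), c(1, 1))
  expect_equal(mo$top_states$state, c("A", "B"))

  # an interval holding a single state has frequency exactly 1
  mo2 <- motif(make_seqs(rbind(c("C", "C"))), factor("1"),
               motif_interval_h = 2)
  expect_equal(mo2$frequencies$frequency, 1)
  expect_error(motif(seqs, factor(rep("1", 4), levels = c("1", "2"))),
               "no members")
})

test_that("transition proportions match hand enumeration and honour the filter", {
  # constant sequence: pure maintenance
  cs <- make_seqs(rbind(rep("A", 24)))
  tr <- transitions(cs, factor("1"), transition_window_h = 2,
                    motif_interval_h = 12)
  expect_true(all(tr$from == "A" & tr$to == "A"))
  expect_true(all(tr$proportion == 1))

  # 3 members x 4 frames, one interval: hand-enumerated pair counts.
  # Consecutive pairs per member: m1 AA,AB,BB  m2 AA,AA,AA  m3 AB,BB,BB
  # 2-frame windows double interior pairs: total counts
  # AA: 1+2+2+1(m1 f1,f1,f2.. ) -> enumerate: windows s=0 (pairs f1,f2), s=1
  # (pairs f2,f3): m1: AA,AB | AB,BB ; m2: AA,AA | AA,AA ; m3: AB,BB | BB,BB
  # counts: AA = 2+... m1 s0: AA,AB; m1 s1: AB,BB -> AA1 AB2 BB1
  # m2: AA4 ; m3 s0: AB,BB s1: BB,BB -> AB1 BB3
  # totals: AA5 AB3 BB4, grand 12
  M <- rbind(c("A", "A", "B", "B"),
             c("A", "A", "A", "A"),
             c("A", "B", "B", "B"))
  tr2 <- transitions(make_seqs(M), factor(rep("1", 3)),
                     transition_window_h = 2, motif_interval_h = 12,
                     transition_min_freq = 0)
  expect_equal(tr2$proportion[tr2$from == "A" & tr2$to == "A"], 5 / 12)
  expect_equal(tr2$proportion[tr2$from == "A" & tr2$to == "B"], 3 / 12)
  expect_equal(tr2$proportion[tr2$from == "B" & tr2$to == "B"], 4 / 12)
  expect_equal(sum(tr2$proportion), 1)

  # a 1%-frequency transition is filtered at the 2% threshold
  long <- rep("A", 102)
  long[51] <- "B"; long[52] <- "A"
  many <- make_seqs(rbind(matrix("A", 3, 102), long))
  tr3 <- transitions(many, factor(rep("1", 4)), transition_window_h = 2,
                     motif_interval_h = 102, transition_min_freq = 0.02)
  expect_false(any(tr3$from == "A" & tr3$to == "B"))
  tr4 <- transitions(many, factor(rep("1", 4)), transition_window_h = 2,
                     motif_interval_h = 102, transition_min_freq = 0)
  expect_true(any(tr4$from == "A" & tr4$to == "B"))
  expect_lt(tr4$proportion[tr4$from == "A" & tr4$to == "B"], 0.02)
})

test_that("the representative member minimises edit distance to the consensus", {
  M <- rbind(c("A", "A", "B", "B", "C"),
             c("A", "B", "B", "B", "C"),
             c("C", "C", "C", "C", "C"),
             c("A", "A", "B", "C", "C"),
             c("B", "A", "B", "B", "A"))
  seqs <- make_seqs(M)
  co <- mca_embed(seqs, 4)
  model <- structure(list(
    sequences = seqs, raw_sequences = seqs, coords = co,
    trajectory_labels = factor(rep("1", 5)),
    consensus = list("1" = consensus_sequence(M))),
    class = "pt_trajectory_model")
  sel <- representative_spheroid(model)
  # brute-force DP oracle over every member
  cons <- consensus_sequence(M)
  d <- apply(M, 1, function(v) oracle_edit_distance(v, cons))
  expect_equal(sel$track_id, which.min(d))
  expect_equal(sel$edit_distance, min(d))

  # a member identical to the consensus is always selected
  M2 <- rbind(cons, M[c(3, 5), ])
  model2 <- structure(list(
    sequences = make_seqs(M2), raw_sequences = make_seqs(M2),
    trajectory_labels = factor(rep("1", 3)),
    consensus = list("1" = cons)), class = "pt_trajectory_model")
  sel2 <- representative_spheroid(model2)
  expect_equal(sel2$track_id, 1L)
  expect_equal(sel2$edit_distance, 0)

  # permutation invariance given the tie rule
  perm <- c(4, 2, 5, 1, 3)
  Mp <- M[perm, ]
  modelp <- structure(list(
    sequences = make_seqs(Mp), raw_sequences = make_seqs(Mp),
    trajectory_labels = factor(rep("1", 5)),
    consensus = list("1" = cons)), class = "pt_trajectory_model")
  selp <- representative_spheroid(modelp)
  expect_equal(Mp[selp$track_id, ], M[sel$track_id, ])
})

test_that("missing frames are dropped from members before comparison", {
  cons <- c("A", "B", "B")
  M <- rbind(c("A", NA, "B"),         # compared as "AB": distance 1
             c("C", "C", "C"))        # distance 3
  model <- structure(list(
    sequences = make_seqs(rbind(c("A", "B", "B"), c("C", "C", "C"))),
    raw_sequences = make_seqs(M),
    trajectory_labels = factor(rep("1", 2)),
    consensus = list("1" = cons)), class = "pt_trajectory_model")
  sel <- representative_spheroid(model)
  expect_equal(sel$track_id, 1L)
  expect_equal(sel$edit_distance, oracle_edit_distance(c("A", "B"), cons))
})

test_that("class counts and stratified tables assemble by hand", {
  df <- tibble::tibble(
    sample = rep(c("ref", "cmp"), each = 100),
    replicate = rep(rep(1:2, each = 50), 2),
    cls = c(rep("X", 10), rep("Y", 90), rep("X", 30), rep("Y", 70)))
  cnt <- quantify_classes(df, "cls")
  expect_equal(sum(cnt$n_in[cnt$sample == "ref" & cnt$class == "X"]), 10)
  expect_equal(sum(cnt$n_in[cnt$sample == "cmp" & cnt$class == "X"]), 30)
  pr <- tapply(cnt$n_in, list(cnt$sample, cnt$class), sum) / 100
  expect_equal(unname(pr["ref", "X"]), 0.1)
  expect_equal(unname(pr["cmp", "X"]), 0.3)

  tab <- stratified_table(cnt, "X", "cmp", "ref")
  expect_equal(dim(tab), c(2, 2, 2))
  expect_equal(sum(tab), 200)
  # replicate 1 of ref: X count 10 (all X rows sit in replicate 1)
  expect_equal(tab["in_class", "ref", "1"], 10)
  expect_equal(tab["in_class", "cmp", "1"], 30)
  expect_equal(tab["not_in_class", "ref", "2"], 50)

  # per-interval variant
  df$time_h <- rep(c(0, 13), 100)
  cnt_iv <- quantify_classes(df, "cls", interval_h = 12)
  expect_setequal(unique(cnt_iv$interval_start_h), c(0, 12))
})
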