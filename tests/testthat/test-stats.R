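test_that("CMH matches the direct formula and the base-R implementation", {
  # observed == expected in every stratum
  flat <- array(c(5, 5, 5, 5), c(2, 2, 2))
  out <- cmh_test(flat)
  expect_equal(unname(out$statistic), 0)
  expect_equal(out$p.value, 1)

  fixed <- array(c(10, 3, 5, 12, 8, 2, 4, 10), c(2, 2, 2))
  expect_equal(unname(cmh_test(fixed)$statistic),
               oracle_cmh(fixed)$statistic, tolerance = 1e-10)

  set.seed(101)
  for (i in 1:25) {
    tab <- rand_strat_table(sample(2:5, 1))
    mine <- cmh_test(tab)
    expect_equal(unname(mine$statistic), oracle_cmh(tab)$statistic,
                 tolerance = 1e-8)
    ref <- mantelhaen.test(tab, correct = FALSE)
    expect_equal(unname(mine$statistic), unname(ref$statistic),
                 tolerance = 1e-8)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-8)
  }

  # a single stratum reduces to the unadjusted MH chi-square of that 2x2,
  # i.e. (n-1)/n times the uncorrected Pearson chi-square
  one <- rand_strat_table(1)
  n1 <- sum(one)
  pear <- suppressWarnings(chisq.test(one[, , 1], correct = FALSE))
  expect_equal(unname(cmh_test(one)$statistic),
               unname(pear$statistic) * (n1 - 1) / n1, tolerance = 1e-10)
  expect_equal(unname(cmh_test(one)$statistic), oracle_cmh(one)$statistic,
               tolerance = 1e-10)

  # zero-margin strata are dropped as uninformative
  degen <- array(c(0, 0, 5, 5, 4, 6, 5, 5), c(2, 2, 2))
  expect_warning(res <- cmh_test(degen), "zero margin")
  expect_equal(unname(res$statistic),
               unname(cmh_test(degen[, , 2, drop = FALSE])$statistic))
})

test_that("Breslow-Day agrees with the closed-form oracle", {
  same <- array(rep(c(12, 8, 9, 15), 2), c(2, 2, 2))
  expect_lt(unname(breslow_day(same)$statistic), 1e-10)
  expect_equal(breslow_day(same)$p.value, 1, tolerance = 1e-8)

  # strata with odds ratios 2 and 0.5 at n ~ 120 each: clear heterogeneity
  het <- array(c(40, 20, 30, 30,  20, 40, 30, 30), c(2, 2, 2))
  res <- breslow_day(het)
  expect_equal(unname(res$statistic), oracle_bd(het)$statistic,
               tolerance = 1e-8)
  expect_lt(res$p.value, 0.05)

  set.seed(102)
  for (i in 1:25) {
    tab <- rand_strat_table(sample(2:5, 1))
    expect_equal(unname(breslow_day(tab)$statistic),
                 oracle_bd(tab)$statistic, tolerance = 1e-8)
    expect_equal(unname(breslow_day(tab, tarone = TRUE)$statistic),
                 oracle_bd(tab, tarone = TRUE)$statistic, tolerance = 1e-8)
    # the Tarone flag subtracts the documented correction term
    expect_lte(unname(breslow_day(tab, tarone = TRUE)$statistic),
               unname(breslow_day(tab)$statistic) + 1e-12)
  }
  expect_error(breslow_day(rand_strat_table(1)), "single stratum")
})

test_that("Woolf agrees with the step-by-step formula and guards zero cells", {
  same <- array(rep(c(12, 8, 9, 15), 3), c(2, 2, 3))
  expect_lt(unname(woolf_test(same)$statistic), 1e-12)

  set.seed(103)
  for (i in 1:25) {
    tab <- rand_strat_table(sample(2:5, 1))
    expect_equal(unname(woolf_test(tab)$statistic),
                 oracle_woolf(tab)$statistic, tolerance = 1e-8)
  }
  withzero <- array(c(0, 10, 5, 5, 3, 7, 4, 6), c(2, 2, 2))
  expect_true(is.finite(woolf_test(withzero)$statistic))
  expect_error(woolf_test(rand_strat_table(1)), "single stratum")
})

test_that("interval t-tests use pooled variance and a Bonferroni family", {
  set.seed(104)
  df <- tibble::tibble(
    sample = rep(c("ref", "cmp"), each = 100),
    time_h = rep(rep(c(1, 13), each = 50), 2),
    Area = c(rnorm(100), rnorm(50), rnorm(50, 5)))
  out <- interval_ttests(df, "Area", reference = "ref", interval_h = 12)
  expect_equal(nrow(out), 2)
  expect_equal(out$p_adj, pmin(1, out$p * 2))
  expect_lt(out$p[out$interval_start_h == 12], 1e-10)
  expect_gt(out$p[out$interval_start_h == 0], 0.001)

  # identical groups: t = 0, p = 1
  df2 <- tibble::tibble(sample = rep(c("ref", "cmp"), each = 3),
                        time_h = 1, Area = rep(c(1, 2, 3), 2))
  out2 <- interval_ttests(df2, "Area", reference = "ref")
  expect_equal(out2$t, 0)
  expect_equal(out2$p, 1)
  # cross-check against the pooled-variance t
  df3 <- df[df$time_h == 13, ]
  tt <- t.test(df3$Area[df3$sample == "cmp"], df3$Area[df3$sample == "ref"],
               var.equal = TRUE)
  expect_equal(out$t[out$interval_start_h == 12], unname(tt$statistic))
})

test_that("fold-change tables are antisymmetric in reference choice", {
  cnt <- tibble::tibble(
    class = rep(c("X", "Y"), each = 4),
    sample = rep(rep(c("a", "b"), each = 2), 2),
    replicate = rep(1:2, 4),
    n_in = c(10, 12, 40, 38, 90, 88, 60, 62),
    n_total = rep(100, 8))
  fa <- fold_change_table(cnt, reference = "a")
  fb <- fold_change_table(cnt, reference = "b")
  expect_equal(fa$table$log2fc, -fb$table$log2fc, tolerance = 1e-12)
  expect_equal(fa$table$p_cmh, fb$table$p_cmh, tolerance = 1e-12)

  # 0.1 -> 0.4 is a log2 fold change of 2; equal proportions give 0
  expect_equal(fa$table$log2fc[fa$table$class == "X"],
               log2((40 + 38) / 200 / ((10 + 12) / 200)))
  same <- dplyr::mutate(cnt, n_in = rep(c(20, 20, 20, 20), 2))
  fs <- fold_change_table(same, reference = "a")
  expect_equal(fs$table$log2fc, c(0, 0))
  expect_equal(unname(fs$table$p_cmh), c(1, 1))
})

test_that("count curves normalise to the initial count per replicate", {
  rec <- tibble::tibble(
    sample = rep("s", 95), replicate = 1L,
    frame = c(rep(0L, 50), rep(1L, 45)),
    time_h = c(rep(0, 50), rep(1, 45)))
  out <- count_curve(rec)
  expect_equal(out$normalized, c(1, 0.9))

  # constant counts give a flat line; replicate order is immaterial
  rec2 <- tibble::tibble(sample = "s", replicate = rep(c(2L, 1L), each = 4),
                         frame = rep(0:3, 2), time_h = rep(0:3, 2))
  out2 <- count_curve(rec2)
  expect_true(all(out2$normalized == 1))
  out2b <- count_curve(rec2[sample(nrow(rec2)), ])
  expect_equal(out2, out2b)
})
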