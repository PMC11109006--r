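test_that("robust SD is 1.4826 x MAD with a degeneracy flag", {
  s <- robust_sd(c(1, 2, 3, 4, 5))
  expect_identical(as.numeric(s), 1.4826)
  expect_false(attr(s, "degenerate"))
  s0 <- robust_sd(rep(7, 10))
  expect_identical(as.numeric(s0), 0)
  expect_true(attr(s0, "degenerate"))
  expect_error(robust_sd(1:3), ">= 5")
  expect_error(threshold_set(s0), "degenerate")
  # consistency for Gaussian noise
  set.seed(17)
  expect_equal(as.numeric(robust_sd(rnorm(20000))), 1, tolerance = 0.03)
})

test_that("positivity rules: 2-frame confirmation, 3-frame gap tolerance", {
  th <- 1
  # exactly two supra frames confirm; onset is the first of the two
  r <- call_positive(c(0, 0, 2, 2, 0, 0), th)
  expect_true(r$positive)
  expect_equal(r$onset, 3)
  # one isolated supra frame is not enough
  expect_false(call_positive(c(0, 2, 0, 0, 0), th)$positive)
  # supra 5 / sub 3 / supra 5 is a single episode spanning all 13 frames
  v <- c(rep(2, 5), rep(0, 3), rep(2, 5))
  r2 <- call_positive(v, th)
  expect_equal(nrow(r2$episodes), 1)
  expect_equal(r2$episodes$start, 1)
  expect_equal(r2$episodes$end, 13)
  # a 4-frame gap splits the trace into two episodes
  v3 <- c(rep(2, 5), rep(0, 4), rep(2, 5))
  r3 <- call_positive(v3, th)
  expect_equal(nrow(r3$episodes), 2)
  expect_equal(r3$episodes$start, c(1, 10))
  # all-zero trace is negative; short trace is flagged
  expect_false(call_positive(rep(0, 10), th)$positive)
  expect_true(call_positive(c(5), th)$insufficient_data)
})

test_that("state machine agrees with the rle-segment oracle exhaustively", {
  # every supra/sub pattern up to length 12, default rules
  mismatches <- 0L
  checked <- 0L
  for (n in 1:12) {
    for (code in 0:(2^n - 1)) {
      supra <- bitwAnd(code, 2^(0:(n - 1))) > 0
      got <- call_positive(as.numeric(supra), 0.5)
      want <- oracle_episodes(supra)
      same <- nrow(got$episodes) == nrow(want) &&
        identical(as.integer(got$episodes$start), as.integer(want$start)) &&
        identical(as.integer(got$episodes$end), as.integer(want$end))
      if (!same) mismatches <- mismatches + 1L
      checked <- checked + 1L
    }
  }
  expect_equal(checked, sum(2^(1:12)))
  expect_identical(mismatches, 0L)
})

test_that("raising the threshold never creates a positive call", {
  set.seed(3)
  for (i in 1:50) {
    v <- cumsum(rnorm(30, 0.2))
    lo <- call_positive(v, 1)$positive
    hi <- call_positive(v, 3)$positive
    expect_true(lo || !hi)
  }
})

test_that("activity classification partitions wells by the 50-sigma rule", {
  th <- threshold_set(structure(1, degenerate = FALSE))
  expect_equal(th$detect, 3)
  expect_equal(th$hyper, 50)
  expect_identical(classify_activity(FALSE, 0, th), "silent")
  expect_identical(classify_activity(TRUE, 100, th), "hyperactive")
  expect_identical(classify_activity(TRUE, 50, th), "hyperactive")  # boundary
  expect_identical(classify_activity(TRUE, 10, th), "slightly_active")
})

test_that("call_secretion combines channels and classifies each well once", {
  th <- threshold_set(structure(1, degenerate = FALSE))
  mk <- function(id, ch, vals) tibble::tibble(well_id = id, channel = ch,
                                              frame = seq_along(vals),
                                              time = seq_along(vals), css = vals)
  tbl <- dplyr::bind_rows(
    mk("w1", "IL5", c(0, 0, 0, 0, 0, 0)),          # silent
    mk("w1", "IL13", c(0, 0, 0, 0, 0, 0)),
    mk("w2", "IL5", c(0, 5, 6, 7, 8, 8)),          # slightly active
    mk("w2", "IL13", c(0, 0, 0, 0, 0, 0)),
    mk("w3", "IL5", c(0, 0, 0, 0, 0, 0)),          # hyperactive via IL-13 only
    mk("w3", "IL13", c(0, 20, 60, 80, 90, 95))
  )
  calls <- call_secretion(tbl, th)
  per_well <- dplyr::distinct(calls, well_id, class)
  expect_equal(nrow(per_well), 3)
  expect_identical(per_well$class[per_well$well_id == "w1"], "silent")
  expect_identical(per_well$class[per_well$well_id == "w2"], "slightly_active")
  expect_identical(per_well$class[per_well$well_id == "w3"], "hyperactive")
  # onset of w2 is the first supra frame
  expect_equal(calls$onset_frame[calls$well_id == "w2" & calls$channel == "IL5"], 2)
  # class counts partition the wells
  expect_equal(sum(table(per_well$class)), 3)
})

test_that("activation curve is the empirical cumulative onset function", {
  calls <- tibble::tibble(
    well_id = sprintf("w%d", 1:10),
    positive = c(rep(TRUE, 6), rep(FALSE, 4)),
    onset_time = c(1, 1, 2, 4, 4, 4, NA, NA, NA, NA)
  )
  ac <- activation_curve(calls, horizon = 10)
  expect_equal(ac$fraction_active[ac$time == 1], 0.2)
  expect_equal(max(ac$fraction_active), 0.6)
  expect_equal(ac$n_risk[1], 10)
  # all wells onset at t = 1: single step from 0 to 1
  one <- tibble::tibble(well_id = c("a", "b"), positive = TRUE, onset_time = 1)
  ac1 <- activation_curve(one, horizon = 5)
  expect_equal(ac1$fraction_active[ac1$time == 1], 1)
  # no onsets: flat zero, everything censored
  none <- tibble::tibble(well_id = c("a", "b", "c"), positive = FALSE,
                         onset_time = NA_real_)
  ac0 <- activation_curve(none, horizon = 5)
  expect_true(all(ac0$fraction_active == 0))
  expect_error(activation_curve(none[0, ], 5), "no calls")
})

test_that("exponential onsets reproduce their cumulative distribution", {
  set.seed(71)
  lambda <- 0.2
  n <- 800
  onsets <- stats::rexp(n, lambda)
  horizon <- 30
  calls <- tibble::tibble(well_id = sprintf("w%d", 1:n),
                          positive = onsets <= horizon,
                          onset_time = ifelse(onsets <= horizon, onsets, NA))
  ac <- activation_curve(calls, horizon)
  for (tt in c(2, 5, 10, 20)) {
    emp <- max(c(0, ac$fraction_active[ac$time <= tt]))
    expected <- 1 - exp(-lambda * tt)
    expect_lt(abs(emp - expected), 3 * sqrt(expected * (1 - expected) / n))
  }
})

test_that("group comparison applies BH across the pairwise family", {
  # hand application of the step-up formula on known raw p-values:
  # {0.01, 0.02, 0.03} with m = 3 adjusts to {0.03, 0.03, 0.03}
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), method = "BH"), rep(0.03, 3))

  set.seed(13)
  df <- tibble::tibble(
    group = rep(c("a", "b", "c"), each = 200),
    value = c(rnorm(200), rnorm(200, 1), rnorm(200))
  )
  res <- compare_groups(df, "group", value = "value", method = "mannwhitney")
  expect_equal(nrow(res), 3)
  expect_equal(res$p.adjust, p.adjust(res$p.value, "BH"))
  ab <- res[res$group1 == "a" & res$group2 == "b", ]
  expect_lt(ab$p.adjust, 0.001)      # 1-SD shift at n = 200 is decisive
  expect_identical(ab$signif, "***")
  ac_row <- res[res$group1 == "a" & res$group2 == "c", ]
  expect_gt(ac_row$p.value, 0.01)
  # all-tied data warns and returns p = 1
  tied <- tibble::tibble(group = rep(c("a", "b"), each = 5), value = 1)
  expect_warning(rt <- compare_groups(tied, "group", value = "value"),
                 "tied")
  expect_equal(rt$p.value, 1)
})

test_that("log-rank comparison: identical groups give statistic 0", {
  df <- tibble::tibble(
    group = rep(c("a", "b"), each = 6),
    time = rep(c(1, 2, 3, 4, 5, 6), 2),
    event = rep(TRUE, 12)
  )
  res <- compare_groups(df, "group", time = "time", event = "event",
                        method = "logrank")
  expect_lt(res$statistic, 1e-10)
  expect_equal(res$p.value, 1)
  # clearly separated onset distributions are detected
  set.seed(41)
  df2 <- tibble::tibble(
    group = rep(c("early", "late"), each = 80),
    time = c(stats::rexp(80, 1), stats::rexp(80, 0.2)),
    event = TRUE
  )
  res2 <- compare_groups(df2, "group", time = "time", event = "event",
                         method = "logrank")
  expect_lt(res2$p.adjust, 0.001)
})

test_that("k-means split concords with the 50-sigma rule on separated data", {
  th <- threshold_set(structure(1, degenerate = FALSE))
  set.seed(19)
  n <- 60
  vals <- c(10^runif(n / 2, 0.5, 1.2), 10^runif(n / 2, 2, 3))  # 3-16 vs 100-1000
  tbl <- purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(well_id = sprintf("w%02d", i), channel = "IL5",
                   frame = 1:6, time = 1:6,
                   css = c(0, rep(vals[i], 5)))
  })
  calls <- call_secretion(tbl, th)
  chk <- kmeans_activity_check(calls, th)
  expect_equal(chk$concordance, 1)
  expect_lt(chk$centers[1], chk$centers[2])
})
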