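mk_traces <- function(value_list) {
  out <- tibble::tibble(
    track_id = seq_along(value_list),
    baseline = 1, baseline_n = 1L, valid = TRUE,
    raw = value_list, values = value_list
  )
  class(out) <- c("cal_traces", class(out))
  out
}

test_that("identical constant traces produce no outliers (zero-variance rule)", {
  tr <- mk_traces(rep(list(rep(1, 10)), 5))
  ro <- remove_outliers(tr, 3)
  expect_length(ro$removed_ids, 0L)
  expect_equal(nrow(ro$kept), 5L)
})

test_that("a single wild track is removed by the pooled Z rule", {
  vals <- rep(list(rep(1, 25)), 20)
  vals[[21]] <- c(rep(1, 24), 50)
  tr <- mk_traces(vals)
  ro <- remove_outliers(tr, 3)
  expect_equal(ro$removed_ids, 21L)
  # direct pooled-Z computation confirms
  pooled <- unlist(vals)
  z <- abs((50 - mean(pooled)) / sd(pooled))
  expect_gt(z, 3)
})

test_that("infinite cutoff removes nothing; removal is idempotent", {
  withr::local_seed(61)
  tr <- mk_traces(lapply(1:10, function(i) runif(25, 0.8, 1.4)))
  expect_length(remove_outliers(tr, Inf)$removed_ids, 0L)
  ro1 <- remove_outliers(tr, 2)
  # a second pass under the original pooled statistics removes nothing
  mu <- ro1$pooled_mean; sdev <- ro1$pooled_sd
  again <- vapply(ro1$kept$values, function(v) any(abs((v - mu) / sdev) > 2),
                  logical(1))
  expect_false(any(again))
})

test_that("mean activity is spikes per cell per minute", {
  expect_equal(mean_activity(8, 10, 2), 0.4)
  expect_equal(mean_activity(0, 10, 2), 0)
  expect_error(mean_activity(1, 0, 2), "n_cells")
  expect_error(mean_activity(1, 5, 0), "duration")
  # 25 frames at 5 s span 2 minutes
  fs <- frame_stack(array(1, c(4, 4, 25)), frame_interval_s = 5)
  expect_equal(stack_duration_min(fs), 2)
})

test_that("paired t on identical vectors is t = 0, p = 1", {
  x <- c(0.4, 0.5, 0.6)
  res <- paired_ttest(x, x)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_equal(res$df, 2L)
})

test_that("paired t matches the textbook formula on a hand-worked example", {
  pre <- c(1, 2, 3); post <- c(2, 4, 6)
  res <- paired_ttest(pre, post)
  d <- post - pre
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  p_hand <- 2 * pt(-abs(t_hand), df = 2)
  expect_equal(res$t, t_hand, tolerance = 1e-9)
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(res$p, p_hand, tolerance = 1e-9)
  expect_equal(res$df, 2)
})

test_that("paired t is antisymmetric and guards degenerate input", {
  withr::local_seed(62)
  pre <- runif(6); post <- runif(6)
  expect_equal(paired_ttest(pre, post)$t, -paired_ttest(post, pre)$t)
  expect_error(paired_ttest(1, 2), "insufficient pairs")
  expect_error(paired_ttest(c(1, 2), c(2, 3)), "degenerate")
})

test_that("tidy and glance expose broom-style summaries", {
  res <- paired_ttest(c(1, 2, 3), c(2, 4, 6))
  td <- tidy(res)
  expect_equal(td$statistic, res$t)
  expect_equal(td$p.value, res$p)
  gl <- glance(res)
  expect_equal(gl$nobs, 3L)
})

test_that("the spike map contains exactly the cells peaking at that frame", {
  tb <- tibble::tibble(track_id = rep(1:3, each = 2), frame = rep(0:1, 3),
                       mean_intensity = 1, area_px = 5L,
                       x = rep(c(10.5, 3, 8), each = 2),
                       y = rep(c(20, 4, 9), each = 2))
  calls <- tibble::tibble(track_id = 3L, peak_frame = 1L,
                          rule = "single_step", magnitude_pct = 12)
  expect_equal(nrow(spike_map(tb, calls, 0L)), 0L)
  sm <- spike_map(tb, calls, 1L)
  expect_equal(sm$track_id, 3L)
  expect_equal(sm$x, 8)
  expect_equal(sm$y, 9)
  expect_error(spike_map(tb, calls, 5L), "out of range")
})

test_that("scheduled spikes appear on the map at their scheduled frames", {
  sched <- tibble::tibble(cell = c(2L, 4L), peak_frame = c(9L, 16L),
                          amplitude = 0.3, decay_frames = 3L)
  mv <- tiny_movie(seed = 12, n_cells = 5L, schedule = sched)
  tb <- measure_tracks(mv$stack, mv$truth$mask)
  bg <- sample_background(mv$stack, mv$truth$mask, 100, 4)
  nt <- normalize_traces(subtract_background(tb, bg), 10)
  calls <- detect_spikes(nt, 10)
  expect_equal(spike_map(tb, calls, 9L)$track_id, 2L)
  expect_equal(spike_map(tb, calls, 16L)$track_id, 4L)
})

test_that("trial summary enforces its accounting invariants", {
  s <- trial_summary("t1", "pre", "1 V/cm", 10, 8, 16, 2, c(1L, 4L))
  expect_equal(s$mean_activity, 16 / (8 * 2))
  expect_error(trial_summary("t1", "pre", "", 5, 8, 1, 2), "more cells")
  gl <- glance(s)
  expect_equal(gl$n_spikes, 16L)
  expect_equal(gl$n_active, 2L)
})
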