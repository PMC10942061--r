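track_tbl <- function(traces) {
  # traces: list of numeric vectors, one per track
  Tn <- length(traces[[1]])
  tibble::tibble(
    track_id = rep(seq_along(traces), each = Tn),
    frame = rep(seq_len(Tn) - 1L, length(traces)),
    mean_intensity = unlist(traces),
    area_px = 10L, x = 0, y = 0
  )
}

test_that("background sampling is seeded, unique, outside ROIs, and averaged per frame", {
  mv <- tiny_movie(seed = 6, n_cells = 4L)
  m <- mv$truth$mask
  b1 <- sample_background(mv$stack, m, n = 100, seed = 7)
  b2 <- sample_background(mv$stack, m, n = 100, seed = 7)
  expect_identical(b1$coords, b2$coords)
  expect_equal(nrow(b1$coords), 100L)
  expect_equal(anyDuplicated(b1$coords), 0L)
  labs <- unclass(m)[cbind(b1$coords$row + 1L, b1$coords$col + 1L)]
  expect_true(all(labs == 0L))
  b3 <- sample_background(mv$stack, m, n = 100, seed = 8)
  expect_false(identical(b1$coords, b3$coords))
})

test_that("constant background frames give that constant as the per-frame mean", {
  frames <- array(200, c(16, 16, 5))
  m <- matrix(0L, 16, 16); m[2:5, 2:5] <- 1L
  frames[2:5, 2:5, ] <- 900
  bg <- sample_background(frame_stack(frames), label_mask(m), n = 50, seed = 1)
  expect_equal(bg$per_frame_mean, rep(200, 5))
})

test_that("requesting more background pixels than exist uses all with a warning", {
  frames <- array(100, c(8, 8, 2))
  m <- matrix(1L, 8, 8)
  m[1:5, 1:8] <- 0L  # 40 background pixels
  expect_warning(
    bg <- sample_background(frame_stack(frames), label_mask(m), n = 100, seed = 1),
    "40"
  )
  expect_equal(bg$n_sampled, 40L)
  m2 <- label_mask(matrix(1L, 8, 8))
  expect_error(sample_background(frame_stack(frames), m2, 10, 1), "no background")
})

test_that("per-frame background means subtract from matching frames only", {
  tb <- track_tbl(list(c(500, 500, 500, 500)))
  bg <- structure(list(per_frame_mean = c(0, 100, 200, 50)),
                  class = "background_sample")
  out <- subtract_background(tb, bg)
  expect_equal(out$mean_intensity, c(500, 400, 300, 450))
  # zero background is the identity
  bg0 <- structure(list(per_frame_mean = rep(0, 4)), class = "background_sample")
  expect_equal(subtract_background(tb, bg0), tb)
  short <- structure(list(per_frame_mean = rep(0, 2)), class = "background_sample")
  expect_error(subtract_background(tb, short), "misalignment")
})

test_that("background-subtracted traces track the noise-free truth on a noisy movie", {
  sched <- tibble::tibble(cell = 1:3, peak_frame = 10L, amplitude = 0.3,
                          decay_frames = 3L)
  mv <- tiny_movie(seed = 9, n_cells = 6L, schedule = sched, read_noise_sd = 5)
  tb <- measure_tracks(mv$stack, mv$truth$mask)
  bg <- sample_background(mv$stack, mv$truth$mask, n = 100, seed = 2)
  sub <- subtract_background(tb, bg)
  truth <- mv$truth$traces - mv$truth$background_offset
  err <- abs(sub$mean_intensity -
               truth[cbind(sub$track_id, sub$frame + 1L)])
  # bg-estimator error ~sigma/10 per frame plus per-cell mean noise
  expect_lt(mean(err), 3 * 5 / sqrt(100) + 1)
})

test_that("baseline search implements the first >=10% crossing rule", {
  raw <- c(100, 105, 115, 120, 110)
  nt <- normalize_traces(track_tbl(list(raw)), threshold_pct = 10)
  expect_equal(nt$baseline_n, 2L)
  expect_equal(nt$baseline, 102.5)
  expect_equal(nt$values[[1]][1:3], c(100, 105, 115) / 102.5, tolerance = 1e-12)
  expect_true(nt$valid)
})

test_that("a never-crossing trace falls back to its whole-trace mean", {
  raw <- rep(100, 25)
  nt <- normalize_traces(track_tbl(list(raw)), 10)
  expect_equal(nt$baseline_n, 25L)
  expect_equal(nt$baseline, 100)
  expect_equal(nt$values[[1]], rep(1, 25))
})

test_that("normalization is scale invariant and flags non-positive baselines", {
  withr::local_seed(51)
  raw <- runif(25, 200, 400)
  for (c0 in c(0.1, 1, 7, 100)) {
    a <- normalize_traces(track_tbl(list(raw)), 10)
    b <- normalize_traces(track_tbl(list(raw * c0)), 10)
    expect_equal(b$values[[1]], a$values[[1]], tolerance = 1e-12)
    expect_equal(b$baseline_n, a$baseline_n)
  }
  neg <- normalize_traces(track_tbl(list(rep(-5, 25))), 10)
  expect_false(neg$valid)
  # first value 0: crossing undefined, whole-trace mean is the baseline
  z <- normalize_traces(track_tbl(list(c(0, rep(10, 24)))), 10)
  expect_equal(z$baseline_n, 25L)
  expect_true(z$valid)
})

test_that("a single >=10% step before a peak is a single_step spike", {
  calls <- detect_spikes(as_traces(c(1.0, 1.15, 1.0)), 10)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$peak_frame, 1L)
  expect_equal(calls$rule, "single_step")
  expect_equal(calls$magnitude_pct, 15, tolerance = 1e-9)
})

test_that("a slow multi-step rise qualifies through the cumulative rule", {
  v <- c(1.0, 1.04, 1.09, 1.15, 1.0)
  steps <- 100 * diff(v[1:4]) / v[1:3]
  expect_true(all(steps < 10))
  calls <- detect_spikes(as_traces(v), 10)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$rule, "cumulative")
  expect_equal(calls$peak_frame, 3L)
  expect_equal(calls$magnitude_pct, sum(steps), tolerance = 1e-9)
})

test_that("constant traces have no peaks and no spikes", {
  expect_equal(nrow(detect_spikes(as_traces(rep(1, 25)), 10)), 0L)
})

test_that("spike detection matches the brute-force oracle on 1000 random traces", {
  withr::local_seed(52)
  for (i in 1:1000) {
    v <- runif(25, 0.5, 1.5)
    if (i > 500) v <- round(v, 2)  # induce plateaus and ties
    got <- detect_spikes(as_traces(v), 10)
    want <- oracle_spikes(v, 10)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$peak_frame, want$peak_frame)
      expect_equal(got$rule, want$rule)
      expect_equal(got$magnitude_pct, want$magnitude_pct, tolerance = 1e-12)
    }
  }
})

test_that("raising the threshold never increases the number of spikes", {
  withr::local_seed(53)
  for (i in 1:50) {
    v <- round(runif(25, 0.5, 1.5), if (i %% 2) 10 else 2)
    counts <- vapply(c(5, 10, 15, 20),
                     function(th) nrow(detect_spikes(as_traces(v), th)),
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("spike calls are invariant to rescaling the raw trace", {
  withr::local_seed(54)
  raw <- runif(25, 200, 400)
  for (c0 in c(0.5, 7, 100)) {
    a <- detect_spikes(normalize_traces(track_tbl(list(raw)), 10), 10)
    b <- detect_spikes(normalize_traces(track_tbl(list(raw * c0)), 10), 10)
    expect_equal(a$peak_frame, b$peak_frame)
    expect_equal(a$magnitude_pct, b$magnitude_pct, tolerance = 1e-9)
  }
})

test_that("active cells are exactly the tracks with at least one call", {
  calls <- tibble::tibble(track_id = c(2L, 2L, 5L), peak_frame = c(1L, 5L, 3L),
                          rule = "single_step", magnitude_pct = 12)
  expect_equal(active_cells(calls), c(2L, 5L))
  expect_length(active_cells(calls[0, ]), 0L)
})

test_that("scheduled spiking cells are the active set end-to-end", {
  sched <- tibble::tibble(cell = c(1L, 3L), peak_frame = c(8L, 14L),
                          amplitude = 0.25, decay_frames = 3L)
  mv <- tiny_movie(seed = 10, n_cells = 5L, schedule = sched)
  tb <- measure_tracks(mv$stack, mv$truth$mask)
  bg <- sample_background(mv$stack, mv$truth$mask, 100, 3)
  nt <- normalize_traces(subtract_background(tb, bg), 10)
  calls <- detect_spikes(nt, 10)
  expect_equal(active_cells(calls), c(1L, 3L))
})
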