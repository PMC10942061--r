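# Independent brute-force oracles, deliberately written with different
# algorithms than the package internals they cross-check.

# pixelwise loop maximum over frames
oracle_max_composite <- function(frames) {
  d <- dim(frames)
  out <- frames[, , 1]
  for (t in seq_len(d[3])[-1]) {
    for (r in seq_len(d[1])) {
      for (cc in seq_len(d[2])) {
        if (frames[r, cc, t] > out[r, cc]) out[r, cc] <- frames[r, cc, t]
      }
    }
  }
  out
}

# per-pixel accumulation of sums/areas/centroids
oracle_measure <- function(frames, labels) {
  d <- dim(frames)
  nc <- max(labels)
  sums <- matrix(0, nc, d[3])
  area <- integer(nc)
  sx <- numeric(nc); sy <- numeric(nc)
  for (r in seq_len(d[1])) {
    for (cc in seq_len(d[2])) {
      l <- labels[r, cc]
      if (l == 0L) next
      area[l] <- area[l] + 1L
      sx[l] <- sx[l] + (cc - 1L)
      sy[l] <- sy[l] + (r - 1L)
      for (t in seq_len(d[3])) sums[l, t] <- sums[l, t] + frames[r, cc, t]
    }
  }
  list(mean = sums / area, area = area, x = sx / area, y = sy / area)
}

# enumerate every index, classify peaks, test both spike criteria
oracle_spikes <- function(v, thr) {
  Tt <- length(v)
  peaks <- integer(0)
  t <- 2L
  while (t <= Tt - 1L) {
    if (v[t] > v[t - 1L]) {
      e <- t
      while (e < Tt && v[e + 1L] == v[t]) e <- e + 1L
      if (e < Tt && v[e + 1L] < v[t]) peaks <- c(peaks, t)
      t <- e + 1L
    } else {
      t <- t + 1L
    }
  }
  if (v[Tt] > v[Tt - 1L]) peaks <- c(peaks, Tt)

  out <- data.frame(peak_frame = integer(0), rule = character(0),
                    magnitude_pct = numeric(0))
  for (t in peaks) {
    if (v[t - 1L] <= 0) next
    p_t <- 100 * (v[t] - v[t - 1L]) / v[t - 1L]
    if (p_t >= thr) {
      out <- rbind(out, data.frame(peak_frame = t - 1L, rule = "single_step",
                                   magnitude_pct = p_t))
      next
    }
    # trough: one past the last downward step before the peak
    drops <- which(diff(v[seq_len(t - 1L)]) < 0)
    m <- if (length(drops)) max(drops) + 1L else 1L
    seg <- m:t
    if (any(v[seg[-length(seg)]] <= 0)) next
    cum <- 100 * sum(diff(v[seg]) / v[seg[-length(seg)]])
    if (cum >= thr) {
      out <- rbind(out, data.frame(peak_frame = t - 1L, rule = "cumulative",
                                   magnitude_pct = cum))
    }
  }
  out
}

# wrap a plain numeric trace as a single-track cal_traces table
as_traces <- function(v, track_id = 1L) {
  out <- tibble::tibble(track_id = track_id, baseline = 1, baseline_n = 1L,
                        valid = TRUE, raw = list(v), values = list(v))
  class(out) <- c("cal_traces", class(out))
  out
}

# small noise-free movie used across tests
tiny_movie <- function(seed = 1, n_cells = 6L, schedule = NULL,
                       read_noise_sd = 0, shot_noise = FALSE,
                       background_offset = 200, image_size = c(128L, 128L)) {
  generate_movie(synth_params(
    image_size = image_size, n_cells = n_cells,
    spike_schedule = schedule, read_noise_sd = read_noise_sd,
    shot_noise = shot_noise, background_offset = background_offset,
    seed = seed
  ))
}
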