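#' Sample background pixels outside all ROIs
#'
#' Fluorescence recordings carry background from excess dye and thermal
#' camera fluctuation. A well-distributed background estimate is obtained by
#' drawing pixel locations uniformly at random from outside every ROI
#' (mask value 0, checked explicitly), without replacement, and averaging
#' them per frame. One fixed coordinate set serves all frames.
#'
#' @param stack A [frame_stack()].
#' @param mask A [label_mask()] matching the stack frames.
#' @param n Number of background pixels to draw (default 100). If fewer are
#'   available, all of them are used and a warning is emitted.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A `background_sample`: list with `coords` (tibble of 0-based
#'   `row`, `col`), `per_frame_mean` (length-T vector), `n_requested`,
#'   `n_sampled`, `seed`.
#' @export
sample_background <- function(stack, mask, n = 100L, seed = 1L) {
  stopifnot(inherits(stack, "frame_stack"), inherits(mask, "label_mask"))
  d <- dim(stack$frames)
  if (!identical(d[1:2], dim(unclass_mask(mask)))) {
    abort("stack and mask dimensions differ.")
  }
  if (n < 1L) abort("`n` must be >= 1.")
  labv <- as.vector(unclass_mask(mask))
  bg_idx <- which(labv == 0L)
  if (length(bg_idx) == 0L) abort("no background: every pixel belongs to an ROI.")
  n_take <- min(as.integer(n), length(bg_idx))
  if (n_take < n) {
    warn(sprintf("only %d background pixels available (requested %d); using all.",
                 length(bg_idx), n))
  }
  take <- withr::with_seed(as.integer(seed), sample(bg_idx, n_take))
  stopifnot(all(labv[take] == 0L))       # every sampled pixel is outside ROIs
  flat <- matrix(stack$frames, nrow = d[1] * d[2], ncol = d[3])
  pfm <- colMeans(flat[take, , drop = FALSE])
  structure(
    list(
      coords = tibble(row = (take - 1L) %% d[1], col = (take - 1L) %/% d[1]),
      per_frame_mean = as.numeric(pfm),
      n_requested = as.integer(n),
      n_sampled = n_take,
      seed = as.integer(seed)
    ),
    class = "background_sample"
  )
}

#' Subtract the per-frame background mean from a track table
#'
#' @param table A track table from [measure_tracks()].
#' @param bg A `background_sample` from [sample_background()] covering every
#'   frame present in `table`.
#' @return The table with `mean_intensity` replaced by the
#'   background-subtracted value (may be negative); other columns untouched.
#' @export
subtract_background <- function(table, bg) {
  stopifnot(is.data.frame(table), inherits(bg, "background_sample"))
  Tn <- length(bg$per_frame_mean)
  if (any(table$frame < 0L) || any(table$frame >= Tn)) {
    abort(sprintf(
      "frame misalignment: table frames span %d..%d but background covers 0..%d",
      min(table$frame), max(table$frame), Tn - 1L
    ))
  }
  mutate(table,
         mean_intensity = .data$mean_intensity - bg$per_frame_mean[.data$frame + 1L])
}

#' Normalize background-subtracted traces to per-cell baselines
#'
#' Dye loading varies from cell to cell with size, cluster position and
#' uptake, so intensities are only comparable after dividing each trace by
#' a per-cell baseline. The baseline is found by scanning forward for the
#' first point whose absolute change from the first recorded intensity
#' reaches `threshold_pct`; the mean of the points strictly before that
#' crossing is the baseline. A trace that never crosses uses the mean of
#' all its points instead (as does a trace whose first value is 0, where
#' the fractional-change test is undefined). Traces whose baseline is not
#' positive are flagged invalid rather than dropped.
#'
#' @param table A background-subtracted track table.
#' @param threshold_pct Percent change defining the crossing (default 10).
#' @return A `cal_traces` tibble, one row per track:
#'   `track_id, baseline, baseline_n, valid`, plus list-columns `raw`
#'   (background-subtracted trace) and `values` (`raw / baseline`).
#' @export
normalize_traces <- function(table, threshold_pct = 10) {
  stopifnot(is.data.frame(table))
  if (threshold_pct <= 0) abort("`threshold_pct` must be > 0.")
  tb <- arrange(table, .data$track_id, .data$frame)
  ids <- unique(tb$track_id)
  raws <- split(tb$mean_intensity, factor(tb$track_id, levels = ids))
  Tn <- length(raws[[1]])
  if (Tn < 2L) abort("need at least 2 frames to normalize.")

  one <- function(raw) {
    Tt <- length(raw)
    if (raw[1] == 0) {
      baseline <- mean(raw)
      baseline_n <- Tt
    } else {
      chg <- abs(raw - raw[1]) / abs(raw[1])
      tstar <- which(chg >= threshold_pct / 100)
      tstar <- tstar[tstar >= 2L]
      if (length(tstar)) {
        t1 <- tstar[1]
        baseline_n <- t1 - 1L
        baseline <- mean(raw[seq_len(baseline_n)])
      } else {
        baseline_n <- Tt
        baseline <- mean(raw)
      }
    }
    list(baseline = baseline, baseline_n = as.integer(baseline_n),
         valid = baseline > 0, values = raw / baseline)
  }
  res <- unname(lapply(raws, one))
  out <- tibble(
    track_id = ids,
    baseline = map_dbl(res, "baseline"),
    baseline_n = map_int(res, "baseline_n"),
    valid = map_lgl(res, "valid"),
    raw = unname(raws),
    values = lapply(res, function(r) r$values)
  )
  class(out) <- c("cal_traces", class(out))
  attr(out, "threshold_pct") <- threshold_pct
  out
}

# peak positions (1-based) of a numeric trace: interior strict local maxima
# with plateaus reported at their first index, plus a strictly rising final
# point
find_peaks <- function(v) {
  Tt <- length(v)
  if (Tt < 2L) return(integer(0))
  r <- rle(v)
  k <- length(r$values)
  starts <- cumsum(c(1L, r$lengths[-k]))
  peaks <- integer(0)
  if (k >= 3L) {
    for (j in 2:(k - 1L)) {
      if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L]) {
        peaks <- c(peaks, starts[j])
      }
    }
  }
  if (v[Tt] > v[Tt - 1L]) peaks <- c(peaks, Tt)
  sort(unique(peaks))
}

# trough preceding a peak: walk back while the ascent (weakly) continues
preceding_trough <- function(v, t) {
  m <- t - 1L
  while (m > 1L && v[m - 1L] <= v[m]) m <- m - 1L
  m
}

spike_calls_one <- function(v, threshold_pct) {
  peaks <- find_peaks(v)
  out <- list()
  for (t in peaks) {
    if (v[t - 1L] <= 0) next           # percent change undefined/degenerate
    p_t <- 100 * (v[t] - v[t - 1L]) / v[t - 1L]
    if (p_t >= threshold_pct) {
      out[[length(out) + 1L]] <- list(peak = t, rule = "single_step",
                                      magnitude = p_t)
    } else {
      m <- preceding_trough(v, t)
      s <- (m + 1L):t
      if (any(v[s - 1L] <= 0)) next
      cum <- 100 * sum((v[s] - v[s - 1L]) / v[s - 1L])
      if (cum >= threshold_pct) {
        out[[length(out) + 1L]] <- list(peak = t, rule = "cumulative",
                                        magnitude = cum)
      }
    }
  }
  out
}

#' Detect calcium spikes in normalized traces
#'
#' A peak of a normalized trace is an interior strict local maximum
#' (plateaus count once, at their first index), or a final point that rises
#' above its predecessor. Writing `p_t` for the percent change of the trace
#' from point `t-1` to `t`, a peak is called a spike when either
#' \itemize{
#'   \item \strong{single_step}: `p_t >= threshold_pct` -- a single percent
#'     change of at least the threshold immediately preceding the peak; or
#'   \item \strong{cumulative}: the sum of the percent changes over the
#'     ascent from the preceding trough to the peak reaches the threshold,
#'     catching slow multi-frame rises no single step of which qualifies.
#' }
#' Each peak yields at most one call; the single-step rule is checked first.
#' Invalid traces are skipped with a message.
#'
#' @param traces A `cal_traces` tibble from [normalize_traces()].
#' @param threshold_pct Spike threshold in percent (default 10).
#' @return A tibble of spike calls: `track_id`, `peak_frame` (0-based),
#'   `rule` (`"single_step"` or `"cumulative"`), `magnitude_pct`.
#' @export
detect_spikes <- function(traces, threshold_pct = 10) {
  stopifnot(inherits(traces, "cal_traces"))
  if (threshold_pct <= 0) abort("`threshold_pct` must be > 0.")
  rows <- list()
  for (i in seq_len(nrow(traces))) {
    if (!traces$valid[i]) {
      inform(sprintf("track %s skipped: non-positive baseline.",
                     traces$track_id[i]))
      next
    }
    calls <- spike_calls_one(traces$values[[i]], threshold_pct)
    for (cl in calls) {
      rows[[length(rows) + 1L]] <- tibble(
        track_id = traces$track_id[i],
        peak_frame = cl$peak - 1L,
        rule = cl$rule,
        magnitude_pct = cl$magnitude
      )
    }
  }
  if (length(rows) == 0L) {
    return(tibble(track_id = integer(0), peak_frame = integer(0),
                  rule = character(0), magnitude_pct = numeric(0)))
  }
  arrange(bind_rows(rows), .data$track_id, .data$peak_frame)
}

#' Cells with at least one spike
#'
#' An active cell is any cell that spikes at least once during an imaging
#' period.
#'
#' @param calls A spike-call tibble from [detect_spikes()].
#' @return Sorted vector of active track ids.
#' @export
active_cells <- function(calls) {
  stopifnot(is.data.frame(calls))
  sort(unique(calls$track_id))
}

#' Long-format view of normalized traces
#'
#' @param traces A `cal_traces` tibble.
#' @return A tibble with one row per (track, frame): `track_id, frame, raw,
#'   value, valid` (`frame` 0-based).
#' @export
trace_long <- function(traces) {
  stopifnot(inherits(traces, "cal_traces"))
  Tn <- length(traces$raw[[1]])
  tibble(
    track_id = rep(traces$track_id, each = Tn),
    frame = rep(seq_len(Tn) - 1L, times = nrow(traces)),
    raw = unlist(traces$raw, use.names = FALSE),
    value = unlist(traces$values, use.names = FALSE),
    valid = rep(traces$valid, each = Tn)
  )
}

#' Plot normalized traces, optionally with spike calls marked
#'
#' @param object A `cal_traces` tibble.
#' @param calls Optional spike-call tibble; called peaks are marked.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cal_traces <- function(object, calls = NULL, ...) {
  lng <- filter(trace_long(object), .data$valid)
  p <- ggplot(lng, aes(x = .data$frame, y = .data$value,
                       group = .data$track_id)) +
    geom_line(alpha = 0.5) +
    labs(x = "frame", y = "normalized intensity (a.u.)") +
    theme_minimal()
  if (!is.null(calls) && nrow(calls) > 0) {
    pts <- left_join(calls,
                     dplyr::rename(lng, peak_frame = "frame"),
                     by = c("track_id", "peak_frame"))
    p <- p + geom_point(data = pts,
                        aes(x = .data$peak_frame, y = .data$value),
                        colour = "red", inherit.aes = FALSE)
  }
  p
}
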