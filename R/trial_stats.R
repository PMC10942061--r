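#' Remove outlier tracks by pooled Z score
#'
#' Before trial statistics, tracks carrying implausible values (debris,
#' segmentation faults, focal drift) are discarded: every normalized value
#' is scored against the mean and sample standard deviation of *all*
#' normalized values pooled across the trial, computed once before any
#' removal, and a track is removed if any of its values exceeds `z_max` in
#' absolute value. With zero pooled variance nothing is removed. The
#' operation is idempotent under the fixed pooled statistics.
#'
#' Note that on recordings where most cells spike in near lock-step with
#' little background variability, genuine spike peaks can themselves exceed
#' the cutoff; `z_max = Inf` disables the filter.
#'
#' @param traces A `cal_traces` tibble (normally only valid traces).
#' @param z_max Absolute Z cutoff (default 3).
#' @return A list: `kept` (`cal_traces` tibble), `removed_ids`,
#'   `pooled_mean`, `pooled_sd`.
#' @export
remove_outliers <- function(traces, z_max = 3.0) {
  stopifnot(inherits(traces, "cal_traces"))
  if (z_max <= 0) abort("`z_max` must be > 0.")
  pooled <- unlist(traces$values, use.names = FALSE)
  if (length(pooled) < 2L) abort("need at least 2 pooled values for Z scores.")
  mu <- mean(pooled)
  sdev <- sd(pooled)
  if (is.na(sdev) || sdev == 0) {
    return(list(kept = traces, removed_ids = traces$track_id[0],
                pooled_mean = mu, pooled_sd = sdev))
  }
  bad <- map_lgl(traces$values, function(v) any(abs((v - mu) / sdev) > z_max))
  list(
    kept = traces[!bad, , drop = FALSE],
    removed_ids = traces$track_id[bad],
    pooled_mean = mu,
    pooled_sd = sdev
  )
}

#' Mean spiking activity of a trial
#'
#' Total spikes divided by cell count and imaging duration, in units of
#' spikes per cell per minute, so that trials of different length or cell
#' yield compare on one scale.
#'
#' @param n_spikes Total spike count for the trial.
#' @param n_cells Number of cells analysed (after outlier removal).
#' @param duration_min Imaging duration in minutes (see
#'   [stack_duration_min()]).
#' @return Spikes per cell per minute.
#' @export
mean_activity <- function(n_spikes, n_cells, duration_min) {
  if (n_cells < 1) abort("`n_cells` must be >= 1.")
  if (duration_min <= 0) abort("`duration_min` must be > 0.")
  n_spikes / (n_cells * duration_min)
}

#' Two-tailed paired t test on per-trial activities
#'
#' Tests pre- versus post-stimulation activity with trials as pairs:
#' differences `d = post - pre`, `t = mean(d) / (sd(d) / sqrt(m))` with the
#' sample standard deviation, and a two-sided p value on `m - 1` degrees of
#' freedom. Identical vectors give `t = 0, p = 1`; a constant nonzero
#' difference has no variance to test against and raises an error.
#'
#' @param pre,post Numeric vectors of equal length `m >= 2`, paired by trial.
#' @return A `paired_ttest` object with fields `t`, `p`, `df`, `m`,
#'   `mean_diff`, `sd_diff`; see [tidy()] / [glance()].
#' @export
paired_ttest <- function(pre, post) {
  if (length(pre) != length(post)) abort("`pre` and `post` must pair up.")
  m <- length(pre)
  if (m < 2L) abort("insufficient pairs: need at least 2 paired trials.")
  d <- post - pre
  sdd <- sd(d)
  if (sdd == 0) {
    if (mean(d) == 0) {
      res <- list(t = 0, p = 1, df = m - 1L, m = m, mean_diff = 0, sd_diff = 0)
      return(structure(res, class = "paired_ttest"))
    }
    abort("degenerate pairing: constant nonzero difference has zero variance.")
  }
  ht <- stats::t.test(post, pre, paired = TRUE, alternative = "two.sided")
  structure(
    list(t = unname(ht$statistic), p = ht$p.value,
         df = unname(ht$parameter), m = m,
         mean_diff = mean(d), sd_diff = sdd),
    class = "paired_ttest"
  )
}

#' @export
print.paired_ttest <- function(x, ...) {
  cat(sprintf("Paired t test: t = %.4g, df = %d, p = %.4g (mean diff %.4g, m = %d)\n",
              x$t, x$df, x$p, x$mean_diff, x$m))
  invisible(x)
}

#' @rdname paired_ttest
#' @param x A `paired_ttest` object.
#' @param ... Unused.
#' @export
tidy.paired_ttest <- function(x, ...) {
  tibble(
    estimate = x$mean_diff,
    statistic = x$t,
    p.value = x$p,
    parameter = x$df,
    method = "Paired t-test",
    alternative = "two.sided"
  )
}

#' @rdname paired_ttest
#' @export
glance.paired_ttest <- function(x, ...) {
  tibble(statistic = x$t, p.value = x$p, parameter = x$df, nobs = x$m)
}

#' Locate the cells spiking at a given frame
#'
#' Spatial view of activity: the centroids of exactly the cells with a
#' spike whose peak falls on the requested frame.
#'
#' @param table A track table (for centroids).
#' @param calls A spike-call tibble from [detect_spikes()].
#' @param frame 0-based frame index.
#' @return A tibble `track_id, x, y` (possibly empty).
#' @export
spike_map <- function(table, calls, frame) {
  stopifnot(is.data.frame(table), is.data.frame(calls))
  if (length(frame) != 1L || frame < 0L || frame > max(table$frame)) {
    abort(sprintf("frame %s out of range 0..%d", format(frame), max(table$frame)))
  }
  cents <- distinct(table, .data$track_id, .data$x, .data$y)
  hits <- filter(calls, .data$peak_frame == frame)
  out <- left_join(select(hits, "track_id"), cents, by = "track_id")
  arrange(out, .data$track_id)
}

#' Plot the spiking-cell map for one frame
#'
#' @param table A track table.
#' @param calls Spike calls.
#' @param frame 0-based frame index.
#' @return A ggplot with image-style axes (y increases downwards).
#' @export
plot_spike_map <- function(table, calls, frame) {
  sm <- spike_map(table, calls, frame)
  cents <- distinct(table, .data$track_id, .data$x, .data$y)
  ggplot(cents, aes(x = .data$x, y = .data$y)) +
    geom_point(colour = "grey70") +
    geom_point(data = sm, colour = "red", size = 3, shape = 1, stroke = 1.2) +
    scale_y_reverse() +
    coord_fixed() +
    labs(title = sprintf("cells spiking at frame %d", frame),
         x = "x (px)", y = "y (px)") +
    theme_minimal()
}

#' Summarise one trial
#'
#' @param trial_id Identifier for the trial.
#' @param period `"pre"` or `"post"`.
#' @param condition Free-text condition label (e.g. an EFS field strength in
#'   V/cm); metadata only.
#' @param n_cells_segmented Cells in the mask.
#' @param n_cells_after_outliers Cells analysed after outlier removal.
#' @param n_spikes Total spikes among analysed cells.
#' @param duration_min Imaging duration in minutes.
#' @param active_track_ids Ids of cells with at least one spike.
#' @return A `trial_summary` list; `mean_activity` is filled in when both
#'   denominators are positive, otherwise `NA`.
#' @export
trial_summary <- function(trial_id, period = c("pre", "post"), condition = "",
                          n_cells_segmented, n_cells_after_outliers, n_spikes,
                          duration_min, active_track_ids = integer(0)) {
  period <- match.arg(period)
  if (n_cells_after_outliers > n_cells_segmented) {
    abort("cannot keep more cells than were segmented.")
  }
  act <- if (n_cells_after_outliers > 0 && duration_min > 0) {
    mean_activity(n_spikes, n_cells_after_outliers, duration_min)
  } else {
    NA_real_
  }
  structure(
    list(trial_id = trial_id, condition = condition, period = period,
         n_cells_segmented = as.integer(n_cells_segmented),
         n_cells_after_outliers = as.integer(n_cells_after_outliers),
         n_spikes = as.integer(n_spikes),
         duration_min = as.numeric(duration_min),
         mean_activity = act,
         active_track_ids = as.integer(active_track_ids)),
    class = "trial_summary"
  )
}

#' @rdname trial_summary
#' @param x A `trial_summary`.
#' @param ... Unused.
#' @export
glance.trial_summary <- function(x, ...) {
  tibble(
    trial_id = x$trial_id, condition = x$condition, period = x$period,
    n_cells_segmented = x$n_cells_segmented,
    n_cells_after_outliers = x$n_cells_after_outliers,
    n_spikes = x$n_spikes, duration_min = x$duration_min,
    mean_activity = x$mean_activity,
    n_active = length(x$active_track_ids)
  )
}

#' @export
print.trial_summary <- function(x, ...) {
  cat(sprintf(
    "<trial_summary> %s [%s%s]: %d cells (%d kept), %d spikes over %.2g min, activity %.3g spikes/cell/min\n",
    x$trial_id, x$period,
    if (nzchar(x$condition)) paste0(", ", x$condition) else "",
    x$n_cells_segmented, x$n_cells_after_outliers, x$n_spikes,
    x$duration_min, x$mean_activity
  ))
  invisible(x)
}
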