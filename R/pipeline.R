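stage <- function(name, logf, expr) {
  res <- tryCatch(force(expr), error = function(e) {
    abort(sprintf("stage %s failed: %s", name, conditionMessage(e)))
  })
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), name)
  cat(line, "\n", file = logf, append = TRUE)
  res
}

#' Run the full calcium-imaging pipeline on one trial period
#'
#' Executes the whole chain in order: read the stack, build the max-value
#' composite, merge the nuclear channel if given, segment (built-in
#' fallback, external backend, or a precomputed mask), measure per-cell
#' tracks, sample and subtract background, normalize to per-cell baselines,
#' remove pooled-Z outliers, detect spikes, and write all artifacts to
#' `outdir`: `composite.tif`, `mask.tif`, `tracks.csv`, `traces.csv`,
#' `spikes.csv`, `summary.json`, `run.log`. The summary echoes the full
#' effective configuration including the seed, so a run is reproducible from
#' its summary alone (given the inputs).
#'
#' @param cell_stack Path to a TIFF stack, or a [frame_stack()].
#' @param outdir Output directory (created if needed).
#' @param config A [run_config()].
#' @param nuclear Optional nuclear-channel image: a TIFF path or `H x W`
#'   matrix.
#' @param mask Optional precomputed mask (TIFF path or [label_mask()]);
#'   skips segmentation.
#' @param backend Optional external segmentation backend function (used
#'   when `config$segmentation_backend == "external"`).
#' @param trial_id Trial identifier (default: `basename(outdir)`).
#' @param condition Condition label, e.g. an EFS field strength; metadata.
#' @param period `"pre"` or `"post"`.
#' @return Invisibly, a list with the `summary` ([trial_summary()]), the
#'   intermediate tables (`tracks`, `traces`, `spikes`, `kept`,
#'   `removed_ids`, `invalid_ids`, `mask`) and `paths` to the artifacts.
#' @export
run_pipeline <- function(cell_stack, outdir, config = run_config(),
                         nuclear = NULL, mask = NULL, backend = NULL,
                         trial_id = basename(outdir), condition = "",
                         period = c("pre", "post")) {
  period <- match.arg(period)
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(outdir, "run.log")
  cat(sprintf("[%s] run start: trial %s (%s)\n",
              format(Sys.time(), "%Y-%m-%d %H:%M:%S"), trial_id, period),
      file = logf)

  stk <- stage("read_stack", logf, {
    if (inherits(cell_stack, "frame_stack")) cell_stack
    else read_stack(cell_stack, frame_interval_s = config$frame_interval_s)
  })
  nuc <- NULL
  if (!is.null(nuclear)) {
    nuc <- stage("read_nuclear", logf, {
      if (is.matrix(nuclear)) nuclear
      else {
        s <- read_stack(nuclear)
        s$frames[, , 1L]
      }
    })
  }
  comp <- stage("max_composite", logf, {
    cc <- max_composite(stk)
    if (is.null(nuc)) cc else merge_channels(cc, nuc)
  })
  msk <- stage("segment", logf, {
    if (!is.null(mask)) {
      if (inherits(mask, "label_mask")) mask else read_label_mask(mask)
    } else if (config$segmentation_backend == "external") {
      segment_external(comp, backend,
                       min_cell_area_px = config$min_cell_area_px)
    } else {
      segment_fallback(comp,
                       smooth_sigma = config$smooth_sigma,
                       min_cell_area_px = config$min_cell_area_px,
                       use_nuclear_seeds = config$use_nuclear_seeds)
    }
  })
  cat(sprintf("  segmented %d cells\n", n_cells(msk)), file = logf, append = TRUE)

  tracks <- stage("measure_tracks", logf, measure_tracks(stk, msk))
  bg <- stage("sample_background", logf,
              sample_background(stk, msk, n = config$n_background_pixels,
                                seed = config$rng_seed))
  sub <- stage("subtract_background", logf, subtract_background(tracks, bg))
  traces <- stage("normalize_traces", logf,
                  normalize_traces(sub, threshold_pct = config$spike_threshold_pct))
  invalid_ids <- traces$track_id[!traces$valid]
  valid <- traces[traces$valid, , drop = FALSE]
  ro <- stage("remove_outliers", logf, remove_outliers(valid, config$z_max))
  cat(sprintf("  %d invalid, %d outlier track(s) removed\n",
              length(invalid_ids), length(ro$removed_ids)),
      file = logf, append = TRUE)
  calls <- stage("detect_spikes", logf,
                 detect_spikes(ro$kept, threshold_pct = config$spike_threshold_pct))

  dur <- stack_duration_min(stk)
  summ <- trial_summary(
    trial_id = trial_id, period = period, condition = condition,
    n_cells_segmented = n_cells(msk),
    n_cells_after_outliers = nrow(ro$kept),
    n_spikes = nrow(calls),
    duration_min = dur,
    active_track_ids = active_cells(calls)
  )

  paths <- list(
    composite = file.path(outdir, "composite.tif"),
    mask = file.path(outdir, "mask.tif"),
    tracks = file.path(outdir, "tracks.csv"),
    traces = file.path(outdir, "traces.csv"),
    spikes = file.path(outdir, "spikes.csv"),
    summary = file.path(outdir, "summary.json"),
    log = logf
  )
  stage("write_artifacts", logf, {
    write_stack(comp$cell, paths$composite)
    write_label_mask(msk, paths$mask)
    write_track_table(tracks, paths$tracks)

    lng <- trace_long(traces)
    lng$value[!lng$valid] <- NA_real_
    raw0 <- arrange(tracks, .data$track_id, .data$frame)
    tr_out <- data.frame(
      TRACK_ID = lng$track_id, FRAME = lng$frame,
      RAW = raw0$mean_intensity, BG_SUB = lng$raw, NORMALIZED = lng$value
    )
    write.csv(tr_out, paths$traces, row.names = FALSE, quote = FALSE)

    sp_out <- data.frame(TRACK_ID = calls$track_id,
                         PEAK_FRAME = calls$peak_frame,
                         RULE = calls$rule,
                         MAGNITUDE_PCT = calls$magnitude_pct)
    write.csv(sp_out, paths$spikes, row.names = FALSE, quote = FALSE)

    jsonlite::write_json(
      c(unclass(summ),
        list(removed_track_ids = as.integer(ro$removed_ids),
             invalid_track_ids = as.integer(invalid_ids),
             config = unclass(config))),
      paths$summary, auto_unbox = TRUE, digits = NA, null = "null"
    )
  })
  cat(sprintf("[%s] run complete: %d spikes from %d cells\n",
              format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
              summ$n_spikes, summ$n_cells_after_outliers),
      file = logf, append = TRUE)

  invisible(list(summary = summ, tracks = tracks, traces = traces,
                 spikes = calls, kept = ro$kept,
                 removed_ids = ro$removed_ids, invalid_ids = invalid_ids,
                 mask = msk, paths = paths))
}

read_summary <- function(x) {
  if (inherits(x, "trial_summary")) return(unclass(x))
  if (is.character(x)) return(jsonlite::read_json(x, simplifyVector = TRUE))
  if (is.list(x)) return(x)
  abort("summaries must be trial_summary objects, paths, or lists.")
}

#' Compare pre- and post-stimulation trial summaries
#'
#' Pairs trials by `trial_id`, then for each condition runs a two-tailed
#' paired t test on mean spiking activity (post vs pre) and reports the
#' activity deltas. Pre and post periods come from separate pipeline runs,
#' mirroring an acquisition protocol that records before and after (but not
#' during) stimulation.
#'
#' @param pre,post Lists/vectors of `summary.json` paths or
#'   [trial_summary()] objects, one per trial.
#' @param out Optional path; when given, the report is written there as
#'   JSON.
#' @return A tibble with one row per condition: `condition, m,
#'   mean_activity_pre, mean_activity_post, mean_delta, t, df, p`
#'   (`t`/`p` are `NA` for conditions with a single pair).
#' @export
compare_periods <- function(pre, post, out = NULL) {
  pre_s <- lapply(pre, read_summary)
  post_s <- lapply(post, read_summary)
  pre_ids <- vapply(pre_s, function(s) as.character(s$trial_id), character(1))
  post_ids <- vapply(post_s, function(s) as.character(s$trial_id), character(1))
  if (length(pre_s) != length(post_s) || !setequal(pre_ids, post_ids) ||
      anyDuplicated(pre_ids) || anyDuplicated(post_ids)) {
    abort(sprintf(
      "unpaired trials: pre has [%s], post has [%s]",
      paste(pre_ids, collapse = ", "), paste(post_ids, collapse = ", ")
    ))
  }
  post_s <- post_s[match(pre_ids, post_ids)]
  df <- tibble(
    trial_id = pre_ids,
    condition = vapply(pre_s, function(s) as.character(s$condition), character(1)),
    pre = vapply(pre_s, function(s) as.numeric(s$mean_activity), numeric(1)),
    post = vapply(post_s, function(s) as.numeric(s$mean_activity), numeric(1))
  )
  res <- df |>
    group_by(.data$condition) |>
    summarise(
      m = n(),
      mean_activity_pre = mean(.data$pre),
      mean_activity_post = mean(.data$post),
      mean_delta = mean(.data$post - .data$pre),
      t = if (n() >= 2) paired_ttest(.data$pre, .data$post)$t else NA_real_,
      df = if (n() >= 2) n() - 1L else NA_integer_,
      p = if (n() >= 2) paired_ttest(.data$pre, .data$post)$p else NA_real_,
      .groups = "drop"
    )
  if (!is.null(out)) {
    jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA)
  }
  res
}
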