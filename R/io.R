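#' Read a grayscale TIFF stack
#'
#' Reads a single- or multi-page grayscale TIFF into a [frame_stack()].
#' Pixel values are read as stored (`as.is`), so 8- and 16-bit integer data
#' round-trip bit-exactly through [write_stack()].
#'
#' @param path Path to a TIFF file.
#' @param frame_interval_s Seconds between frames (default 5).
#' @return A [frame_stack()] with `T` equal to the page count.
#' @export
read_stack <- function(path, frame_interval_s = 5) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) {
      abort(sprintf("unsupported format: %s is not a readable TIFF (%s)",
                    path, conditionMessage(e)))
    }
  )
  if (!is.list(pages)) pages <- list(pages)
  for (i in seq_along(pages)) {
    if (length(dim(pages[[i]])) != 2L) {
      abort(sprintf(
        "unsupported format: page %d of %s is not single-sample grayscale",
        i, path
      ))
    }
  }
  d1 <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), d1), logical(1)))) {
    abort(sprintf("pages of %s differ in size", path))
  }
  frames <- array(0, c(d1, length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]]
  frame_stack(frames, frame_interval_s = frame_interval_s)
}

#' Write a stack as a multi-page grayscale TIFF
#'
#' Values are rounded to the nearest integer and stored at the requested bit
#' depth; integer-valued stacks round-trip exactly through [read_stack()].
#'
#' @param stack A [frame_stack()] (or bare matrix/array).
#' @param path Output path.
#' @param bits Bits per sample, 8 or 16 (default 16).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  if (inherits(stack, "frame_stack")) stack <- stack$frames
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  if (!bits %in% c(8L, 16L)) abort("`bits` must be 8 or 16.")
  maxv <- 2^bits - 1
  vals <- round(stack)
  if (any(vals < 0) || any(vals > maxv)) {
    abort(sprintf("pixel values outside [0, %d] cannot be stored at %d bits",
                  maxv, bits))
  }
  pages <- lapply(seq_len(dim(vals)[3L]),
                  function(t) vals[, , t] / maxv)
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits)),
                 error = function(e) abort(sprintf("cannot write %s: %s", path,
                                                   conditionMessage(e))))
  invisible(path)
}

#' Write a label mask as a 16-bit TIFF
#'
#' @param mask A [label_mask()] (integer matrix, 0 = background).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  m <- unclass_mask(mask)
  if (max(m) > 65535) {
    abort(sprintf("depth overflow: %d labels exceed the 16-bit limit of 65535",
                  max(m)))
  }
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label mask from a TIFF
#'
#' @param path Path to a single-page 8- or 16-bit grayscale TIFF whose pixel
#'   values are cell labels (0 = background).
#' @return A [label_mask()].
#' @export
read_label_mask <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) != 2L) {
    abort(sprintf("unsupported format: %s is not a grayscale label image", path))
  }
  label_mask(m)
}

track_table_cols <- c("track_id", "frame", "mean_intensity", "area_px", "x", "y")

#' Write a track table to CSV
#'
#' The CSV uses TrackMate-like column names
#' (`TRACK_ID,FRAME,MEAN_INTENSITY,AREA,POSITION_X,POSITION_Y`) for
#' familiarity. `FRAME` is 0-based; positions are 0-based pixel coordinates
#' with x = column and y = row.
#'
#' @param table A track table from [measure_tracks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_table <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    abort("track table is empty; nothing to write.")
  }
  stopifnot(all(track_table_cols %in% names(table)))
  out <- table[order(table$track_id, table$frame), track_table_cols]
  names(out) <- c("TRACK_ID", "FRAME", "MEAN_INTENSITY", "AREA",
                  "POSITION_X", "POSITION_Y")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a track table written by [write_track_table()]
#'
#' @param path CSV path.
#' @return A tibble with columns `track_id, frame, mean_intensity, area_px, x, y`.
#' @export
read_track_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- read.csv(path, check.names = FALSE)
  expected <- c("TRACK_ID", "FRAME", "MEAN_INTENSITY", "AREA",
                "POSITION_X", "POSITION_Y")
  if (!all(expected %in% names(raw))) {
    abort(sprintf("%s lacks the track-table columns %s", path,
                  paste(setdiff(expected, names(raw)), collapse = ", ")))
  }
  out <- tibble(
    track_id = as.integer(raw$TRACK_ID),
    frame = as.integer(raw$FRAME),
    mean_intensity = as.numeric(raw$MEAN_INTENSITY),
    area_px = as.integer(raw$AREA),
    x = as.numeric(raw$POSITION_X),
    y = as.numeric(raw$POSITION_Y)
  )
  arrange(out, .data$track_id, .data$frame)
}

#' Run configuration
#'
#' Bundles the tunable parameters of a pipeline run. Defaults follow the
#' standard beta-cell calcium protocol: a 10% fractional-change spike
#' threshold, 100 randomly sampled background pixels, and |Z| > 3 outlier
#' removal.
#'
#' @param spike_threshold_pct Percent change that qualifies as spiking
#'   activity (default 10).
#' @param n_background_pixels Background pixels sampled outside all ROIs
#'   (default 100).
#' @param z_max Absolute pooled Z score beyond which a track is discarded as
#'   an outlier (default 3). Use `Inf` to disable outlier removal.
#' @param rng_seed Integer seed controlling background sampling (default 1).
#' @param min_cell_area_px Minimum object size kept by segmentation
#'   (default 50 px).
#' @param smooth_sigma Gaussian smoothing sigma in pixels used by the
#'   built-in segmenter (default 2).
#' @param use_nuclear_seeds Split touching cells with nuclear-channel seeds
#'   when a nuclear image is available (default TRUE).
#' @param segmentation_backend `"fallback"` (built-in, deterministic) or
#'   `"external"` (user-supplied adapter).
#' @param frame_interval_s Seconds between frames (default 5).
#' @return A `run_config` list.
#' @export
run_config <- function(spike_threshold_pct = 10,
                       n_background_pixels = 100L,
                       z_max = 3.0,
                       rng_seed = 1L,
                       min_cell_area_px = 50L,
                       smooth_sigma = 2.0,
                       use_nuclear_seeds = TRUE,
                       segmentation_backend = c("fallback", "external"),
                       frame_interval_s = 5) {
  segmentation_backend <- match.arg(segmentation_backend)
  if (spike_threshold_pct <= 0) abort("`spike_threshold_pct` must be > 0.")
  if (n_background_pixels < 1) abort("`n_background_pixels` must be >= 1.")
  if (z_max <= 0) abort("`z_max` must be > 0.")
  if (min_cell_area_px < 1) abort("`min_cell_area_px` must be >= 1.")
  if (smooth_sigma < 0) abort("`smooth_sigma` must be >= 0.")
  structure(
    list(
      spike_threshold_pct = as.numeric(spike_threshold_pct),
      n_background_pixels = as.integer(n_background_pixels),
      z_max = as.numeric(z_max),
      rng_seed = as.integer(rng_seed),
      min_cell_area_px = as.integer(min_cell_area_px),
      smooth_sigma = as.numeric(smooth_sigma),
      use_nuclear_seeds = isTRUE(use_nuclear_seeds),
      segmentation_backend = segmentation_backend,
      frame_interval_s = as.numeric(frame_interval_s)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Keys missing from the file fall back to the [run_config()] defaults;
#' unknown keys raise an error so typos do not pass silently.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    abort(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}
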