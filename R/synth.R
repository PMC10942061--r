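#' Parameters for the synthetic calcium movie generator
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' static disk-like cells scattered without overlap, a per-cell
#' multiplicative dye-loading factor `L_c` (lognormal), transient
#' multiplicative calcium spikes riding on a flat baseline, an additive
#' background offset with Gaussian read noise (truncated at 0) and optional
#' Poisson shot noise, and a nuclear channel of smaller concentric disks.
#' The noise-free value of a pixel of cell `c` at frame `t` is
#' `L_c * B * (1 + A * g(t)) + b`, where `g` is the spike kernel: 1 at the
#' scheduled peak, decaying as `exp(-3 j / k)` over the `k` following
#' frames, 0 elsewhere. Background pixels sit at `b` plus noise.
#'
#' @param image_size `(H, W)` in pixels (default 256 x 256).
#' @param n_cells Number of cells (default 20).
#' @param cell_radius_px Range of cell radii in pixels (default 6..9).
#' @param nucleus_radius_px Range of nuclear radii (default 2..4; must stay
#'   below the cell radius).
#' @param dye_factor_sd Lognormal sigma of the per-cell loading factor
#'   `L_c` (default 0.2).
#' @param baseline_intensity Baseline cell intensity `B` in fluorescence
#'   units (default 1000).
#' @param background_offset Additive background `b` (default 200).
#' @param read_noise_sd Gaussian read-noise sigma (default 5).
#' @param shot_noise Replace each noise-free pixel value by a Poisson draw
#'   with that mean before adding read noise (default FALSE).
#' @param n_frames Frames per movie (default 25).
#' @param frame_interval_s Seconds between frames (default 5).
#' @param spike_schedule Tibble/data.frame with columns
#'   `cell, peak_frame` (0-based)`, amplitude, decay_frames`; default none.
#' @param seed Integer seed; the whole movie is deterministic given it.
#' @return A `synth_params` list.
#' @export
synth_params <- function(image_size = c(256L, 256L),
                         n_cells = 20L,
                         cell_radius_px = c(6, 9),
                         nucleus_radius_px = c(2, 4),
                         dye_factor_sd = 0.2,
                         baseline_intensity = 1000,
                         background_offset = 200,
                         read_noise_sd = 5,
                         shot_noise = FALSE,
                         n_frames = 25L,
                         frame_interval_s = 5,
                         spike_schedule = NULL,
                         seed = 1L) {
  if (length(image_size) != 2L || any(image_size < 16L)) {
    abort("`image_size` must be (H, W) with both >= 16.")
  }
  if (n_cells < 1L) abort("`n_cells` must be >= 1.")
  if (max(nucleus_radius_px) >= min(cell_radius_px)) {
    abort("nuclear radii must be smaller than the smallest cell radius.")
  }
  if (n_frames < 1L) abort("`n_frames` must be >= 1.")
  if (read_noise_sd < 0) abort("`read_noise_sd` must be >= 0.")
  if (is.null(spike_schedule)) {
    spike_schedule <- tibble(cell = integer(0), peak_frame = integer(0),
                             amplitude = numeric(0), decay_frames = integer(0))
  }
  spike_schedule <- as_tibble(spike_schedule)
  stopifnot(all(c("cell", "peak_frame", "amplitude", "decay_frames") %in%
                  names(spike_schedule)))
  if (nrow(spike_schedule)) {
    if (any(spike_schedule$amplitude <= 0)) abort("spike amplitudes must be > 0.")
    if (any(spike_schedule$peak_frame < 0L |
            spike_schedule$peak_frame >= n_frames)) {
      abort("scheduled peak frames must lie within 0..n_frames-1.")
    }
    if (any(spike_schedule$cell < 1L | spike_schedule$cell > n_cells)) {
      abort("scheduled cells must lie within 1..n_cells.")
    }
  }
  structure(
    list(image_size = as.integer(image_size), n_cells = as.integer(n_cells),
         cell_radius_px = as.numeric(cell_radius_px),
         nucleus_radius_px = as.numeric(nucleus_radius_px),
         dye_factor_sd = as.numeric(dye_factor_sd),
         baseline_intensity = as.numeric(baseline_intensity),
         background_offset = as.numeric(background_offset),
         read_noise_sd = as.numeric(read_noise_sd),
         shot_noise = isTRUE(shot_noise),
         n_frames = as.integer(n_frames),
         frame_interval_s = as.numeric(frame_interval_s),
         spike_schedule = spike_schedule,
         seed = as.integer(seed)),
    class = "synth_params"
  )
}

# spike kernel over frames 1..Tn for one scheduled spike (0-based peak)
spike_kernel <- function(Tn, peak_frame, decay_frames) {
  g <- numeric(Tn)
  p1 <- peak_frame + 1L
  g[p1] <- 1
  if (decay_frames > 0L) {
    j <- seq_len(decay_frames)
    keep <- p1 + j <= Tn
    g[p1 + j[keep]] <- exp(-3 * j[keep] / decay_frames)
  }
  g
}

#' Generate a synthetic calcium movie with full ground truth
#'
#' Cells are placed by rejection sampling with a safety margin so no two
#' disks touch; placement failure after bounded retries raises an error
#' suggesting fewer or smaller cells. The returned ground truth carries the
#' exact rendered mask, per-cell loading factors, the noise-free mean trace
#' of every cell, and the realized spike schedule, so segmentation,
#' measurement, background subtraction, normalization and spike detection
#' can each be checked against truth.
#'
#' @param params A [synth_params()].
#' @return A list: `stack` ([frame_stack()], cell channel), `nuclear`
#'   (`H x W` matrix), `truth` (a `synth_truth`: `mask` ([label_mask()]),
#'   `cells` tibble (`cell, row, col, radius, nucleus_radius, dye_factor`),
#'   `traces` (`n_cells x T` noise-free mean intensities, background
#'   included), `schedule`, `background_offset`, `params`).
#' @export
generate_movie <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  H <- params$image_size[1]; W <- params$image_size[2]
  nc <- params$n_cells; Tn <- params$n_frames
  withr::with_seed(params$seed, {
    radii <- runif(nc, params$cell_radius_px[1], params$cell_radius_px[2])
    nradii <- runif(nc, params$nucleus_radius_px[1], params$nucleus_radius_px[2])
    margin <- max(radii) + 4
    rows <- numeric(nc); cols <- numeric(nc)
    for (i in seq_len(nc)) {
      ok <- FALSE
      for (try in seq_len(500L)) {
        r0 <- runif(1, margin + 1, H - margin)
        c0 <- runif(1, margin + 1, W - margin)
        if (i == 1L ||
            all(sqrt((rows[seq_len(i - 1)] - r0)^2 +
                     (cols[seq_len(i - 1)] - c0)^2) >=
                radii[seq_len(i - 1)] + radii[i] + 6)) {
          rows[i] <- r0; cols[i] <- c0; ok <- TRUE; break
        }
      }
      if (!ok) {
        abort(paste("placement infeasible: could not fit all cells;",
                    "reduce n_cells or cell_radius_px."))
      }
    }
    L <- exp(rnorm(nc, 0, params$dye_factor_sd))

    rr <- matrix(seq_len(H), H, W)
    cm <- matrix(seq_len(W), H, W, byrow = TRUE)
    lab <- matrix(0L, H, W)
    nuc <- matrix(100, H, W)
    for (i in seq_len(nc)) {
      disk <- (rr - rows[i])^2 + (cm - cols[i])^2 <= radii[i]^2
      lab[disk] <- i
      nuc[(rr - rows[i])^2 + (cm - cols[i])^2 <= nradii[i]^2] <- 1000
    }
    mask <- label_mask(lab)

    # noise-free per-cell mean traces (uniform disks: mean = pixel value)
    g <- matrix(0, nc, Tn)
    sch <- params$spike_schedule
    if (nrow(sch)) {
      for (s in seq_len(nrow(sch))) {
        k <- spike_kernel(Tn, sch$peak_frame[s], sch$decay_frames[s])
        g[sch$cell[s], ] <- pmax(g[sch$cell[s], ], sch$amplitude[s] * k)
      }
    }
    traces <- L * params$baseline_intensity * (1 + g) + params$background_offset

    frames <- array(params$background_offset, c(H, W, Tn))
    cellpix <- which(lab > 0L)
    for (t in seq_len(Tn)) {
      img <- frames[, , t]
      img[cellpix] <- traces[lab[cellpix], t]
      if (params$shot_noise) {
        img[] <- rpois(length(img), lambda = img)
      }
      if (params$read_noise_sd > 0) {
        img <- img + rnorm(length(img), 0, params$read_noise_sd)
      }
      frames[, , t] <- pmax(img, 0)
    }
  })
  truth <- structure(
    list(mask = mask,
         cells = tibble(cell = seq_len(nc), row = rows - 1, col = cols - 1,
                        radius = radii, nucleus_radius = nradii,
                        dye_factor = L),
         traces = traces,
         schedule = params$spike_schedule,
         background_offset = params$background_offset,
         params = params),
    class = "synth_truth"
  )
  list(stack = frame_stack(frames, params$frame_interval_s),
       nuclear = nuc, truth = truth)
}

#' Match segmented labels to ground-truth cells by overlap
#'
#' Each segmented label is paired with the true cell it overlaps most, and
#' the pair's intersection-over-union is reported.
#'
#' @param mask Segmented [label_mask()].
#' @param true_mask Ground-truth [label_mask()] of the same size.
#' @return A tibble `track_id, true_cell, iou`, one row per segmented label
#'   (`true_cell` NA when a label overlaps no true cell).
#' @export
match_labels <- function(mask, true_mask) {
  stopifnot(inherits(mask, "label_mask"), inherits(true_mask, "label_mask"))
  a <- as.vector(unclass_mask(mask))
  b <- as.vector(unclass_mask(true_mask))
  if (length(a) != length(b)) abort("masks differ in size.")
  na <- n_cells(mask)
  area_a <- tabulate(a[a > 0L], nbins = max(na, 1L))
  area_b <- tabulate(b[b > 0L], nbins = max(n_cells(true_mask), 1L))
  out <- tibble(track_id = seq_len(na), true_cell = NA_integer_, iou = 0)
  both <- a > 0L & b > 0L
  if (any(both)) {
    ov <- tapply(rep(1L, sum(both)), list(a[both], b[both]), sum)
    for (i in seq_len(na)) {
      key <- as.character(i)
      if (!key %in% rownames(ov)) next
      row <- ov[key, ]
      j <- which.max(row)
      inter <- row[j]
      if (is.na(inter) || inter == 0) next
      tb <- as.integer(colnames(ov)[j])
      out$true_cell[i] <- tb
      out$iou[i] <- inter / (area_a[i] + area_b[tb] - inter)
    }
  }
  out
}

#' Graded benchmark suite of synthetic movies
#'
#' A fixed grid of movies crossing spike amplitudes
#' `{5, 10, 15, 20, 50}%` with read-noise levels `{0, 1, 2}%` of the
#' baseline intensity -- bracketing the 10% spike threshold from both
#' sides -- each with `n_cells` cells and one scheduled spike per cell at a
#' random mid-movie frame. Deterministic given `seed`.
#'
#' @param seed Integer seed.
#' @param amplitudes Spike amplitudes as fractions (default
#'   `c(.05, .10, .15, .20, .50)`).
#' @param noise_pcts Read-noise sigmas as percent of baseline (default
#'   `c(0, 1, 2)`).
#' @param n_cells Cells per movie (default 20).
#' @return A list of 15 entries, each
#'   `list(stack, nuclear, truth, amplitude, noise_pct)`.
#' @export
benchmark_suite <- function(seed = 1L,
                            amplitudes = c(0.05, 0.10, 0.15, 0.20, 0.50),
                            noise_pcts = c(0, 1, 2),
                            n_cells = 20L) {
  grid <- expand.grid(amplitude = amplitudes, noise_pct = noise_pcts,
                      KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(grid))
  B <- 1000
  for (i in seq_len(nrow(grid))) {
    sub_seed <- (as.integer(seed) %% 100000L) * 1000L + i
    sched <- withr::with_seed(sub_seed + 500L, tibble(
      cell = seq_len(n_cells),
      peak_frame = sample(8:18, n_cells, replace = TRUE),
      amplitude = grid$amplitude[i],
      decay_frames = 3L
    ))
    p <- synth_params(
      n_cells = n_cells,
      baseline_intensity = B,
      read_noise_sd = grid$noise_pct[i] / 100 * B,
      spike_schedule = sched,
      seed = sub_seed
    )
    mv <- generate_movie(p)
    out[[i]] <- c(mv, list(amplitude = grid$amplitude[i],
                           noise_pct = grid$noise_pct[i]))
  }
  out
}
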