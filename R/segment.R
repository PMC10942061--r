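#' Label mask
#'
#' An `H x W` integer image assigning every pixel to background (0) or to
#' one cell (1..n). Labels are required to be consecutive; use
#' [sanitize_mask()] to bring arbitrary labelled output into this form.
#'
#' @param labels Integer matrix of non-negative labels.
#' @return A `label_mask` (integer matrix with attribute `n_cells`).
#' @export
label_mask <- function(labels) {
  if (!is.matrix(labels)) abort("`labels` must be an H x W matrix.")
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 0L)) abort("labels must be >= 0.")
  u <- sort(unique(as.vector(labels)))
  n <- max(labels, 0L)
  if (n > 0L && !identical(setdiff(u, 0L), seq_len(n))) {
    abort("labels must be consecutive 1..n (use sanitize_mask()).")
  }
  structure(labels, class = "label_mask", n_cells = as.integer(n))
}

#' Number of cells in a mask
#' @param mask A [label_mask()].
#' @return Integer cell count.
#' @export
n_cells <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  attr(mask, "n_cells")
}

unclass_mask <- function(mask) {
  m <- unclass(mask)
  attr(m, "n_cells") <- NULL
  m
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d px, %d cell(s)\n",
              nrow(x), ncol(x), attr(x, "n_cells")))
  invisible(x)
}

# 8-connectivity connected-component labelling, row-major first-pixel order.
# Two-pass union-find over foreground pixels only.
label_components8 <- function(fg) {
  stopifnot(is.matrix(fg))
  H <- nrow(fg); W <- ncol(fg)
  lab <- matrix(0L, H, W)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nxt <- 0L
  for (r in seq_len(H)) {
    for (cc in seq_len(W)) {
      if (!fg[r, cc]) next
      # previously visited neighbours in row-major scan order
      nb <- integer(0)
      if (r > 1L) {
        if (cc > 1L && lab[r - 1L, cc - 1L] > 0L) nb <- c(nb, lab[r - 1L, cc - 1L])
        if (lab[r - 1L, cc] > 0L) nb <- c(nb, lab[r - 1L, cc])
        if (cc < W && lab[r - 1L, cc + 1L] > 0L) nb <- c(nb, lab[r - 1L, cc + 1L])
      }
      if (cc > 1L && lab[r, cc - 1L] > 0L) nb <- c(nb, lab[r, cc - 1L])
      if (length(nb) == 0L) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[r, cc] <- nxt
      } else {
        roots <- unique(vapply(nb, find, integer(1)))
        keep <- min(roots)
        lab[r, cc] <- keep
        for (rt in roots) parent[rt] <- keep
      }
    }
  }
  if (nxt == 0L) return(lab)
  # resolve equivalences, then relabel by first pixel in row-major order
  roots <- vapply(seq_len(nxt), find, integer(1))
  labv <- as.vector(t(lab))            # row-major traversal
  pos <- labv > 0L
  labv[pos] <- roots[labv[pos]]
  first <- !duplicated(labv[pos])
  newid <- integer(nxt)
  newid[labv[pos][first]] <- seq_len(sum(first))
  labv[pos] <- newid[labv[pos]]
  matrix(labv, H, W, byrow = TRUE)
}

# drop objects below min area, then relabel consecutively in row-major
# first-pixel order
sanitize_labels <- function(lab, min_cell_area_px) {
  storage.mode(lab) <- "integer"
  if (max(lab) > 0L && min_cell_area_px > 1L) {
    areas <- tabulate(lab[lab > 0L], nbins = max(lab))
    small <- which(areas < min_cell_area_px & areas > 0L)
    if (length(small)) lab[lab %in% small] <- 0L
  }
  labv <- as.vector(t(lab))
  pos <- labv > 0L
  if (any(pos)) {
    old <- labv[pos]
    first <- old[!duplicated(old)]
    newid <- integer(max(old))
    newid[first] <- seq_along(first)
    labv[pos] <- newid[old]
  }
  label_mask(matrix(labv, nrow(lab), ncol(lab), byrow = TRUE))
}

#' Sanitize an arbitrary labelled image into a valid mask
#'
#' Removes objects smaller than `min_cell_area_px` and relabels the rest
#' consecutively (1..n) in row-major first-encountered-pixel order, the
#' package's deterministic tie-break.
#'
#' @param labels Integer matrix with arbitrary non-negative labels.
#' @param min_cell_area_px Minimum object area kept (default 1 = keep all).
#' @return A [label_mask()].
#' @export
sanitize_mask <- function(labels, min_cell_area_px = 1L) {
  if (!is.matrix(labels)) abort("`labels` must be a matrix.")
  if (anyNA(labels) || any(labels < 0)) abort("labels must be >= 0.")
  sanitize_labels(labels, as.integer(min_cell_area_px))
}

#' Built-in deterministic segmentation of a composite image
#'
#' A dependency-light segmenter for bright cells on a dark background:
#' Gaussian smoothing, a global Otsu threshold, then either 8-connectivity
#' component labelling or -- when a nuclear channel is present and
#' `use_nuclear_seeds` is on -- nuclear-seeded region growing that splits
#' touching cells. Because dye loading varies, a single global threshold
#' sits above the half-maximum edge of dimly loaded cells and erodes them;
#' an optional refinement pass therefore re-thresholds a padded window
#' around each detected object with a local Otsu cut, growing the object
#' out to its own half-maximum boundary. Refinement only ever claims pixels
#' that were background after the global pass, so seeded splits between
#' touching cells are preserved. Objects below `min_cell_area_px` are
#' discarded and labels are made consecutive in row-major first-pixel
#' order, so identical inputs always give identical masks.
#'
#' @param composite A `composite_image` from [max_composite()] /
#'   [merge_channels()].
#' @param smooth_sigma Gaussian sigma in pixels (default 2).
#' @param min_cell_area_px Minimum cell area in pixels (default 50).
#' @param use_nuclear_seeds Use the nuclear channel (if present) to seed the
#'   splitting of touching cells (default TRUE).
#' @param refine_boundary Apply the per-object local-threshold refinement
#'   (default TRUE).
#' @return A [label_mask()].
#' @export
segment_fallback <- function(composite,
                             smooth_sigma = 2.0,
                             min_cell_area_px = 50L,
                             use_nuclear_seeds = TRUE,
                             refine_boundary = TRUE) {
  stopifnot(inherits(composite, "composite_image"))
  if (smooth_sigma < 0) abort("`smooth_sigma` must be >= 0.")
  cell <- composite$cell
  rng <- range(cell)
  if (rng[1] == rng[2]) {
    abort("no foreground: composite image is constant, cannot threshold.")
  }
  blur <- function(x) {
    if (smooth_sigma > 0) {
      EBImage::imageData(EBImage::gblur(EBImage::Image(x), smooth_sigma))
    } else {
      x
    }
  }
  # detect in log intensity: with cell-to-cell dye variation spanning an
  # order of magnitude, a linear global threshold can sit above the dimmest
  # cells entirely; log compression keeps one cut below every cell plateau
  sml <- blur(log1p(cell))
  smln <- (sml - min(sml)) / (max(sml) - min(sml))
  fg <- smln > EBImage::otsu(EBImage::Image(smln), range = c(0, 1))
  if (!any(fg)) abort("no foreground: Otsu threshold left an empty image.")
  # linear smoothed image, for seeded splitting and boundary refinement
  sm <- blur(cell)
  smn <- (sm - min(sm)) / (max(sm) - min(sm))

  if (isTRUE(use_nuclear_seeds) && !is.null(composite$nuclear)) {
    nuc <- composite$nuclear
    nrng <- range(nuc)
    if (nrng[1] == nrng[2]) abort("nuclear channel is constant; cannot seed.")
    nn <- (nuc - nrng[1]) / (nrng[2] - nrng[1])
    nthr <- EBImage::otsu(EBImage::Image(nn), range = c(0, 1))
    seeds <- label_components8(nn > nthr)
    if (max(seeds) == 0L) abort("no nuclear seeds found above threshold.")
    lab <- EBImage::imageData(EBImage::propagate(
      EBImage::Image(1 - smn), EBImage::Image(seeds), mask = EBImage::Image(fg)
    ))
    lab <- matrix(as.integer(round(lab)), nrow(cell), ncol(cell))
  } else {
    lab <- label_components8(fg)
  }
  if (isTRUE(refine_boundary) && max(lab) > 0L) {
    # boundary placement needs less smoothing than detection: heavy blur
    # pulls the half-maximum of small convex objects inward by ~sigma^2/2r
    sig_r <- min(1, smooth_sigma)
    smr <- if (sig_r > 0) {
      EBImage::imageData(EBImage::gblur(EBImage::Image(cell), sig_r))
    } else {
      cell
    }
    smrn <- (smr - min(smr)) / (max(smr) - min(smr))
    lab <- refine_labels_local(lab, smrn, pad = ceiling(3 * smooth_sigma) + 4L)
  }
  sanitize_labels(lab, as.integer(min_cell_area_px))
}

# Re-cut each labelled object at its own half-maximum boundary. The
# object's plateau is the maximum of the smoothed image over its pixels and
# the background level is the median of the smoothed image outside all
# objects; the half-maximum cut between the two is applied in a padded
# bounding box and the connected component(s) containing the object become
# its refined pixel set. Pixels belonging to *other* objects of the initial
# labelling are never claimed, so boundaries between touching objects
# (e.g. from seeded splitting) are preserved.
refine_labels_local <- function(lab, smn, pad = 10L) {
  H <- nrow(lab); W <- ncol(lab)
  out <- matrix(0L, H, W)
  bg_level <- stats::median(smn[lab == 0L])
  for (i in seq_len(max(lab))) {
    px <- which(lab == i, arr.ind = TRUE)
    if (nrow(px) == 0L) next
    r0 <- max(1L, min(px[, 1]) - pad); r1 <- min(H, max(px[, 1]) + pad)
    c0 <- max(1L, min(px[, 2]) - pad); c1 <- min(W, max(px[, 2]) + pad)
    plateau <- max(smn[cbind(px[, 1], px[, 2])])
    thr <- bg_level + 0.5 * (plateau - bg_level)
    sub <- smn[r0:r1, c0:c1]
    ll <- label_components8(sub >= thr)
    seedlab <- unique(ll[cbind(px[, 1] - r0 + 1L, px[, 2] - c0 + 1L)])
    seedlab <- seedlab[seedlab > 0L]
    if (thr <= bg_level || length(seedlab) == 0L) {
      # degenerate cut: keep the object as initially labelled
      tgt <- out[r0:r1, c0:c1]
      src <- lab[r0:r1, c0:c1]
      tgt[src == i & tgt == 0L] <- i
      out[r0:r1, c0:c1] <- tgt
      next
    }
    tgt <- out[r0:r1, c0:c1]
    src <- lab[r0:r1, c0:c1]
    claim <- matrix(FALSE, nrow(sub), ncol(sub))
    claim[ll %in% seedlab] <- TRUE
    claim <- claim & (src == 0L | src == i) & tgt == 0L
    tgt[claim] <- i
    out[r0:r1, c0:c1] <- tgt
  }
  out
}

#' Segment through an external backend adapter
#'
#' Wraps a user-supplied segmentation backend (for example a generalist
#' deep-learning model such as Cellpose, called through reticulate or a
#' shell wrapper). The backend receives the cell channel and, if present,
#' the nuclear channel, and must return an `H x W` matrix of non-negative
#' integer labels. Its output is sanitized with [sanitize_mask()] so
#' downstream code sees the same contract as the built-in segmenter.
#'
#' @param composite A `composite_image`.
#' @param backend A function `(cell, nuclear) -> H x W integer matrix`, or
#'   `NULL` if no backend is configured.
#' @param min_cell_area_px Minimum cell area kept (default 50).
#' @return A [label_mask()].
#' @export
segment_external <- function(composite, backend, min_cell_area_px = 50L) {
  stopifnot(inherits(composite, "composite_image"))
  if (is.null(backend) || !is.function(backend)) {
    abort(paste(
      "no segmentation backend configured: pass a function",
      "`(cell, nuclear) -> label matrix` (e.g. a Cellpose wrapper), or use",
      "segment_fallback()."
    ))
  }
  out <- backend(composite$cell, composite$nuclear)
  if (!is.matrix(out) || !identical(dim(out), dim(composite$cell))) {
    abort(sprintf(
      "adapter contract violated: backend returned %s, expected a %s matrix",
      paste(dim(out), collapse = "x"),
      paste(dim(composite$cell), collapse = "x")
    ))
  }
  if (anyNA(out) || any(out < 0) || any(out != round(out))) {
    abort("adapter contract violated: labels must be non-negative integers.")
  }
  sanitize_mask(out, min_cell_area_px)
}
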