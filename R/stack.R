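#' Frame stack: a grayscale time-lapse movie
#'
#' A `frame_stack` holds a `H x W x T` array of non-negative fluorescence
#' intensities together with the acquisition interval between frames.
#' Rows index image y (top to bottom), columns image x, and the third
#' dimension indexes time.
#'
#' @param frames Numeric `H x W x T` array (a plain `H x W` matrix is
#'   promoted to a single-frame stack). All values must be finite and >= 0.
#' @param frame_interval_s Seconds between consecutive frames (default 5,
#'   a typical low-phototoxicity calcium imaging cadence).
#' @return An object of class `frame_stack`.
#' @examples
#' fs <- frame_stack(array(1:24, c(2, 3, 4)))
#' n_frames(fs)
#' @export
frame_stack <- function(frames, frame_interval_s = 5) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    abort("`frames` must be an H x W x T array (or an H x W matrix).")
  }
  if (any(dim(frames) < 1L)) abort("all dimensions of `frames` must be >= 1.")
  if (!is.numeric(frames) || anyNA(frames) || any(!is.finite(frames))) {
    abort("`frames` must be finite and numeric.")
  }
  if (any(frames < 0)) abort("fluorescence intensities must be non-negative.")
  if (!is.numeric(frame_interval_s) || length(frame_interval_s) != 1L ||
      frame_interval_s <= 0) {
    abort("`frame_interval_s` must be a single positive number.")
  }
  structure(
    list(frames = frames, frame_interval_s = as.numeric(frame_interval_s)),
    class = "frame_stack"
  )
}

#' Number of frames in a stack
#' @param stack A [frame_stack()].
#' @return Integer frame count `T`.
#' @export
n_frames <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  dim(stack$frames)[3L]
}

#' Imaging duration of a stack in minutes
#'
#' Duration spans the intervals between frames, `(T - 1) * dt / 60`, so a
#' 25-frame stack at 5 s intervals covers 2 minutes.
#'
#' @param stack A [frame_stack()].
#' @return Duration in minutes.
#' @export
stack_duration_min <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  (n_frames(stack) - 1L) * stack$frame_interval_s / 60
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<frame_stack> %d x %d px, %d frame(s) at %gs (%.2g min), range [%g, %g]\n",
    d[1], d[2], d[3], x$frame_interval_s,
    (d[3] - 1) * x$frame_interval_s / 60,
    min(x$frames), max(x$frames)
  ))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$frames)
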