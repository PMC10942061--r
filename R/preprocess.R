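#' Maximum-value composite of a time-lapse stack
#'
#' Collapses a stack to a single image in which every pixel carries its
#' brightest value across all frames. Because calcium signalling
#' oscillates, any one frame can miss cells that happen to be dark; the
#' composite guarantees every dye-loaded cell is fully fluorescing
#' somewhere in the image handed to segmentation.
#'
#' @param stack A [frame_stack()].
#' @return A `composite_image` with the cell channel only.
#' @examples
#' fs <- frame_stack(array(c(1, 3, 2, 0, 0, 1, 5, 4), c(2, 2, 2)))
#' max_composite(fs)$cell
#' @export
max_composite <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  cell <- apply(stack$frames, c(1, 2), max)
  composite_image(cell)
}

#' Two-channel composite for segmentation
#'
#' Pairs the cell-channel composite with a nuclear-stain image (e.g. DAPI /
#' NucBlue, taken as a single user-supplied frame). Neither channel is
#' modified; the nuclear channel is used only to seed the splitting of
#' touching cells.
#'
#' @param cell_img `H x W` cell-channel image (matrix or `composite_image`).
#' @param nuclear_img `H x W` nuclear-channel image, same size.
#' @return A `composite_image` with both channels.
#' @export
merge_channels <- function(cell_img, nuclear_img) {
  if (inherits(cell_img, "composite_image")) cell_img <- cell_img$cell
  if (!is.matrix(cell_img) || !is.matrix(nuclear_img)) {
    abort("both channels must be H x W matrices.")
  }
  if (!identical(dim(cell_img), dim(nuclear_img))) {
    abort(sprintf(
      "channel dimensions differ: cell %s vs nuclear %s",
      paste(dim(cell_img), collapse = "x"),
      paste(dim(nuclear_img), collapse = "x")
    ))
  }
  composite_image(cell_img, nuclear_img)
}

composite_image <- function(cell, nuclear = NULL) {
  stopifnot(is.matrix(cell))
  structure(list(cell = cell, nuclear = nuclear), class = "composite_image")
}

#' @export
print.composite_image <- function(x, ...) {
  cat(sprintf("<composite_image> %d x %d px, %s nuclear channel\n",
              nrow(x$cell), ncol(x$cell),
              if (is.null(x$nuclear)) "no" else "with"))
  invisible(x)
}
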