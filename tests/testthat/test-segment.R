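make_disk_image <- function(H, W, centers, radii, values) {
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  img <- matrix(0, H, W)
  for (i in seq_along(radii)) {
    d <- (rr - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= radii[i]^2
    img[d] <- pmax(img[d], values[i])
  }
  img
}

test_that("two separated bright disks yield two cells", {
  img <- make_disk_image(64, 64, rbind(c(20, 20), c(20, 48)), c(8, 8),
                         c(1000, 1000))
  m <- segment_fallback(max_composite(frame_stack(img)))
  expect_equal(n_cells(m), 2L)
})

test_that("constant composite raises a no-foreground error", {
  comp <- max_composite(frame_stack(array(0, c(16, 16, 2))))
  expect_error(segment_fallback(comp), "no foreground")
})

test_that("overlapping disks split into two cells via nuclear seeds", {
  H <- 64
  rr <- matrix(seq_len(H), H, H); cc <- t(rr)
  d1 <- (rr - 32)^2 + (cc - 24)^2 <= 100
  d2 <- (rr - 32)^2 + (cc - 40)^2 <= 100
  cell <- matrix(0, H, H); cell[d1] <- 900; cell[d2] <- pmax(cell[d2], 1000)
  nuc <- matrix(0, H, H)
  nuc[(rr - 32)^2 + (cc - 24)^2 <= 9] <- 500
  nuc[(rr - 32)^2 + (cc - 40)^2 <= 9] <- 500
  m <- segment_fallback(merge_channels(cell, nuc), min_cell_area_px = 20)
  expect_equal(n_cells(m), 2L)
  for (i in 1:2) {
    a <- unclass(m) == i
    iou <- max(sum(a & d1) / sum(a | d1), sum(a & d2) / sum(a | d2))
    expect_gte(iou, 0.8)
  }
})

test_that("noiseless non-overlapping disks are recovered exactly in count with IoU >= 0.9", {
  for (seed in 1:3) {
    mv <- tiny_movie(seed = seed, n_cells = 8L)
    m <- segment_fallback(max_composite(mv$stack))
    expect_equal(n_cells(m), n_cells(mv$truth$mask))
    mm <- match_labels(m, mv$truth$mask)
    expect_true(all(mm$iou >= 0.9))
  }
})

test_that("segmentation is deterministic", {
  mv <- tiny_movie(seed = 5, n_cells = 6L)
  comp <- merge_channels(max_composite(mv$stack), mv$nuclear)
  m1 <- segment_fallback(comp)
  m2 <- segment_fallback(comp)
  expect_identical(unclass(m1), unclass(m2))
})

test_that("external backend output is sanitized into consecutive labels", {
  comp <- merge_channels(matrix(runif(64), 8, 8), matrix(runif(64), 8, 8))
  stub <- function(cell, nuclear) {
    out <- matrix(0L, 8, 8)
    out[1:2, 1:2] <- 3L
    out[5:6, 5:6] <- 7L
    out
  }
  m <- segment_external(comp, stub, min_cell_area_px = 1L)
  expect_equal(sort(unique(as.vector(unclass(m)))), 0:2)
  expect_equal(n_cells(m), 2L)
})

test_that("external backend objects below the area floor are dropped", {
  comp <- merge_channels(matrix(runif(400), 20, 20), matrix(runif(400), 20, 20))
  stub <- function(cell, nuclear) {
    out <- matrix(0L, 20, 20)
    out[1:2, 1:5] <- 1L  # 10 px
    out
  }
  m <- segment_external(comp, stub, min_cell_area_px = 50L)
  expect_equal(n_cells(m), 0L)
})

test_that("backend contract violations and missing backends are reported", {
  comp <- merge_channels(matrix(runif(64), 8, 8), matrix(runif(64), 8, 8))
  bad_shape <- function(cell, nuclear) matrix(0L, 8, 9)
  expect_error(segment_external(comp, bad_shape), "adapter contract")
  expect_error(segment_external(comp, NULL), "backend")
})

test_that("permuting backend label values leaves the pixel regions unchanged", {
  withr::local_seed(31)
  base <- matrix(0L, 16, 16)
  base[2:5, 2:5] <- 1L; base[8:12, 8:12] <- 2L; base[2:5, 10:14] <- 3L
  comp <- merge_channels(matrix(runif(256), 16, 16), matrix(runif(256), 16, 16))
  perm <- c(5L, 9L, 2L)
  permuted <- base
  permuted[base > 0L] <- perm[base[base > 0L]]
  m1 <- segment_external(comp, function(...) base, min_cell_area_px = 1L)
  m2 <- segment_external(comp, function(...) permuted, min_cell_area_px = 1L)
  regions <- function(m) {
    lapply(seq_len(n_cells(m)), function(i) which(unclass(m) == i))
  }
  expect_setequal(
    vapply(regions(m1), paste, character(1), collapse = ","),
    vapply(regions(m2), paste, character(1), collapse = ",")
  )
})

test_that("8-connectivity labelling joins diagonal pixels and orders labels row-major", {
  fg <- matrix(FALSE, 8, 8)
  fg[2:3, 2:3] <- TRUE
  fg[4:5, 4:5] <- TRUE   # touches the first block only diagonally
  fg[7, 7] <- TRUE
  lab <- calcitrack:::label_components8(fg)
  expect_equal(max(lab), 2L)
  expect_equal(lab[2, 2], 1L)  # first-encountered (row-major) gets label 1
  expect_equal(lab[5, 5], 1L)  # diagonally connected
  expect_equal(lab[7, 7], 2L)
})
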