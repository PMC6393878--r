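test_that("connectivity semantics: diagonal pixels merge only under 8", {
  m <- matrix(FALSE, 4, 4)
  m[2, 2] <- m[3, 3] <- TRUE
  expect_equal(length(label_connected(m, 8L)$sizes), 1L)
  expect_equal(length(label_connected(m, 4L)$sizes), 2L)
  expect_equal(length(label_connected(matrix(FALSE, 3, 3), 8L)$sizes), 0L)
})

test_that("label_connected matches the flood-fill oracle on random masks", {
  set.seed(8)
  for (conn in c(4L, 8L)) for (trial in 1:10) {
    m <- matrix(runif(400) < 0.45, 20, 20)
    got <- label_connected(m, conn)
    want <- flood_label(m, conn)
    expect_true(same_partition(got$labels, want))
    expect_equal(sort(got$sizes), sort(as.vector(table(want[want > 0]))))
    # labels numbered by raster-scan first encounter
    first_rows <- vapply(seq_along(got$sizes), function(l) {
      idx <- which(got$labels == l, arr.ind = TRUE)
      min(idx[, 1] * 1000 + idx[, 2])
    }, numeric(1))
    first_raster <- vapply(seq_along(got$sizes), function(l) {
      idx <- which(got$labels == l, arr.ind = TRUE)
      min((idx[, 1] - 1) * 20 + idx[, 2])
    }, numeric(1))
    expect_equal(order(first_raster), seq_along(got$sizes))
  }
})

test_that("largest_component selects the maximum with raster tie-breaks", {
  m <- matrix(FALSE, 8, 8)
  m[1:5, 1] <- TRUE    # size 5
  m[1:3, 4] <- TRUE    # size 3
  expect_equal(sum(largest_component(label_connected(m, 8L))), 5L)
  # equal sizes: earlier raster label wins
  m2 <- matrix(FALSE, 8, 8)
  m2[2, 2:4] <- TRUE
  m2[5, 2:4] <- TRUE
  lc <- largest_component(label_connected(m2, 8L))
  expect_true(all(lc[2, 2:4]))
  expect_false(any(lc[5, ]))
  expect_error(largest_component(label_connected(matrix(FALSE, 4, 4), 8L)),
               class = "neuroseg_empty_region_error")
})

test_that("apply_mask keeps original intensities exactly on the support", {
  p <- matrix(runif(256), 16, 16)
  expect_equal(apply_mask(p, matrix(TRUE, 16, 16)), p)
  expect_true(all(apply_mask(p, matrix(FALSE, 16, 16)) == 0))
  set.seed(9)
  mk <- matrix(runif(256) > 0.5, 16, 16)
  out <- apply_mask(p, mk)
  expect_identical(out != 0, mk)           # support equality (p > 0 a.s.)
  expect_equal(out[mk], p[mk])
  expect_error(apply_mask(p, matrix(TRUE, 8, 8)),
               class = "neuroseg_shape_error")
})

test_that("extract_boundary yields thin 4-adjacency contours", {
  sq <- matrix(FALSE, 5, 5); sq[2:4, 2:4] <- TRUE
  b <- extract_boundary(sq)
  expect_equal(length(b), 1L)
  expect_equal(nrow(b[[1]]), 8L)           # perimeter of 3x3, center excluded
  expect_false(any(b[[1]][, 1] == 3 & b[[1]][, 2] == 3))
  single <- matrix(FALSE, 4, 4); single[2, 2] <- TRUE
  expect_equal(extract_boundary(single)[[1]],
               matrix(c(2L, 2L), 1, 2, dimnames = list(NULL, c("row", "col"))))
  expect_equal(extract_boundary(matrix(FALSE, 4, 4)), list())
  # ellipse boundary length within 10% of the Ramanujan perimeter
  m <- make_ellipse_mask(64, 64, ellipse_params(32, 32, 20, 10))
  n <- sum(vapply(extract_boundary(m), nrow, integer(1)))
  per <- pi * (3 * 30 - sqrt(70 * 50))
  expect_lt(abs(n - per) / per, 0.1)
  # traversal order: successive pixels are 8-adjacent along the contour
  steps <- diff(extract_boundary(m)[[1]])
  expect_true(all(pmax(abs(steps[, 1]), abs(steps[, 2])) <= 2))
})

test_that("fill_holes closes enclosed background only", {
  ring <- make_ellipse_mask(40, 40, ellipse_params(20, 20, 15, 10)) &
    !make_ellipse_mask(40, 40, ellipse_params(20, 20, 10, 6))
  filled <- fill_holes(ring)
  expect_identical(filled, make_ellipse_mask(40, 40, ellipse_params(20, 20, 15, 10)))
  open_ <- matrix(FALSE, 10, 10); open_[1, ] <- TRUE
  expect_identical(fill_holes(open_), open_)
})

test_that("segment_gm_wm output satisfies its structural invariants", {
  ph <- small_phantom(0.05, 0)
  res <- cached("seg_small_0.05_0", segment_gm_wm(ph$slice))
  expect_false(any(res$gm_mask & res$wm_mask))
  expect_equal(length(label_connected(res$gm_mask, 8L)$sizes), 1L)
  expect_equal(length(label_connected(res$wm_mask, 8L)$sizes), 1L)
  # region images are the original intensities exactly on the mask, 0 off it
  expect_equal(res$gm_region$pixels[res$gm_mask],
               ph$slice$pixels[res$gm_mask])
  expect_true(all(res$gm_region$pixels[!res$gm_mask] == 0))
  expect_gt(dice(res$gm_mask, ph$truth$gm_mask), 0.95)
  expect_gt(dice(res$wm_mask, ph$truth$wm_mask), 0.95)
})

test_that("pipeline is deterministic and affine-intensity invariant", {
  ph <- small_phantom(0.05, 0)
  res <- cached("seg_small_0.05_0", segment_gm_wm(ph$slice))
  res2 <- segment_gm_wm(ph$slice)
  expect_identical(res$gm_mask, res2$gm_mask)
  expect_identical(res$wm_mask, res2$wm_mask)
  # global affine rescale of the input changes nothing (normalization first)
  rescaled <- grayscale_slice(ph$slice$pixels * 537 + 41, "PHANTOM")
  res3 <- segment_gm_wm(rescaled)
  expect_identical(res$gm_mask, res3$gm_mask)
  expect_identical(res$wm_mask, res3$wm_mask)
})

test_that("tumor mode finds the blob and flags implausible results", {
  tu <- list(center_row = 120, center_col = 140, radius = 12)
  ph <- default_phantom(0.05, 0, tumor = tu)
  res <- cached("tumor_0.05_0", segment_tumor(ph$slice))
  expect_gte(dice(res$tumor_mask, ph$truth$tumor_mask), 0.9)
  expect_true(res$plausible)
  expect_equal(length(label_connected(res$tumor_mask, 8L)$sizes), 1L)
  # no tumor present: the white matter is caught instead and flagged
  ph0 <- default_phantom(0.05, 0)
  expect_warning(res0 <- segment_tumor(ph0$slice), "implausible")
  expect_false(res0$plausible)
  expect_gt(sum(res0$tumor_mask), 0.25 * sum(res0$brain_mask))
  # empty brain errors before clustering
  expect_error(segment_tumor(grayscale_slice(matrix(0, 64, 64))),
               class = "neuroseg_detection_error")
})

test_that("median_filter is a running median with reflective borders", {
  m <- matrix(as.numeric(1:25), 5, 5)
  f <- median_filter(m, 3L)
  expect_equal(f[3, 3], median(m[2:4, 2:4]))
  # salt noise removed
  s <- matrix(0.5, 9, 9); s[5, 5] <- 1
  expect_equal(median_filter(s, 3L)[5, 5], 0.5)
  expect_error(median_filter(m, 4L), "odd")
})
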