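#' Threshold a slice into foreground and background
#'
#' Foreground is the set of pixels strictly above the threshold level. With
#' `method = "otsu"` the level maximizing the between-class variance is
#' computed from a 256-bin histogram; with `method = "fixed"` the supplied
#' `level` is used directly.
#'
#' @param slice a [grayscale_slice] or numeric matrix (normalized input
#'   expected; the Otsu histogram is built over the observed range).
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param level threshold level, required for `method = "fixed"`.
#' @return Logical matrix with attribute `"level"` (the threshold used).
#' @export
threshold_slice <- function(slice, method = c("otsu", "fixed"), level = NULL) {
  method <- match.arg(method)
  p <- .as_pixels(slice)
  if (method == "fixed") {
    if (is.null(level)) stop("method = \"fixed\" requires a level")
  } else {
    level <- otsu_level(p)
  }
  structure(p > level, level = level)
}

#' Otsu's threshold level
#'
#' Exhaustive search over 256 histogram bin edges for the level maximizing
#' the between-class variance (equivalently minimizing within-class
#' variance). Ties take the lowest level; a constant image returns its value.
#'
#' @param x numeric vector or matrix of intensities.
#' @param nbins number of histogram bins.
#' @return Scalar threshold level.
#' @export
otsu_level <- function(x, nbins = 256L) {
  x <- as.vector(x)
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  counts <- tabulate(pmin(findInterval(x, br, all.inside = TRUE), nbins),
                     nbins = nbins)
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(counts)
  mu <- cumsum(counts * mids)
  n <- w[nbins]; mu_t <- mu[nbins]
  w0 <- w[-nbins]; mu0 <- mu[-nbins]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nbins - 1L)
  bcv[valid] <- (mu_t * w0[valid] - n * mu0[valid])^2 / (w0[valid] * w1[valid])
  br[-c(1L, nbins + 1L)][which.max(bcv)]
}

# Boundary pixels of a mask: foreground with at least one 4-neighbour
# background pixel; the image border counts as background.
.boundary_mask <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  up <- rbind(FALSE, mask[-nr, , drop = FALSE])
  down <- rbind(mask[-1, , drop = FALSE], FALSE)
  left <- cbind(FALSE, mask[, -nc, drop = FALSE])
  right <- cbind(mask[, -1, drop = FALSE], FALSE)
  mask & !(up & down & left & right)
}

#' Fill holes in a binary mask
#'
#' Background components (4-connectivity) that do not touch the image border
#' are interior holes and are set to foreground.
#'
#' @param mask logical matrix.
#' @return Logical matrix.
#' @export
fill_holes <- function(mask) {
  bg <- .ccl_label(!mask, 4L)
  border_labels <- unique(c(bg$labels[1, ], bg$labels[nrow(mask), ],
                            bg$labels[, 1], bg$labels[, ncol(mask)]))
  hole <- !mask & !(bg$labels %in% border_labels)
  mask | matrix(hole, nrow(mask), ncol(mask))
}

#' Detect the skull outline as the best-supported ellipse
#'
#' Votes are accumulated over an explicit (center, semi-axes, rotation) grid:
#' each outer-contour pixel of the (hole-filled) mask votes for every
#' candidate ellipse passing within `tol` pixels of it. The coarse grid
#' (centers every 2 px around the foreground centroid, axes every 2 px,
#' rotation every 10 degrees) is refined once at 1 px / 2 degrees around the
#' best cell. Deterministic given the search grid.
#'
#' @param mask logical matrix (typically from [threshold_slice()]).
#' @param search optional named list overriding the search grid: components
#'   `center_row`, `center_col`, `semi_major`, `semi_minor` (numeric grids in
#'   pixels) and `rotation` (radians).
#' @param tol vote tolerance: maximal point-to-curve distance in pixels.
#' @param min_support_frac minimal fraction of the ideal ellipse perimeter
#'   that must vote; below it a detection-failure error (class
#'   `neuroseg_detection_error`) is raised.
#' @return An [ellipse_params] with `votes` set to the winning accumulator
#'   support.
#' @export
detect_skull_ellipse <- function(mask, search = NULL, tol = 1.5,
                                 min_support_frac = 0.3) {
  if (!any(mask))
    .stop_neuroseg("skull detection failed: empty mask",
                   "neuroseg_detection_error")
  edge <- .boundary_mask(fill_holes(mask))
  idx <- which(edge, arr.ind = TRUE)
  if (nrow(idx) < 8L)
    .stop_neuroseg("skull detection failed: too few edge pixels",
                   "neuroseg_detection_error")
  er <- as.numeric(idx[, 1]); ec <- as.numeric(idx[, 2])
  if (is.null(search)) search <- list()
  r0 <- mean(er); c0 <- mean(ec)
  d <- sqrt((er - r0)^2 + (ec - c0)^2)
  rmax <- as.numeric(quantile(d, 0.99)); rmin <- as.numeric(quantile(d, 0.01))
  grid <- list(
    center_row = search$center_row %||% seq(r0 - 6, r0 + 6, by = 2),
    center_col = search$center_col %||% seq(c0 - 6, c0 + 6, by = 2),
    semi_major = search$semi_major %||% seq(max(3, floor(0.85 * rmax)),
                                            ceiling(1.1 * rmax), by = 2),
    semi_minor = search$semi_minor %||% seq(max(2, floor(0.8 * rmin)),
                                            ceiling(1.15 * rmin), by = 2),
    rotation = search$rotation %||% (seq(0, 170, by = 10) * pi / 180)
  )
  acc <- .hough_accumulate(er, ec, grid$center_row, grid$center_col,
                           grid$semi_major, grid$semi_minor, grid$rotation,
                           tol)
  best <- arrayInd(which.max(acc), dim(acc))
  cur <- list(cr = grid$center_row[best[1]], cc = grid$center_col[best[2]],
              a = grid$semi_major[best[3]], b = grid$semi_minor[best[4]],
              th = grid$rotation[best[5]])
  # one refinement pass at 1 px / 2 degree resolution around the best cell
  racc <- .hough_accumulate(er, ec,
                            seq(cur$cr - 2, cur$cr + 2, by = 1),
                            seq(cur$cc - 2, cur$cc + 2, by = 1),
                            seq(max(2, cur$a - 2), cur$a + 2, by = 1),
                            seq(max(1, cur$b - 2), cur$b + 2, by = 1),
                            cur$th + seq(-10, 10, by = 2) * pi / 180,
                            tol)
  rb <- arrayInd(which.max(racc), dim(racc))
  fin <- list(cr = seq(cur$cr - 2, cur$cr + 2, by = 1)[rb[1]],
              cc = seq(cur$cc - 2, cur$cc + 2, by = 1)[rb[2]],
              a = seq(max(2, cur$a - 2), cur$a + 2, by = 1)[rb[3]],
              b = seq(max(1, cur$b - 2), cur$b + 2, by = 1)[rb[4]],
              th = (cur$th + seq(-10, 10, by = 2) * pi / 180)[rb[5]])
  votes <- max(racc)
  perim <- .ellipse_perimeter(fin$a, fin$b)
  if (votes < min_support_frac * perim)
    .stop_neuroseg(sprintf(
      "skull detection failed: best ellipse supported by %d votes (< %.0f%% of perimeter %.0f)",
      as.integer(votes), 100 * min_support_frac, perim),
      "neuroseg_detection_error")
  ellipse_params(fin$cr, fin$cc, fin$a, fin$b, fin$th %% pi, votes = votes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Ramanujan's approximation
.ellipse_perimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

#' Remove everything outside the detected skull ellipse
#'
#' Pixels outside the ellipse shrunk inward by `margin` pixels (both
#' semi-axes reduced by `margin`) are set to zero; pixels inside are
#' unchanged. The result is the cerebral-cortex slice passed to clustering.
#'
#' @param slice a [grayscale_slice].
#' @param ellipse an [ellipse_params], typically from
#'   [detect_skull_ellipse()].
#' @param margin non-negative inward margin in pixels; must be smaller than
#'   `semi_minor`.
#' @return A [grayscale_slice] with attribute `"brain_mask"` (the retained
#'   interior).
#' @export
remove_skull <- function(slice, ellipse, margin = 0) {
  stopifnot(inherits(ellipse, "ellipse_params"), margin >= 0)
  if (margin >= ellipse$semi_minor)
    .stop_neuroseg("margin exceeds the ellipse semi-minor axis",
                   "neuroseg_degenerate_error")
  p <- .as_pixels(slice)
  inner <- ellipse_params(ellipse$center_row, ellipse$center_col,
                          ellipse$semi_major - margin,
                          ellipse$semi_minor - margin, ellipse$rotation)
  keep <- make_ellipse_mask(nrow(p), ncol(p), inner)
  p[!keep] <- 0
  out <- grayscale_slice(p,
    source_format = if (inherits(slice, "grayscale_slice")) slice$source_format else "PHANTOM",
    intensity_max = if (inherits(slice, "grayscale_slice")) slice$intensity_max else NULL)
  attr(out, "brain_mask") <- keep
  out
}

# Radial extent of the bright outer band along the major axis, averaged over
# both directions: used to set the default stripping margin.
.estimate_band_thickness <- function(mask, ellipse) {
  ts <- seq(ellipse$semi_major + 2, 1, by = -0.5)
  u <- c(sin(ellipse$rotation), cos(ellipse$rotation))  # (drow, dcol)
  one_side <- function(sgn) {
    rr <- round(ellipse$center_row + sgn * ts * u[1])
    cc <- round(ellipse$center_col + sgn * ts * u[2])
    ok <- rr >= 1 & rr <= nrow(mask) & cc >= 1 & cc <= ncol(mask)
    vals <- rep(FALSE, length(ts))
    vals[ok] <- mask[cbind(rr[ok], cc[ok])]
    first <- match(TRUE, vals)
    if (is.na(first)) return(NA_real_)
    stop_at <- match(FALSE, vals[first:length(vals)])
    if (is.na(stop_at)) stop_at <- length(vals) - first + 2L
    (stop_at - 1L) * 0.5
  }
  mean(c(one_side(1), one_side(-1)), na.rm = TRUE)
}

#' Skull stripping: threshold, detect, remove
#'
#' Convenience wrapper running the whole brain-extraction stage:
#' thresholding, largest-component + hole-fill cleanup, elliptical Hough
#' detection and removal with a margin. If no ellipse reaches the minimal
#' accumulator support, stripping falls back to the shrunken convex hull of
#' the foreground (reported in `method`).
#'
#' @param slice a [grayscale_slice]; it is normalized internally.
#' @param threshold_method,threshold_level passed to [threshold_slice()].
#' @param margin inward margin in pixels; `NULL` (default) uses 1.5 x the
#'   estimated radial thickness of the bright outer band (the skull ring).
#' @param search optional search grid for [detect_skull_ellipse()].
#' @return List with `slice` (stripped, normalized), `brain_mask`, `ellipse`
#'   (or `NULL` for the hull fallback), `margin`, and `method` (`"hough"` or
#'   `"hull"`).
#' @export
strip_skull <- function(slice, threshold_method = "otsu",
                        threshold_level = NULL, margin = NULL, search = NULL) {
  norm <- normalize_slice(slice)
  fg <- threshold_slice(norm, method = threshold_method,
                        level = threshold_level)
  if (!any(fg))
    .stop_neuroseg("skull detection failed: empty thresholded image",
                   "neuroseg_detection_error")
  # fill the CSF gap etc. first so the skull ring and brain merge into one
  # head disk, then drop noise specks outside the head
  clean <- largest_component(label_connected(fill_holes(fg), 8L))
  ellipse <- tryCatch(detect_skull_ellipse(clean, search = search),
                      neuroseg_detection_error = function(e) NULL)
  if (!is.null(ellipse)) {
    if (is.null(margin)) {
      th <- .estimate_band_thickness(fg, ellipse)
      if (!is.finite(th) || th <= 0) th <- 2
      margin <- 1.5 * th
    }
    margin <- min(margin, ellipse$semi_minor - 2)
    stripped <- remove_skull(norm, ellipse, margin)
    list(slice = stripped, brain_mask = attr(stripped, "brain_mask"),
         ellipse = ellipse, margin = margin, method = "hough")
  } else {
    message("neuroseg: ellipse support below threshold; convex-hull fallback")
    if (is.null(margin)) margin <- 3
    keep <- .hull_shrink_mask(clean, margin)
    p <- norm$pixels
    p[!keep] <- 0
    list(slice = grayscale_slice(p, source_format = norm$source_format,
                                 intensity_max = 1),
         brain_mask = keep, ellipse = NULL, margin = margin, method = "hull")
  }
}

# Convex hull of the foreground, shrunk toward its centroid so that the
# boundary moves inward by roughly `margin` pixels.
.hull_shrink_mask <- function(mask, margin) {
  idx <- which(mask, arr.ind = TRUE)
  hull <- idx[chull(idx[, 2], idx[, 1]), , drop = FALSE]
  ctr <- colMeans(idx)
  rad <- sqrt((hull[, 1] - ctr[1])^2 + (hull[, 2] - ctr[2])^2)
  f <- pmax(0, 1 - margin / pmax(rad, 1e-9))
  poly_r <- ctr[1] + (hull[, 1] - ctr[1]) * f
  poly_c <- ctr[2] + (hull[, 2] - ctr[2]) * f
  .point_in_polygon_mask(nrow(mask), ncol(mask), poly_r, poly_c)
}

# even-odd rule rasterization of a polygon given by vertex rows/cols
.point_in_polygon_mask <- function(height, width, pr, pc) {
  n <- length(pr)
  inside <- matrix(FALSE, height, width)
  rows <- matrix(seq_len(height), height, width)
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  j <- n
  for (i in seq_len(n)) {
    cross <- ((pr[i] > rows) != (pr[j] > rows)) &
      (cols < (pc[j] - pc[i]) * (rows - pr[i]) / (pr[j] - pr[i]) + pc[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}
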