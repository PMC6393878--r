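#' Connected-component labeling
#'
#' Partitions the foreground of a binary mask into maximal connected
#' components under 4- or 8-connectivity. Components are numbered 1..R in
#' the order their first pixel is met in a raster scan (row by row, left to
#' right), so the labeling is deterministic.
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default, as used by the pipeline) or 4.
#' @return An object of class `labeled_regions`: list with `labels` (integer
#'   matrix, 0 = background), `sizes` (pixel counts per component) and
#'   `connectivity`.
#' @export
label_connected <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  res <- .ccl_label(mask, as.integer(connectivity))
  structure(list(labels = res$labels, sizes = res$sizes,
                 connectivity = as.integer(connectivity)),
            class = "labeled_regions")
}

#' @export
print.labeled_regions <- function(x, ...) {
  cat(sprintf("<labeled_regions> %d component(s), %d-connectivity\n",
              length(x$sizes), x$connectivity))
  invisible(x)
}

#' Mask of the largest connected component
#'
#' Ties break toward the earlier raster-order label.
#'
#' @param regions a `labeled_regions` (or logical mask, which is labeled
#'   with 8-connectivity first).
#' @return Logical mask of the maximum-size component.
#' @export
largest_component <- function(regions) {
  if (is.logical(regions)) regions <- label_connected(regions, 8L)
  stopifnot(inherits(regions, "labeled_regions"))
  if (length(regions$sizes) == 0L)
    .stop_neuroseg("no components in mask", "neuroseg_empty_region_error")
  best <- which.max(regions$sizes)  # first max = earlier label
  regions$labels == best
}

#' Apply a binary mask to a slice
#'
#' Keeps the original intensity on the mask and zeroes everything else.
#'
#' @param slice a [grayscale_slice] or numeric matrix.
#' @param mask logical matrix of the same dimensions.
#' @return Object of the same kind as `slice`.
#' @export
apply_mask <- function(slice, mask) {
  p <- .as_pixels(slice)
  if (!all(dim(p) == dim(mask)))
    .stop_neuroseg("slice and mask dimensions differ", "neuroseg_shape_error")
  p[!mask] <- 0
  if (inherits(slice, "grayscale_slice")) {
    grayscale_slice(p, source_format = slice$source_format,
                    intensity_max = slice$intensity_max)
  } else {
    p
  }
}

#' Extract the boundary contour of a mask
#'
#' Boundary pixels are foreground pixels with at least one 4-neighbour
#' background pixel (the image border counts as background), which makes the
#' contours thin 8-connected curves. Pixels are returned in traversal order
#' along each connected contour.
#'
#' @param mask logical matrix.
#' @return A list of integer matrices (one per connected contour) with
#'   columns `row`, `col`, 1-based. Empty mask gives an empty list.
#' @export
extract_boundary <- function(mask) {
  if (!any(mask)) return(list())
  b <- .boundary_mask(mask)
  comp <- label_connected(b, 8L)
  lapply(seq_along(comp$sizes), function(lab) {
    idx <- which(comp$labels == lab, arr.ind = TRUE)
    colnames(idx) <- c("row", "col")
    .order_contour(idx)
  })
}

# Greedy traversal: start from the raster-first pixel, repeatedly step to the
# nearest unvisited 8-neighbour pixel of the contour.
.order_contour <- function(idx) {
  n <- nrow(idx)
  if (n <= 2L) return(idx)
  remaining <- rep(TRUE, n)
  ord <- integer(n)
  cur <- 1L
  for (i in seq_len(n)) {
    ord[i] <- cur
    remaining[cur] <- FALSE
    if (i == n) break
    d <- pmax(abs(idx[, 1] - idx[cur, 1]), abs(idx[, 2] - idx[cur, 2]))
    d[!remaining] <- Inf
    cur <- which.min(d)
  }
  idx[ord, , drop = FALSE]
}

#' Parameters of the automatic segmentation pipeline
#'
#' @param threshold_method,threshold_level thresholding stage, see
#'   [threshold_slice()].
#' @param strip_margin inward stripping margin in pixels (`NULL`: automatic,
#'   see [strip_skull()]).
#' @param clusters number of tissue clusters over in-brain pixels.
#' @param fuzziness FCM exponent m.
#' @param tol,max_iter clustering convergence controls.
#' @param connectivity connectivity for the component postprocessing.
#' @param engine `"fcm"` (default) or `"kmeans"`.
#' @param init,seed clustering initialization, see [fcm_cluster()].
#' @param median_window odd window size of the median prefilter used by
#'   tumor mode (gray/white-matter mode applies no smoothing).
#' @param tumor_fuzziness FCM exponent of the tumor-mode membership
#'   refinement; harder (closer to 1) than the main `fuzziness` so a small
#'   hyperintense class can hold its center against the much larger
#'   white-matter class (see the methods vignette).
#' @param tumor_max_frac plausibility guard: a tumor mask larger than this
#'   fraction of the brain area is flagged implausible.
#' @return List of validated parameters.
#' @export
segment_params <- function(threshold_method = "otsu", threshold_level = NULL,
                           strip_margin = NULL, clusters = 3L, fuzziness = 2,
                           tol = 1e-5, max_iter = 100L, connectivity = 8L,
                           engine = c("fcm", "kmeans"), init = "spaced",
                           seed = NULL, median_window = 5L,
                           tumor_fuzziness = 1.2, tumor_max_frac = 0.25) {
  engine <- match.arg(engine)
  stopifnot(clusters >= 2L, fuzziness > 1, tol > 0, max_iter >= 1L,
            connectivity %in% c(4L, 8L), median_window %% 2L == 1L,
            tumor_fuzziness > 1, tumor_max_frac > 0, tumor_max_frac <= 1)
  list(threshold_method = threshold_method, threshold_level = threshold_level,
       strip_margin = strip_margin, clusters = as.integer(clusters),
       fuzziness = fuzziness, tol = tol, max_iter = as.integer(max_iter),
       connectivity = as.integer(connectivity), engine = engine, init = init,
       seed = seed, median_window = as.integer(median_window),
       tumor_fuzziness = tumor_fuzziness, tumor_max_frac = tumor_max_frac)
}

.cluster_brain <- function(pixels, params, c = params$clusters,
                           init_centers = NULL) {
  if (params$engine == "kmeans") {
    kmeans_cluster(pixels, k = c, tol = params$tol,
                   max_iter = params$max_iter, init = params$init,
                   seed = params$seed)
  } else {
    fcm_cluster(pixels, c = c, m = params$fuzziness, tol = params$tol,
                max_iter = params$max_iter, init = params$init,
                seed = params$seed, init_centers = init_centers)
  }
}

#' Fully automatic gray- and white-matter segmentation
#'
#' Runs the complete pipeline on a single slice: normalization, Otsu
#' thresholding, elliptical-Hough skull stripping, fuzzy c-means clustering
#' of the in-brain intensities into CSF/GM/WM, per-tissue crisp masks by
#' membership argmax (so GM and WM cannot overlap), 8-connectivity
#' connected-component labeling with largest-component selection per tissue,
#' mask overlay onto the original intensities, and boundary extraction.
#'
#' @param slice a [grayscale_slice] (any intensity scale).
#' @param params a [segment_params()] list.
#' @return An object of class `segmentation_result` with fields `gm_mask`,
#'   `wm_mask`, `csf_mask`, `gm_region`, `wm_region`, `gm_boundary`,
#'   `wm_boundary`, `stripped`, `brain_mask`, `model`, `tissues`, `strip`.
#' @export
segment_gm_wm <- function(slice, params = segment_params()) {
  if (!inherits(slice, "grayscale_slice")) slice <- grayscale_slice(slice)
  strip <- .stage("skull_strip",
                  strip_skull(slice, params$threshold_method,
                              params$threshold_level, params$strip_margin))
  brain <- strip$brain_mask
  x <- strip$slice$pixels[brain]
  model <- .stage("clustering", .cluster_brain(x, params))
  tissues <- .stage("tissue_labels", assign_tissue_labels(model, "gm_wm"))
  crisp <- .crisp_labels(model)
  tissue_mask <- function(name) {
    m <- matrix(FALSE, slice$height, slice$width)
    m[brain][crisp == tissues[[name]]] <- TRUE
    m
  }
  gm_all <- tissue_mask("gm"); wm_all <- tissue_mask("wm")
  csf_all <- tissue_mask("csf")
  gm <- .stage("postprocess", largest_component(
    label_connected(gm_all, params$connectivity)))
  wm <- .stage("postprocess", largest_component(
    label_connected(wm_all, params$connectivity)))
  stopifnot(!any(gm & wm))  # impossible by argmax construction; asserted
  structure(list(
    gm_mask = gm, wm_mask = wm, csf_mask = csf_all,
    gm_region = apply_mask(slice, gm), wm_region = apply_mask(slice, wm),
    gm_boundary = extract_boundary(gm), wm_boundary = extract_boundary(wm),
    stripped = strip$slice, brain_mask = brain,
    model = model, tissues = tissues, strip = strip[c("ellipse", "margin", "method")]),
    class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> GM %d px, WM %d px (strip: %s)\n",
              sum(x$gm_mask), sum(x$wm_mask), x$strip$method))
  invisible(x)
}

#' Automatic tumor segmentation
#'
#' Same front end as [segment_gm_wm()] (thresholding and skull stripping),
#' followed by a median prefilter and a k-means-then-FCM cascade with one
#' extra cluster seeded at the maximal in-brain intensity: the hard k-means
#' pre-pass anchors a center on the compact hyperintense population, and the
#' fuzzy membership refinement (with the harder `tumor_fuzziness` exponent)
#' polishes the assignment without letting the center collapse into the much
#' larger white-matter class. The crisp mask of the highest-intensity
#' cluster is reduced to its largest 8-connected component and hole-filled
#' (tumors are solid blobs). A mask larger than `tumor_max_frac` of the
#' brain area (the white matter caught instead of a tumor) is flagged
#' implausible with a warning.
#'
#' @param slice a [grayscale_slice].
#' @param params a [segment_params()] list.
#' @return List with `tumor_mask`, `tumor_region`, `tumor_boundary`,
#'   `plausible`, `model`, `stripped`, `brain_mask`, `strip`.
#' @export
segment_tumor <- function(slice, params = segment_params()) {
  if (!inherits(slice, "grayscale_slice")) slice <- grayscale_slice(slice)
  strip <- .stage("skull_strip",
                  strip_skull(slice, params$threshold_method,
                              params$threshold_level, params$strip_margin))
  brain <- strip$brain_mask
  filt <- .median_filter(strip$slice$pixels, params$median_window)
  x <- filt[brain]
  c_tumor <- params$clusters + 1L
  seeds <- c(.init_centers(x, params$clusters, "spaced"), max(x))
  pre <- .stage("clustering",
                kmeans_cluster(x, k = c_tumor, tol = params$tol,
                               max_iter = params$max_iter,
                               init_centers = seeds))
  model <- if (params$engine == "kmeans") pre else
    .stage("clustering",
           fcm_cluster(x, c = c_tumor, m = params$tumor_fuzziness,
                       tol = params$tol, max_iter = params$max_iter,
                       init_centers = pre$centers))
  tissues <- .stage("tissue_labels", assign_tissue_labels(model, "tumor"))
  crisp <- .crisp_labels(model)
  cand <- matrix(FALSE, slice$height, slice$width)
  cand[brain][crisp == tissues[["tumor"]]] <- TRUE
  if (!any(cand))
    .stop_neuroseg("tumor cluster is empty", "neuroseg_empty_region_error")
  tumor <- fill_holes(largest_component(
    label_connected(cand, params$connectivity)))
  plausible <- sum(tumor) <= params$tumor_max_frac * sum(brain)
  if (!plausible)
    warning(sprintf(
      "tumor mask implausible: %.0f%% of brain area (> %.0f%%); likely white matter",
      100 * sum(tumor) / sum(brain), 100 * params$tumor_max_frac))
  list(tumor_mask = tumor, tumor_region = apply_mask(slice, tumor),
       tumor_boundary = extract_boundary(tumor), plausible = plausible,
       model = model, stripped = strip$slice, brain_mask = brain,
       strip = strip[c("ellipse", "margin", "method")])
}

#' Median filter
#'
#' k x k running median with reflective borders; used as the tumor-mode
#' prefilter.
#'
#' @param x numeric matrix or [grayscale_slice].
#' @param size odd window size.
#' @return Numeric matrix.
#' @export
median_filter <- function(x, size = 3L) {
  .median_filter(.as_pixels(x), as.integer(size))
}

# tag stage failures with the stage name, preserving the condition class
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    if (!grepl("^\\[", conditionMessage(e)))
      e$message <- sprintf("[%s] %s", name, conditionMessage(e))
    stop(e)
  })
}
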