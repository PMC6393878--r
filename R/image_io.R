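#' Grayscale slice container
#'
#' A `grayscale_slice` is the internal representation shared by every stage of
#' the pipeline: a single 2-D intensity image together with its native dynamic
#' range and the format it was read from. Pixels are stored as a numeric
#' matrix indexed `[row, column]` with row 1 at the top.
#'
#' @param pixels numeric matrix of non-negative, finite intensities, at least
#'   16 x 16.
#' @param source_format one of `"NIFTI"`, `"DICOM"`, `"PNG"`, `"TIF"`,
#'   `"JPG"`, or `"PHANTOM"` for synthetic slices.
#' @param intensity_max native dynamic-range ceiling (e.g. 255 for 8-bit
#'   rasters). Defaults to `max(1, max(pixels))`.
#' @return An object of class `grayscale_slice` with fields `pixels`,
#'   `height`, `width`, `source_format`, `intensity_max`.
#' @export
grayscale_slice <- function(pixels, source_format = "PHANTOM",
                            intensity_max = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (nrow(pixels) < 16L || ncol(pixels) < 16L)
    stop("slice must be at least 16 x 16 pixels")
  if (!all(is.finite(pixels)))
    stop("all pixel values must be finite")
  if (any(pixels < 0))
    stop("all pixel values must be non-negative")
  fmt <- switch(toupper(source_format), JPEG = "JPG", TIFF = "TIF",
                toupper(source_format))
  if (!fmt %in% c("NIFTI", "DICOM", "PNG", "TIF", "JPG", "PHANTOM"))
    stop("unknown source format: ", source_format)
  if (is.null(intensity_max)) intensity_max <- max(1, max(pixels))
  structure(list(pixels = pixels,
                 height = nrow(pixels),
                 width = ncol(pixels),
                 source_format = fmt,
                 intensity_max = as.numeric(intensity_max)),
            class = "grayscale_slice")
}

#' @export
print.grayscale_slice <- function(x, ...) {
  cat(sprintf("<grayscale_slice> %d x %d, %s, intensity range [%.4g, %.4g] (max %.4g)\n",
              x$height, x$width, x$source_format,
              min(x$pixels), max(x$pixels), x$intensity_max))
  invisible(x)
}

.as_pixels <- function(x) {
  if (inherits(x, "grayscale_slice")) x$pixels else x
}

.detect_format <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  ext_fmt <- switch(ext,
                    nii = "NIFTI", dcm = "DICOM", png = "PNG",
                    tif = "TIF", tiff = "TIF", jpg = "JPG", jpeg = "JPG",
                    NA_character_)
  # magic-byte sniffing wins over extension
  n <- min(file.info(path)$size, 160L)
  magic <- readBin(path, "raw", n = n)
  fmt <- NA_character_
  if (n >= 8 && identical(magic[1:8],
      as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)))) fmt <- "PNG"
  else if (n >= 3 && identical(magic[1:3], as.raw(c(0xff, 0xd8, 0xff)))) fmt <- "JPG"
  else if (n >= 4 && (identical(magic[1:4], as.raw(c(0x49, 0x49, 0x2a, 0x00))) ||
                      identical(magic[1:4], as.raw(c(0x4d, 0x4d, 0x00, 0x2a))))) fmt <- "TIF"
  else if (n >= 132 && identical(magic[129:132], charToRaw("DICM"))) fmt <- "DICOM"
  else if (n >= 2 && identical(magic[1:2], as.raw(c(0x1f, 0x8b)))) fmt <- "NIFTI"  # .nii.gz
  else if (n >= 4) {
    sz <- readBin(magic[1:4], "integer", size = 4, endian = "little")
    szb <- readBin(magic[1:4], "integer", size = 4, endian = "big")
    if (sz == 348L || szb == 348L) fmt <- "NIFTI"
  }
  if (is.na(fmt)) fmt <- ext_fmt
  fmt
}

#' Read a single 2-D slice from a medical or raster image file
#'
#' Supported formats: NIfTI-1 (`.nii`, `.nii.gz`), single-file DICOM, PNG,
#' TIFF (uncompressed baseline), and JPEG. Volumetric inputs are reduced to
#' one axial plane selected by `slice_index` (default: the middle slice).
#' Multi-channel rasters are converted to luminance as the unweighted channel
#' mean. Intensities are preserved at their native scale (e.g. 0..255 for
#' 8-bit PNG, raw stored values for 16-bit DICOM).
#'
#' @param path path to the image file.
#' @param slice_index optional 1-based axial slice index for volumetric
#'   NIfTI/DICOM inputs; ignored for 2-D rasters.
#' @return A [grayscale_slice].
#' @export
read_slice <- function(path, slice_index = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- .detect_format(path)
  if (is.na(fmt))
    .stop_neuroseg(paste0("unreadable file (unrecognized format): ", path),
                   "neuroseg_format_error")
  px <- switch(fmt,
    PNG = {
      img <- png::readPNG(path, info = TRUE)
      info <- attr(img, "info")
      attr(img, "info") <- NULL
      depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
      list(p = .flatten_channels(img) * (2^depth - 1), max = 2^depth - 1)
    },
    JPG = {
      img <- jpeg::readJPEG(path)
      list(p = .flatten_channels(img) * 255, max = 255)
    },
    TIF = {
      t <- .read_tiff(path)
      list(p = t$pixels, max = t$intensity_max)
    },
    NIFTI = {
      v <- .read_nifti(path, slice_index)
      list(p = v$pixels, max = v$intensity_max)
    },
    DICOM = {
      d <- .read_dicom(path, slice_index)
      list(p = d$pixels, max = d$intensity_max)
    })
  p <- px$p
  if (any(p < 0)) {
    warning("negative intensities clamped to 0")
    p[p < 0] <- 0
  }
  grayscale_slice(p, source_format = fmt, intensity_max = px$max)
}

# rasters come in as [row, col] or [row, col, channel] in [0,1]
.flatten_channels <- function(img) {
  if (length(dim(img)) == 3L) {
    ch <- min(dim(img)[3], 3L)  # drop alpha from the luminance mean
    apply(img[, , seq_len(ch), drop = FALSE], c(1, 2), mean)
  } else {
    img
  }
}

.middle_index <- function(n) as.integer(ceiling((n + 1) / 2))

.check_slice_index <- function(slice_index, n) {
  if (is.null(slice_index)) return(.middle_index(n))
  slice_index <- as.integer(slice_index)
  if (slice_index < 1L || slice_index > n)
    .stop_neuroseg(sprintf("slice_index %d out of range [1, %d]", slice_index, n),
                   "neuroseg_bounds_error")
  slice_index
}

#' Write a binary mask as an image file
#'
#' Foreground pixels are written at the maximal intensity of the output
#' format, background as 0, so that `read_slice()` followed by thresholding
#' at half the dynamic range recovers the mask exactly.
#'
#' @param mask logical matrix.
#' @param path output path.
#' @param format `"png"`, `"nifti"` or `"tiff"`. Default: guessed from the
#'   file extension, falling back to PNG.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path, format = NULL) {
  stopifnot(is.matrix(mask), is.logical(mask), nrow(mask) > 0, ncol(mask) > 0)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, nii = "nifti", tif = "tiff", tiff = "tiff",
                     png = "png", "png")
  }
  format <- match.arg(tolower(format), c("png", "nifti", "tiff"))
  switch(format,
    png = png::writePNG(ifelse(mask, 1, 0), path),
    nifti = .write_nifti(ifelse(mask, 255, 0), path, datatype = 2L),
    tiff = .write_tiff(ifelse(mask, 255L, 0L), path, bits = 8L))
  invisible(path)
}

#' Write a grayscale slice to disk
#'
#' Intensities are affinely mapped from `[0, intensity_max]` to the output
#' format's dynamic range (PNG/TIFF); NIfTI output stores the values as-is in
#' float32.
#'
#' @param slice a [grayscale_slice] or numeric matrix.
#' @param path output path.
#' @param format `"png"`, `"nifti"` or `"tiff"` (default from extension).
#' @return Invisibly, `path`.
#' @export
write_slice <- function(slice, path, format = NULL) {
  p <- .as_pixels(slice)
  imax <- if (inherits(slice, "grayscale_slice")) slice$intensity_max else max(1, max(p))
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, nii = "nifti", tif = "tiff", tiff = "tiff", "png")
  }
  format <- match.arg(tolower(format), c("png", "nifti", "tiff"))
  switch(format,
    png = png::writePNG(pmin(pmax(p / imax, 0), 1), path),
    nifti = .write_nifti(p, path, datatype = 16L),
    tiff = .write_tiff(as.integer(round(pmin(pmax(p / imax, 0), 1) * 255)),
                       path, bits = 8L))
  invisible(path)
}

#' Affinely rescale a slice to the unit interval
#'
#' Maps intensities to `[0, 1]` by `(x - min) / (max - min)`; constant images
#' map to all zeros. The map is monotone, so pixel intensity order is
#' preserved, and the function is idempotent on its own output.
#'
#' @param slice a [grayscale_slice] or numeric matrix.
#' @return A [grayscale_slice] with pixels in `[0, 1]` and `intensity_max 1`.
#' @export
normalize_slice <- function(slice) {
  p <- .as_pixels(slice)
  fmt <- if (inherits(slice, "grayscale_slice")) slice$source_format else "PHANTOM"
  rng <- range(p)
  p <- if (rng[2] > rng[1]) (p - rng[1]) / (rng[2] - rng[1]) else
    matrix(0, nrow(p), ncol(p))
  grayscale_slice(p, source_format = fmt, intensity_max = 1)
}
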