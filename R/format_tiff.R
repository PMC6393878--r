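# Minimal baseline TIFF reader/writer.
#
# Reader subset: uncompressed (Compression = 1), grayscale or RGB, 8 or 16
# bits per sample, striped layout, either byte order. Writer emits a single
# uncompressed grayscale strip. Tiled, compressed or planar TIFFs are not
# supported and raise a format error.

.read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  order_ <- rawToChar(raw[1:2])
  endian <- switch(order_, II = "little", MM = "big",
                   .stop_neuroseg("not a TIFF file", "neuroseg_format_error"))
  rd <- function(off, n, size)
    readBin(raw[(off + 1):(off + n * size)], "integer", n = n, size = size,
            signed = size == 4L, endian = endian)
  if (rd(2, 1, 2) != 42L)
    .stop_neuroseg("not a TIFF file", "neuroseg_format_error")
  ifd_off <- rd(4, 1, 4)
  n_entries <- rd(ifd_off, 1, 2)
  tags <- list()
  type_size <- c(1L, 1L, 2L, 4L, 8L)  # BYTE ASCII SHORT LONG RATIONAL
  for (i in seq_len(n_entries)) {
    e <- ifd_off + 2 + (i - 1) * 12
    tag <- rd(e, 1, 2); type <- rd(e + 2, 1, 2); count <- rd(e + 4, 1, 4)
    size <- if (type <= 5L) type_size[type] else 1L
    nbytes <- size * count
    voff <- if (nbytes <= 4) e + 8 else rd(e + 8, 1, 4)
    vals <- if (type %in% c(3L, 4L)) rd(voff, count, size) else
      as.integer(raw[(voff + 1):(voff + nbytes)])
    tags[[as.character(tag)]] <- vals
  }
  g <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) default else v
  }
  width <- g(256); height <- g(257)
  bits <- g(258, 1L)[1]
  compression <- g(259, 1L)
  spp <- g(277, 1L)
  strip_offsets <- g(273); strip_counts <- g(279)
  rows_per_strip <- g(278, height)
  if (is.null(width) || is.null(height) || is.null(strip_offsets))
    .stop_neuroseg("TIFF lacks required tags", "neuroseg_format_error")
  if (compression != 1L)
    .stop_neuroseg("only uncompressed TIFF supported", "neuroseg_format_error")
  if (!bits %in% c(8L, 16L) || !spp %in% c(1L, 3L))
    .stop_neuroseg("unsupported TIFF sample layout", "neuroseg_format_error")
  if (g(284, 1L) != 1L)
    .stop_neuroseg("planar TIFF not supported", "neuroseg_format_error")
  bpp <- bits / 8L
  vals <- integer(0)
  for (s in seq_along(strip_offsets)) {
    nb <- if (!is.null(strip_counts)) strip_counts[s] else
      width * rows_per_strip * spp * bpp
    vals <- c(vals, rd(strip_offsets[s], nb / bpp, bpp))
  }
  if (bpp == 1L) vals <- ifelse(vals < 0, vals + 256L, vals)  # raw bytes as BYTE
  if (bpp == 2L) vals <- ifelse(vals < 0, vals + 65536L, vals)
  npx <- width * height
  if (length(vals) < npx * spp)
    .stop_neuroseg("truncated TIFF pixel data", "neuroseg_format_error")
  if (spp == 3L) {
    m <- matrix(as.numeric(vals[seq_len(npx * 3)]), ncol = 3, byrow = TRUE)
    vals <- rowMeans(m)  # luminance = unweighted channel mean
  }
  list(pixels = matrix(as.numeric(vals[seq_len(npx)]), nrow = height,
                       ncol = width, byrow = TRUE),
       intensity_max = 2^bits - 1)
}

.write_tiff <- function(pixels, path, bits = 8L) {
  stopifnot(is.matrix(pixels), bits %in% c(8L, 16L))
  endian <- "little"
  height <- nrow(pixels); width <- ncol(pixels)
  vals <- as.integer(round(as.vector(t(pixels))))
  bpp <- bits / 8L
  px <- writeBin(vals, raw(), size = bpp, endian = endian)
  n_entries <- 9L
  ifd_off <- 8L
  data_off <- ifd_off + 2L + n_entries * 12L + 4L
  entry <- function(tag, type, count, value) {
    v <- writeBin(as.integer(value), raw(),
                  size = if (type == 3L) 2L else 4L, endian = endian)
    c(writeBin(as.integer(c(tag, type)), raw(), size = 2, endian = endian),
      writeBin(as.integer(count), raw(), size = 4, endian = endian),
      v, raw(4L - length(v)))
  }
  ifd <- c(
    entry(256, 4L, 1L, width),
    entry(257, 4L, 1L, height),
    entry(258, 3L, 1L, bits),
    entry(259, 3L, 1L, 1L),          # uncompressed
    entry(262, 3L, 1L, 1L),          # BlackIsZero
    entry(273, 4L, 1L, data_off),    # strip offset
    entry(277, 3L, 1L, 1L),          # samples per pixel
    entry(278, 4L, 1L, height),      # rows per strip
    entry(279, 4L, 1L, length(px))   # strip byte count
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"),
             writeBin(42L, raw(), size = 2, endian = endian),
             writeBin(ifd_off, raw(), size = 4, endian = endian),
             writeBin(n_entries, raw(), size = 2, endian = endian),
             ifd,
             raw(4),                 # next IFD = 0
             px), con)
  invisible(path)
}
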