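# Minimal single-file DICOM reader (plus a writer used for fixtures).
#
# Supported subset: part-10 files (128-byte preamble + "DICM"), transfer
# syntaxes Implicit VR Little Endian (1.2.840.10008.1.2) and Explicit VR
# Little Endian (1.2.840.10008.1.2.1), uncompressed grayscale pixel data with
# 8 or 16 bits allocated, optional RescaleSlope/Intercept, optional
# multi-frame. Sequences with defined length are skipped; undefined-length
# sequences are rejected. Series stitching and spatial metadata are out of
# scope.

.dcm_tag <- function(group, element) sprintf("%04X,%04X", group, element)

# string values are NUL- or space-padded to even length
.dcm_string <- function(bytes) trimws(rawToChar(bytes[bytes != as.raw(0)]))

.read_dicom <- function(path, slice_index = NULL) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 160 || !identical(raw[129:132], charToRaw("DICM")))
    .stop_neuroseg("not a part-10 DICOM file", "neuroseg_format_error")
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer", size = 2,
                               signed = FALSE, endian = "little")
  u32 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer", size = 4,
                               endian = "little")
  pos <- 132L  # 0-based offset just past "DICM"
  elems <- list()
  explicit <- NA  # decided from the transfer syntax once the meta group ends
  transfer_syntax <- NULL
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 8 <= length(raw)) {
    group <- u16(pos); element <- u16(pos + 2)
    if (group != 0x0002 && is.na(explicit)) {
      explicit <- is.null(transfer_syntax) ||
        transfer_syntax != "1.2.840.10008.1.2"
    }
    expl_here <- if (group == 0x0002) TRUE else explicit
    if (expl_here) {
      vr <- rawToChar(raw[(pos + 5):(pos + 6)])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8); hdr <- 12L
      } else {
        len <- u16(pos + 6); hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- u32(pos + 4); hdr <- 8L
    }
    if (identical(len, -1L) || (!is.na(len) && len < 0))
      .stop_neuroseg("undefined-length DICOM element not supported",
                     "neuroseg_format_error")
    start <- pos + hdr
    if (start + len > length(raw))
      .stop_neuroseg("truncated DICOM element", "neuroseg_format_error")
    tag <- .dcm_tag(group, element)
    if (!identical(vr, "SQ"))
      elems[[tag]] <- list(vr = vr, bytes = raw[seq_len(len) + start])
    if (tag == .dcm_tag(0x0002, 0x0010))
      transfer_syntax <- .dcm_string(elems[[tag]]$bytes)
    pos <- start + len
    if (tag == .dcm_tag(0x7FE0, 0x0010)) break
  }
  if (!is.null(transfer_syntax) &&
      !transfer_syntax %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
    .stop_neuroseg(paste0("unsupported DICOM transfer syntax: ", transfer_syntax),
                   "neuroseg_format_error")
  get_us <- function(group, element, default = NULL) {
    e <- elems[[.dcm_tag(group, element)]]
    if (is.null(e)) return(default)
    readBin(e$bytes, "integer", size = 2, signed = FALSE, endian = "little")
  }
  get_str <- function(group, element, default = NULL) {
    e <- elems[[.dcm_tag(group, element)]]
    if (is.null(e)) return(default)
    .dcm_string(e$bytes)
  }
  rows <- get_us(0x0028, 0x0010); cols <- get_us(0x0028, 0x0011)
  bits_alloc <- get_us(0x0028, 0x0100, 8L)
  bits_stored <- get_us(0x0028, 0x0101, bits_alloc)
  pixrep <- get_us(0x0028, 0x0103, 0L)
  nframes <- as.integer(get_str(0x0028, 0x0008, "1"))
  slope <- as.numeric(get_str(0x0028, 0x1053, "1"))
  inter <- as.numeric(get_str(0x0028, 0x1052, "0"))
  pd <- elems[[.dcm_tag(0x7FE0, 0x0010)]]
  if (is.null(rows) || is.null(cols) || is.null(pd))
    .stop_neuroseg("DICOM file lacks Rows/Columns/PixelData",
                   "neuroseg_format_error")
  if (!bits_alloc %in% c(8L, 16L))
    .stop_neuroseg("only 8- or 16-bit DICOM pixel data supported",
                   "neuroseg_format_error")
  k <- .check_slice_index(slice_index, nframes)
  bpp <- bits_alloc / 8L
  npx <- rows * cols
  off <- (k - 1L) * npx * bpp
  if (off + npx * bpp > length(pd$bytes))
    .stop_neuroseg("truncated DICOM pixel data", "neuroseg_format_error")
  vals <- readBin(pd$bytes[(off + 1):(off + npx * bpp)], "integer",
                  n = npx, size = bpp, signed = pixrep == 1L && bpp == 2L,
                  endian = "little")
  if (bpp == 1L && pixrep == 1L) vals <- ifelse(vals > 127, vals - 256, vals)
  if (slope != 1 || inter != 0) vals <- vals * slope + inter
  m <- matrix(as.numeric(vals), nrow = rows, ncol = cols, byrow = TRUE)
  list(pixels = m, intensity_max = 2^bits_stored - 1, n_slices = nframes)
}

# Writer: Explicit VR Little Endian, minimal tag set. Used to build fixtures
# and to round-trip the reader in tests.
.write_dicom <- function(pixels, path, bits = 16L) {
  stopifnot(is.matrix(pixels), bits %in% c(8L, 16L))
  le16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  le32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
  elem <- function(group, element, vr, bytes) {
    if (length(bytes) %% 2 == 1) bytes <- c(bytes, as.raw(0))
    if (vr %in% c("OB", "OW")) {
      c(le16(group), le16(element), charToRaw(vr), raw(2), le32(length(bytes)), bytes)
    } else {
      c(le16(group), le16(element), charToRaw(vr), le16(length(bytes)), bytes)
    }
  }
  str_bytes <- function(s) charToRaw(s)
  ts <- "1.2.840.10008.1.2.1"
  meta <- c(
    elem(0x0002, 0x0010, "UI", str_bytes(ts)),
    elem(0x0002, 0x0013, "SH", str_bytes("neuroseg"))
  )
  meta <- c(elem(0x0002, 0x0000, "UL", le32(length(meta))), meta)
  vals <- as.integer(round(as.vector(t(pixels))))
  px <- writeBin(vals, raw(), size = bits / 8L, endian = "little")
  body <- c(
    elem(0x0028, 0x0002, "US", le16(1L)),                     # SamplesPerPixel
    elem(0x0028, 0x0004, "CS", str_bytes("MONOCHROME2")),
    elem(0x0028, 0x0010, "US", le16(nrow(pixels))),           # Rows
    elem(0x0028, 0x0011, "US", le16(ncol(pixels))),           # Columns
    elem(0x0028, 0x0100, "US", le16(bits)),                   # BitsAllocated
    elem(0x0028, 0x0101, "US", le16(bits)),                   # BitsStored
    elem(0x0028, 0x0102, "US", le16(bits - 1L)),              # HighBit
    elem(0x0028, 0x0103, "US", le16(0L)),                     # unsigned
    elem(0x7FE0, 0x0010, if (bits == 16L) "OW" else "OB", px)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}
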