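# Minimal NIfTI-1 reader/writer (single-file .nii / .nii.gz).
#
# No R package for NIfTI is available in the supported dependency set, so a
# small codec for the subset this package needs is implemented here: 2-D or
# 3-D volumes, datatypes uint8/int16/int32/float32/float64/uint16, optional
# scl_slope/scl_inter rescaling, either endianness. Orientation/affine
# handling is out of scope: data are returned in storage order with the
# fastest-varying dimension as image columns.

.nifti_datatypes <- data.frame(
  code = c(2L, 4L, 8L, 16L, 64L, 512L),
  what = c("integer", "integer", "integer", "double", "double", "integer"),
  size = c(1L, 2L, 4L, 4L, 8L, 2L),
  signed = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE),
  ceiling = c(255, 32767, 2147483647, 1, 1, 65535)
)

.read_nifti <- function(path, slice_index = NULL) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348)
    .stop_neuroseg("truncated NIfTI header", "neuroseg_format_error")
  endian <- "little"
  sizeof_hdr <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
  }
  if (sizeof_hdr != 348L)
    .stop_neuroseg("not a NIfTI-1 file (bad sizeof_hdr)", "neuroseg_format_error")
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    .stop_neuroseg("not a NIfTI-1 file (bad magic)", "neuroseg_format_error")
  dim16 <- readBin(hdr[41:56], "integer", n = 8, size = 2, endian = endian)
  ndim <- dim16[1]
  if (!ndim %in% c(2L, 3L))
    .stop_neuroseg(sprintf("unsupported NIfTI dimensionality: %d", ndim),
                   "neuroseg_format_error")
  nx <- dim16[2]; ny <- dim16[3]; nz <- if (ndim >= 3L) dim16[4] else 1L
  datatype <- readBin(hdr[71:72], "integer", size = 2, endian = endian)
  dt <- .nifti_datatypes[.nifti_datatypes$code == datatype, ]
  if (nrow(dt) != 1L)
    .stop_neuroseg(sprintf("unsupported NIfTI datatype code %d", datatype),
                   "neuroseg_format_error")
  scl_slope <- readBin(hdr[113:116], "double", size = 4, endian = endian)
  scl_inter <- readBin(hdr[117:120], "double", size = 4, endian = endian)
  vox_offset <- readBin(hdr[109:112], "double", size = 4, endian = endian)
  skip <- max(vox_offset, 352) - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  k <- .check_slice_index(slice_index, nz)
  nvox_slice <- as.numeric(nx) * ny
  if (k > 1) readBin(con, "raw", n = dt$size * nvox_slice * (k - 1))
  vals <- readBin(con, dt$what, n = nvox_slice, size = dt$size,
                  signed = dt$signed || dt$size > 2, endian = endian)
  if (length(vals) < nvox_slice)
    .stop_neuroseg("truncated NIfTI pixel data", "neuroseg_format_error")
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  # storage order: x fastest -> columns of the displayed slice
  m <- matrix(as.numeric(vals), nrow = ny, ncol = nx, byrow = TRUE)
  ceiling_ <- if (dt$ceiling > 1) dt$ceiling else max(1, max(m))
  list(pixels = m, intensity_max = ceiling_, n_slices = nz, slice = k)
}

.write_nifti <- function(pixels, path, datatype = 16L) {
  stopifnot(is.matrix(pixels))
  dt <- .nifti_datatypes[.nifti_datatypes$code == datatype, ]
  stopifnot(nrow(dt) == 1L)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  endian <- "little"
  hdr <- raw(348)
  put <- function(h, off, vals, size, what = "integer") {
    r <- writeBin(if (what == "integer") as.integer(vals) else as.numeric(vals),
                  raw(), size = size, endian = endian)
    h[(off + 1):(off + length(r))] <- r
    h
  }
  hdr <- put(hdr, 0, 348L, 4)                                  # sizeof_hdr
  hdr <- put(hdr, 40, c(2L, ncol(pixels), nrow(pixels), 1L, 1L, 1L, 1L, 1L), 2)  # dim
  hdr <- put(hdr, 70, dt$code, 2)                              # datatype
  hdr <- put(hdr, 72, dt$size * 8L, 2)                         # bitpix
  hdr <- put(hdr, 76, c(1, 1, 1, 1, 0, 0, 0, 0), 4, "double")  # pixdim
  hdr <- put(hdr, 108, 352, 4, "double")                       # vox_offset
  hdr <- put(hdr, 112, 1, 4, "double")                         # scl_slope
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0))               # magic
  writeBin(hdr, con)
  writeBin(raw(4), con)                                        # extension flags
  vals <- as.vector(t(pixels))                                 # x fastest
  if (dt$what == "integer") {
    writeBin(as.integer(round(vals)), con, size = dt$size, endian = endian)
  } else {
    writeBin(as.numeric(vals), con, size = dt$size, endian = endian)
  }
  invisible(path)
}
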