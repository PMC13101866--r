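# Minimal baseline TIFF I/O (little-endian, uncompressed, single-sample
# grayscale, one page per z-slice). No TIFF reader ships with the supported
# dependency set, so the subset needed for image/label volumes is implemented
# here and cross-validated in the test suite against an external reader.
# Voxel spacing travels in a JSON sidecar (<file>.json) because baseline TIFF
# has no standard 3D-spacing tag.

#' Write a 3D volume as a multi-page TIFF with a spacing sidecar
#'
#' Intensity stacks are stored as 32-bit IEEE floats, label volumes as 32-bit
#' unsigned integers, one page per z-slice, uncompressed, little-endian. A
#' JSON sidecar `<path>.json` records the voxel spacing (um, axis order
#' z,y,x) and the volume kind.
#'
#' @param x an [image_stack()] or [label_volume()]
#' @param path output file path (`.tif`)
#' @return `path`, invisibly
#' @export
write_tiff <- function(x, path) {
  if (!(inherits(x, "image_stack") || inherits(x, "label_volume")))
    stop("`x` must be an image_stack or label_volume")
  is_label <- inherits(x, "label_volume")
  d <- dim(x)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  page_bytes <- ny * nx * 4L
  n_entries <- 10L
  ifd_bytes <- 2L + n_entries * 12L + 4L
  stride <- page_bytes + ifd_bytes

  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  w4 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  entry <- function(tag, type, value) {
    w2(tag); w2(type); w4(1L)
    if (type == 3L) { w2(value); w2(0L) } else w4(value)  # SHORT inline / LONG
  }

  writeBin(charToRaw("II"), con)
  w2(42L)
  w4(8L + page_bytes)  # first IFD follows first page's data

  for (z in seq_len(nz)) {
    slice <- as.vector(t(x[z, , , drop = TRUE]))  # row-major: y rows, x cols
    if (is_label) writeBin(as.integer(slice), con, size = 4L, endian = "little")
    else          writeBin(as.double(slice),  con, size = 4L, endian = "little")
    data_off <- 8L + (z - 1L) * stride
    w2(n_entries)
    entry(256L, 4L, nx)                      # ImageWidth
    entry(257L, 4L, ny)                      # ImageLength
    entry(258L, 3L, 32L)                     # BitsPerSample
    entry(259L, 3L, 1L)                      # Compression: none
    entry(262L, 3L, 1L)                      # Photometric: BlackIsZero
    entry(273L, 4L, data_off)                # StripOffsets
    entry(277L, 3L, 1L)                      # SamplesPerPixel
    entry(278L, 4L, ny)                      # RowsPerStrip
    entry(279L, 4L, page_bytes)              # StripByteCounts
    entry(339L, 3L, if (is_label) 1L else 3L)  # SampleFormat: uint / float
    w4(if (z < nz) data_off + stride + page_bytes else 0L)  # next page's IFD
  }

  jsonlite::write_json(
    list(spacing_um = spacing(x), axes = "ZYX",
         kind = if (is_label) "labels" else "intensity"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page grayscale TIFF into an image or label volume
#'
#' Supports the uncompressed single-sample baseline subset (8/16/32-bit
#' unsigned integer and 32-bit float, little-endian, any strip layout). If a
#' sidecar `<path>.json` written by [write_tiff()] exists, its spacing and
#' kind are honoured; otherwise `spacing` is used and the kind is inferred
#' from the sample format.
#'
#' @param path TIFF file path
#' @param spacing fallback voxel spacing (um, z,y,x) when no sidecar exists
#' @return an [image_stack()] or [label_volume()]
#' @export
read_tiff <- function(path, spacing = c(1, 1, 1)) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  u16 <- function(off) sum(as.integer(raw_all[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.numeric(raw_all[off + 1:4]) * c(1, 256, 65536, 16777216))
  if (rawToChar(raw_all[1:2]) != "II")
    stop("only little-endian ('II') TIFF is supported")
  if (u16(2) != 42) stop("not a TIFF file")

  read_values <- function(off, type, count, value_field_off) {
    size <- if (type == 3L) 2L else 4L
    src <- if (count * size <= 4L) value_field_off else u32(value_field_off)
    vapply(seq_len(count) - 1L, function(i)
      if (type == 3L) u16(src + i * 2L) else u32(src + i * 4L), numeric(1))
  }

  slices <- list()
  ifd <- u32(4)
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (e in seq_len(n) - 1L) {
      off <- ifd + 2L + e * 12L
      tag <- u16(off); type <- u16(off + 2L); count <- u32(off + 4L)
      if (tag %in% c(256, 257, 258, 259, 273, 277, 279, 339))
        tags[[as.character(tag)]] <- read_values(off, type, count, off + 8L)
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop("missing required TIFF tag ", tag)
        default
      } else v
    }
    nx <- need(256); ny <- need(257)
    bits <- need(258, 1); fmt <- need(339, 1)
    if (need(259, 1) != 1) stop("compressed TIFF is not supported")
    if (need(277, 1) != 1) stop("only single-sample grayscale TIFF is supported")
    offs <- need(273); counts <- need(279)
    buf <- raw(0)
    for (s in seq_along(offs))
      buf <- c(buf, raw_all[offs[s] + seq_len(counts[s])])
    vals <- switch(paste(fmt, bits),
      "1 8"  = as.numeric(readBin(buf, "integer", n = nx * ny, size = 1L, signed = FALSE)),
      "1 16" = as.numeric(readBin(buf, "integer", n = nx * ny, size = 2L,
                                  signed = FALSE, endian = "little")),
      "1 32" = as.numeric(readBin(buf, "integer", n = nx * ny, size = 4L, endian = "little")),
      "3 32" = readBin(buf, "double", n = nx * ny, size = 4L, endian = "little"),
      stop("unsupported TIFF sample format: format ", fmt, ", ", bits, " bits"))
    slices[[length(slices) + 1L]] <- matrix(vals, nrow = ny, ncol = nx, byrow = TRUE)
    ifd <- u32(ifd + 2L + n * 12L)
    is_float <- fmt == 3
  }
  nz <- length(slices)
  ny <- nrow(slices[[1]]); nx <- ncol(slices[[1]])
  arr <- array(0, dim = c(nz, ny, nx))
  for (z in seq_len(nz)) arr[z, , ] <- slices[[z]]

  kind <- if (is_float) "intensity" else "labels"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$spacing_um)) spacing <- as.numeric(meta$spacing_um)
    if (!is.null(meta$kind)) kind <- meta$kind
  }
  if (kind == "labels") label_volume(arr, spacing) else image_stack(arr, spacing)
}
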