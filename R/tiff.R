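# Minimal baseline TIFF 6 reader/writer for grayscale image stacks: the
# environment provides no TIFF package, and the pipeline only needs
# uncompressed single-sample pages (8/16-bit unsigned in, 32-bit float out,
# NaN encoding uncovered voxels). Not a general TIFF implementation.

TIFF_TAGS <- c(width = 256L, height = 257L, bits = 258L, compression = 259L,
               photometric = 262L, description = 270L, strip_offsets = 273L,
               rows_per_strip = 278L, strip_counts = 279L, sample_format = 339L)

#' Read a multi-page TIFF stack
#'
#' Reads an uncompressed grayscale multi-page (or single-page) TIFF into a
#' [voxel_volume()], pages stacked along the z axis. 8- and 16-bit unsigned
#' and 32-bit float samples are supported, in either byte order. Voxel
#' spacing is taken from a `spacing=<value>` entry in the ImageDescription
#' tag when present (the convention ImageJ uses), else 1.
#'
#' @param path path to a TIFF file
#' @return a [voxel_volume()] with dimensions (pages, height, width)
#' @export
read_tif <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  endian <- if (raw[1] == as.raw(0x49) && raw[2] == as.raw(0x49)) "little"
            else if (raw[1] == as.raw(0x4d) && raw[2] == as.raw(0x4d)) "big"
            else stop("not a TIFF file: ", path)
  ru16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer", size = 2,
                                signed = FALSE, endian = endian)
  ru32 <- function(off) {
    v <- readBin(raw[(off + 1):(off + 4)], "integer", size = 4, endian = endian)
    if (v < 0) v + 2^32 else v
  }
  if (ru16(2) != 42L) stop("not a TIFF file: ", path)
  ifd_off <- ru32(4)
  pages <- list()
  spacing <- 1
  while (ifd_off != 0) {
    n_entries <- ru16(ifd_off)
    entries <- list()
    for (i in seq_len(n_entries)) {
      eo <- ifd_off + 2 + (i - 1) * 12
      tag <- ru16(eo); type <- ru16(eo + 2); count <- ru32(eo + 4)
      size <- c(1, 1, 2, 4, 8)[type]  # BYTE ASCII SHORT LONG RATIONAL
      if (is.na(size)) size <- 4
      total <- size * count
      voff <- if (total <= 4) eo + 8 else ru32(eo + 8)
      vals <- switch(as.character(type),
        "3" = vapply(seq_len(count), function(k) ru16(voff + (k - 1) * 2), 0L),
        "4" = vapply(seq_len(count), function(k) ru32(voff + (k - 1) * 4), 0),
        "2" = rawToChar(raw[(voff + 1):(voff + count)]),
        "1" = as.integer(raw[(voff + 1):(voff + count)]),
        NULL)
      entries[[as.character(tag)]] <- vals
    }
    pages[[length(pages) + 1L]] <- entries
    ifd_off <- ru32(ifd_off + 2 + n_entries * 12)
  }
  if (!length(pages)) stop("TIFF contains no images: ", path)
  getv <- function(p, tag, default = NULL) {
    v <- p[[as.character(TIFF_TAGS[[tag]])]]
    if (is.null(v)) default else v
  }
  dims <- vapply(pages, function(p)
    c(getv(p, "height"), getv(p, "width")), numeric(2))
  if (any(apply(dims, 1, function(r) length(unique(r)) != 1)))
    stop("TIFF pages have differing dimensions")
  h <- dims[1, 1]; w <- dims[2, 1]
  desc <- getv(pages[[1]], "description", "")
  m <- regmatches(desc, regexpr("spacing=[0-9.eE+-]+", desc))
  if (length(m) && nzchar(m)) spacing <- as.numeric(sub("spacing=", "", m))
  slices <- lapply(pages, function(p) {
    if (!identical(getv(p, "compression", 1L)[1], 1L) &&
        getv(p, "compression", 1L)[1] != 1)
      stop("only uncompressed TIFF is supported")
    bits <- getv(p, "bits", 1L)[1]
    fmt <- getv(p, "sample_format", 1L)[1]
    offs <- getv(p, "strip_offsets")
    cnts <- getv(p, "strip_counts")
    bytes <- unlist(lapply(seq_along(offs), function(k)
      raw[(offs[k] + 1):(offs[k] + cnts[k])]))
    px <- if (bits == 8) {
      as.numeric(readBin(bytes, "integer", n = w * h, size = 1,
                         signed = FALSE, endian = endian))
    } else if (bits == 16) {
      as.numeric(readBin(bytes, "integer", n = w * h, size = 2,
                         signed = FALSE, endian = endian))
    } else if (bits == 32 && fmt == 3) {
      readBin(bytes, "double", n = w * h, size = 4, endian = endian)
    } else {
      stop("unsupported TIFF sample layout (", bits, "-bit, format ", fmt, ")")
    }
    matrix(px, nrow = h, ncol = w, byrow = TRUE)  # rows scan y, fastest x
  })
  vol <- array(0, c(length(slices), h, w))
  for (z in seq_along(slices)) vol[z, , ] <- slices[[z]]
  voxel_volume(vol, spacing)
}

#' @rdname read_tif
#' @export
read_stack <- read_tif

#' Write a volume as a multi-page TIFF
#'
#' Writes an uncompressed little-endian grayscale stack, one page per z
#' slice. Binary volumes become 8-bit (0/255); numeric volumes are written
#' as 32-bit float by default (NaN marks uncovered voxels in EF images), or
#' as 8/16-bit unsigned when requested and representable. Voxel spacing is
#' recorded in the ImageDescription tag.
#'
#' @param vol a [voxel_volume()], [binary_volume()], or 3D array
#' @param path output file path
#' @param type `"auto"`, `"uint8"`, `"uint16"`, or `"float32"`
#' @return `path`, invisibly
#' @export
write_tif <- function(vol, path, type = c("auto", "uint8", "uint16", "float32")) {
  type <- match.arg(type)
  spacing <- vol_spacing(vol)
  d <- dim(vol)
  if (length(d) != 3L) stop("`vol` must be a 3D array")
  if (is.logical(vol)) {
    data <- array(as.numeric(vol) * 255, d)
    if (type == "auto") type <- "uint8"
  } else {
    data <- vol
    if (type == "auto") type <- "float32"
  }
  if (type == "uint8" && (anyNA(data) || min(data) < 0 || max(data) > 255))
    stop("data not representable as uint8")
  if (type == "uint16" && (anyNA(data) || min(data) < 0 || max(data) > 65535))
    stop("data not representable as uint16")
  nz <- d[1]; h <- d[2]; w <- d[3]
  bps <- switch(type, uint8 = 8L, uint16 = 16L, float32 = 32L)
  fmt <- if (type == "float32") 3L else 1L
  bytes_pp <- bps / 8L
  strip_len <- w * h * bytes_pp
  desc <- sprintf("boneshape\nspacing=%g\n", spacing)
  if (nchar(desc) %% 2 == 1) desc <- paste0(desc, " ")
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  # header
  writeBin(charToRaw("II"), con); w16(42L)
  data_start <- 8L
  desc_off <- data_start + nz * strip_len
  ifd0 <- desc_off + nchar(desc)
  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  w32(ifd0)
  # pixel data, page by page, rows scan y with x fastest
  for (z in seq_len(nz)) {
    px <- as.vector(t(data[z, , , drop = TRUE]))
    if (type == "uint8") {
      writeBin(as.integer(round(px)), con, size = 1)
    } else if (type == "uint16") {
      v <- as.integer(round(px)); v <- ifelse(v > 32767L, v - 65536L, v)
      writeBin(v, con, size = 2, endian = "little")
    } else {
      writeBin(as.numeric(px), con, size = 4, endian = "little")
    }
  }
  writeBin(charToRaw(desc), con)
  entry <- function(tag, type_id, count, value) {
    w16(tag); w16(type_id); w32(count)
    if (type_id == 3L) { w16(value); w16(0L) } else w32(value)
  }
  for (z in seq_len(nz)) {
    # entries must be sorted by tag id
    w16(n_entries)
    entry(256L, 4L, 1L, w)                      # ImageWidth
    entry(257L, 4L, 1L, h)                      # ImageLength
    entry(258L, 3L, 1L, bps)                    # BitsPerSample
    entry(259L, 3L, 1L, 1L)                     # Compression: none
    entry(262L, 3L, 1L, 1L)                     # Photometric: BlackIsZero
    entry(270L, 2L, nchar(desc), desc_off)      # ImageDescription
    entry(273L, 4L, 1L, data_start + (z - 1L) * strip_len)  # StripOffsets
    entry(278L, 4L, 1L, h)                      # RowsPerStrip
    entry(279L, 4L, 1L, strip_len)              # StripByteCounts
    entry(339L, 3L, 1L, fmt)                    # SampleFormat
    w32(if (z < nz) ifd0 + z * ifd_size else 0L)  # next IFD
  }
  invisible(path)
}
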