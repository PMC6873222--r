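# Minimal single-strip grayscale TIFF I/O (8/16-bit, uncompressed,
# little-endian). Covers exactly the files the simulator writes and the
# analyzer reads; it is not a general TIFF implementation.

TIFF_TAGS <- c(
  width = 256L, length = 257L, bits = 258L, compression = 259L,
  photometric = 262L, strip_offsets = 273L, samples = 277L,
  rows_per_strip = 278L, strip_bytes = 279L
)

#' Write a grayscale image as an uncompressed TIFF
#'
#' Writes a single-strip, little-endian, 8- or 16-bit grayscale baseline TIFF.
#' Intensities are rounded and clipped to the bit depth.
#'
#' @param img Numeric matrix; rows are image rows.
#' @param path Output file path.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @seealso [read_gray_tiff()]
#' @export
write_gray_tiff <- function(img, path, bit_depth = 16L) {
  stopifnot(is.matrix(img))
  if (!bit_depth %in% c(8L, 16L)) abort("`bit_depth` must be 8 or 16.")
  maxv <- 2^bit_depth - 1
  v <- as.integer(pmin(pmax(round(img), 0), maxv))
  nr <- nrow(img); nc <- ncol(img)
  # pixel data, row-major
  px <- matrix(v, nr, nc)
  px <- as.integer(t(px))
  if (bit_depth == 8L) {
    data <- as.raw(px)
  } else {
    data <- as.raw(rbind(px %% 256L, px %/% 256L))  # little-endian 16-bit
  }
  u16 <- function(x) as.raw(c(x %% 256L, x %/% 256L))
  u32 <- function(x) {
    x <- as.numeric(x)
    as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
             (x %/% 16777216) %% 256))
  }
  entry <- function(tag, type, count, value) {
    # type 3 = SHORT (stored left-justified in 4-byte field), 4 = LONG
    val <- if (type == 3L) c(u16(value), u16(0L)) else u32(value)
    c(u16(tag), u16(type), u32(count), val)
  }
  data_offset <- 8L
  ifd_offset <- data_offset + length(data)
  ifd <- c(
    u16(9L),
    entry(TIFF_TAGS[["width"]], 3L, 1L, nc),
    entry(TIFF_TAGS[["length"]], 3L, 1L, nr),
    entry(TIFF_TAGS[["bits"]], 3L, 1L, bit_depth),
    entry(TIFF_TAGS[["compression"]], 3L, 1L, 1L),
    entry(TIFF_TAGS[["photometric"]], 3L, 1L, 1L),  # BlackIsZero
    entry(TIFF_TAGS[["strip_offsets"]], 4L, 1L, data_offset),
    entry(TIFF_TAGS[["samples"]], 3L, 1L, 1L),
    entry(TIFF_TAGS[["rows_per_strip"]], 3L, 1L, nr),
    entry(TIFF_TAGS[["strip_bytes"]], 4L, 1L, length(data)),
    u32(0L)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), u16(42L), u32(ifd_offset)), con)
  writeBin(data, con)
  writeBin(ifd, con)
  invisible(path)
}

#' Read a grayscale TIFF written by [write_gray_tiff()]
#'
#' Supports uncompressed single-sample baseline TIFFs (8/16-bit, single or
#' multiple strips, either byte order).
#'
#' @param path TIFF file path.
#' @return Numeric matrix with attribute `bit_depth`.
#' @export
read_gray_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8) abort(paste0("Not a TIFF file: ", path))
  order <- rawToChar(raw[1:2])
  le <- identical(order, "II")
  if (!le && !identical(order, "MM")) abort(paste0("Not a TIFF file: ", path))
  rd_int <- function(bytes) {
    b <- as.integer(bytes)
    if (!le) b <- rev(b)
    sum(b * 256^(seq_along(b) - 1))
  }
  if (rd_int(raw[3:4]) != 42L) abort(paste0("Not a TIFF file: ", path))
  ifd_off <- rd_int(raw[5:8])
  n_entries <- rd_int(raw[ifd_off + 1:2])
  tags <- list()
  type_size <- c(`1` = 1L, `3` = 2L, `4` = 4L)
  for (e in seq_len(n_entries)) {
    base <- ifd_off + 2L + (e - 1L) * 12L
    tag <- rd_int(raw[base + 1:2])
    type <- rd_int(raw[base + 3:4])
    count <- rd_int(raw[base + 5:8])
    sz <- type_size[as.character(type)]
    if (is.na(sz)) next
    if (sz * count <= 4L) {
      vals <- vapply(seq_len(count), function(i) {
        rd_int(raw[base + 8L + (i - 1L) * sz + 1:sz])
      }, numeric(1))
    } else {
      off <- rd_int(raw[base + 9:12])
      vals <- vapply(seq_len(count), function(i) {
        rd_int(raw[off + (i - 1L) * sz + 1:sz])
      }, numeric(1))
    }
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) abort(paste0("Malformed TIFF (missing tag ", tag, "): ", path))
    v
  }
  nc <- need(TIFF_TAGS[["width"]]); nr <- need(TIFF_TAGS[["length"]])
  bits <- need(TIFF_TAGS[["bits"]])[1]
  comp <- tags[[as.character(TIFF_TAGS[["compression"]])]]
  if (!is.null(comp) && comp[1] != 1) {
    abort(paste0("Unsupported TIFF compression (", comp[1], "): ", path))
  }
  if (!bits %in% c(8, 16)) {
    abort(paste0("Unsupported TIFF bit depth (", bits, "): ", path))
  }
  offsets <- need(TIFF_TAGS[["strip_offsets"]])
  counts <- need(TIFF_TAGS[["strip_bytes"]])
  data <- raw[unlist(Map(function(o, n) o + seq_len(n), offsets, counts))]
  if (length(data) * 8L < nr * nc * bits) {
    abort(paste0("Malformed TIFF (truncated pixel data): ", path))
  }
  if (bits == 8) {
    px <- as.integer(data)
  } else {
    b <- matrix(as.integer(data), nrow = 2L)
    px <- if (le) b[1, ] + 256L * b[2, ] else b[2, ] + 256L * b[1, ]
  }
  out <- matrix(px[seq_len(nr * nc)], nrow = nr, ncol = nc, byrow = TRUE)
  attr(out, "bit_depth") <- as.integer(bits)
  out
}
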