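# Minimal self-contained raster codecs.  PNG (8-bit grayscale/RGB, the
# subset every mask/image in the Kvasir-style layout needs) is implemented on
# top of base R's zlib bindings so the package reads and writes its own
# datasets with no external imaging dependency; uncompressed baseline TIFF
# covers the mask format of CVC-ClinicDB-style datasets.  JPEG input/output
# is delegated to the optional 'jpeg' package when it is installed.

u32be <- function(n) {
  n <- as.double(n)
  as.raw(c(n %/% 16777216, (n %/% 65536) %% 256, (n %/% 256) %% 256, n %% 256))
}

be_to_num <- function(bytes) sum(as.double(bytes) * 256^((length(bytes) - 1):0))

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- cpp_crc32(body)
  c(u32be(length(data)), body, u32be(crc))
}

# Coerce an image to an integer 0..255 array with explicit channel dim.
to_uint8 <- function(img) {
  if (is.matrix(img)) dim(img) <- c(dim(img), 1L)
  if (length(dim(img)) != 3L) stop_data("image must be HxW or HxWxC")
  v <- as.double(img)
  if (max(v, na.rm = TRUE) <= 1 && !is.integer(img)) v <- v * 255
  arr <- array(as.integer(pmin(pmax(round(v), 0), 255)), dim = dim(img))
  arr
}

#' Write an 8-bit PNG image
#'
#' @param img numeric array `HxW` or `HxWx{1,3}`; values in `[0,1]` are scaled
#'   to 0-255, anything else is treated as already being on the 8-bit scale.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_png <- function(img, path) {
  arr <- to_uint8(img)
  h <- dim(arr)[1]; w <- dim(arr)[2]; ch <- dim(arr)[3]
  if (!ch %in% c(1L, 3L)) stop_data("PNG writer supports 1 or 3 channels")
  colour_type <- if (ch == 1L) 0L else 2L
  ihdr <- c(u32be(w), u32be(h), as.raw(8L), as.raw(colour_type),
            as.raw(0L), as.raw(0L), as.raw(0L))
  # scanlines: filter byte 0 followed by interleaved samples, top row first
  samples <- as.raw(aperm(arr, c(3, 2, 1)))
  m <- matrix(samples, nrow = ch * w, ncol = h)
  raw_rows <- as.raw(rbind(as.raw(0L), m))
  idat <- memCompress(raw_rows, type = "gzip")  # zlib stream (RFC 1950)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)), con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", idat), con)
  writeBin(png_chunk("IEND", raw(0)), con)
  invisible(path)
}

#' Read an 8-bit PNG image
#'
#' Supports non-interlaced 8-bit grayscale, RGB, and their alpha variants
#' (alpha is dropped).  All five PNG scanline filters are handled.
#'
#' @param path PNG file path.
#' @return integer array `HxWxC` (C = 1 or 3) with values 0-255.
#' @export
read_png <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
  if (length(bytes) < 8 || !identical(bytes[1:8], sig))
    stop_data("not a PNG file: %s", path)
  pos <- 9L
  idat <- list(); ihdr <- NULL
  while (pos + 8 <= length(bytes)) {
    len <- be_to_num(bytes[pos:(pos + 3)])
    type <- rawToChar(bytes[(pos + 4):(pos + 7)])
    data <- if (len > 0) bytes[(pos + 8):(pos + 7 + len)] else raw(0)
    if (type == "IHDR") ihdr <- data
    else if (type == "IDAT") idat[[length(idat) + 1L]] <- data
    else if (type == "IEND") break
    pos <- pos + 12L + len
  }
  if (is.null(ihdr) || !length(idat)) stop_data("corrupt PNG file: %s", path)
  w <- as.integer(be_to_num(ihdr[1:4])); h <- as.integer(be_to_num(ihdr[5:8]))
  bitdepth <- as.integer(ihdr[9]); colour <- as.integer(ihdr[10])
  interlace <- as.integer(ihdr[13])
  if (bitdepth != 8L) stop_data("unsupported PNG bit depth %d in %s", bitdepth, path)
  if (interlace != 0L) stop_data("interlaced PNG not supported: %s", path)
  ch <- switch(as.character(colour), "0" = 1L, "2" = 3L, "4" = 2L, "6" = 4L,
               stop_data("unsupported PNG colour type %d in %s", colour, path))
  inflated <- memDecompress(do.call(c, idat), type = "gzip")
  samples <- cpp_png_unfilter(inflated, h, w * ch, ch)
  arr <- aperm(array(as.integer(samples), dim = c(ch, w, h)), c(3, 2, 1))
  if (ch == 2L) arr <- arr[, , 1L, drop = FALSE]
  if (ch == 4L) arr <- arr[, , 1:3, drop = FALSE]
  arr
}

le_bytes <- function(n, width) {
  n <- as.double(n)
  as.raw(vapply(seq_len(width) - 1L, function(i) (n %/% 256^i) %% 256, 0))
}

tiff_entry <- function(tag, type, count, value_raw) {
  v <- value_raw
  length(v) <- 4L
  v[is.na(v)] <- as.raw(0L)
  c(le_bytes(tag, 2), le_bytes(type, 2), le_bytes(count, 4), v)
}

#' Write an uncompressed baseline TIFF image
#'
#' @inheritParams write_png
#' @return `path`, invisibly.
#' @export
write_tiff <- function(img, path) {
  arr <- to_uint8(img)
  h <- dim(arr)[1]; w <- dim(arr)[2]; ch <- dim(arr)[3]
  if (!ch %in% c(1L, 3L)) stop_data("TIFF writer supports 1 or 3 channels")
  data <- as.raw(aperm(arr, c(3, 2, 1)))
  data_off <- 8L
  bits_off <- data_off + length(data)
  bits_extra <- if (ch == 3L) c(le_bytes(8, 2), le_bytes(8, 2), le_bytes(8, 2)) else raw(0)
  ifd_off <- bits_off + length(bits_extra)
  bits_value <- if (ch == 3L) le_bytes(bits_off, 4) else le_bytes(8, 2)
  entries <- list(
    tiff_entry(256, 4, 1, le_bytes(w, 4)),
    tiff_entry(257, 4, 1, le_bytes(h, 4)),
    tiff_entry(258, 3, ch, bits_value),
    tiff_entry(259, 3, 1, le_bytes(1, 2)),
    tiff_entry(262, 3, 1, le_bytes(if (ch == 3L) 2 else 1, 2)),
    tiff_entry(273, 4, 1, le_bytes(data_off, 4)),
    tiff_entry(277, 3, 1, le_bytes(ch, 2)),
    tiff_entry(278, 4, 1, le_bytes(h, 4)),
    tiff_entry(279, 4, 1, le_bytes(length(data), 4)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), le_bytes(42, 2), le_bytes(ifd_off, 4)), con)
  writeBin(data, con)
  writeBin(bits_extra, con)
  writeBin(c(le_bytes(length(entries), 2), do.call(c, entries), le_bytes(0, 4)), con)
  invisible(path)
}

#' Read an uncompressed baseline TIFF image
#'
#' Handles 8-bit grayscale and RGB, either byte order, single or multiple
#' strips, chunky planar layout.
#'
#' @param path TIFF file path.
#' @return integer array `HxWxC` (C = 1 or 3) with values 0-255.
#' @export
read_tiff <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) < 8) stop_data("not a TIFF file: %s", path)
  order <- rawToChar(bytes[1:2])
  if (!order %in% c("II", "MM")) stop_data("not a TIFF file: %s", path)
  le <- order == "II"
  num <- function(idx) {
    b <- as.double(bytes[idx])
    if (le) sum(b * 256^(seq_along(b) - 1)) else sum(b * 256^(rev(seq_along(b)) - 1))
  }
  ifd <- num(5:8)
  n_entries <- num(ifd + (1:2))
  tags <- list()
  for (e in seq_len(n_entries)) {
    base <- ifd + 2 + (e - 1) * 12
    tag <- num(base + (1:2)); type <- num(base + (3:4)); count <- num(base + (5:8))
    size <- c(1, 1, 2, 4, 8)[type]
    total <- size * count
    val_idx <- if (total <= 4) base + (9:(8 + total)) else {
      off <- num(base + (9:12)); (off + 1):(off + total)
    }
    vals <- if (type %in% c(3, 4)) {
      vapply(seq_len(count), function(i) num(val_idx[((i - 1) * size + 1):(i * size)]), 0)
    } else num(val_idx[1:min(4, total)])
    tags[[as.character(tag)]] <- vals
  }
  g <- function(tag, default = NULL) tags[[as.character(tag)]] %||% default
  w <- g(256); h <- g(257); ch <- g(277, 1)
  if (is.null(w) || is.null(h)) stop_data("corrupt TIFF file: %s", path)
  if (!identical(g(259, 1), 1)) stop_data("compressed TIFF not supported: %s", path)
  bits <- g(258, 8)
  if (any(bits != 8)) stop_data("unsupported TIFF bit depth in %s", path)
  if (!ch %in% c(1, 3)) stop_data("unsupported TIFF sample count %d in %s", ch, path)
  offs <- g(273); counts <- g(279)
  data <- do.call(c, lapply(seq_along(offs), function(i)
    bytes[(offs[i] + 1):(offs[i] + counts[i])]))
  if (length(data) < w * h * ch) stop_data("truncated TIFF data in %s", path)
  aperm(array(as.integer(data[seq_len(w * h * ch)]), dim = c(ch, w, h)), c(3, 2, 1))
}

#' Read a raster image, dispatching on the file's magic bytes
#'
#' PNG and uncompressed TIFF are read by the built-in codecs; JPEG requires
#' the optional 'jpeg' package.
#'
#' @param path image file path.
#' @return integer array `HxWxC` (C = 1 or 3), values 0-255.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_data("cannot read image, no such file: %s", path)
  magic <- readBin(path, "raw", 4)
  if (length(magic) >= 2 && magic[1] == as.raw(0x89)) return(read_png(path))
  if (rawToChar(magic[1:2]) %in% c("II", "MM")) return(read_tiff(path))
  if (magic[1] == as.raw(0xff) && magic[2] == as.raw(0xd8)) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      stop_data("JPEG support requires the 'jpeg' package: %s", path)
    img <- jpeg::readJPEG(path)
    return(to_uint8(img))
  }
  stop_data("unreadable or unsupported image file: %s", path)
}

#' Write a raster image, dispatching on the file extension
#'
#' `.png` uses the built-in PNG writer, `.tif`/`.tiff` the built-in TIFF
#' writer, `.jpg`/`.jpeg` the optional 'jpeg' package.
#'
#' @inheritParams write_png
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = write_png(img, path),
    tif = , tiff = write_tiff(img, path),
    jpg = , jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop_data("JPEG support requires the 'jpeg' package")
      arr <- to_uint8(img)
      if (dim(arr)[3] == 1L) dim(arr) <- dim(arr)[1:2]
      jpeg::writeJPEG(arr / 255, target = path, quality = 0.95)
      invisible(path)
    },
    stop_data("unsupported image extension '%s'", ext))
}
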