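# 16-bit grayscale PNG I/O for depth frames.
#
# Depth frames are stored as 16-bit grayscale PNGs, pixel value = distance
# in millimeters, 0 = invalid/no return. Reading goes through png::readPNG
# (which preserves 16-bit precision); writing uses a minimal encoder here
# because the installed PNG writers only emit 8-bit channels. The encoder
# emits the standard chunk sequence IHDR / IDAT (filter type 0 scanlines,
# zlib-compressed) / IEND.

int_to_be <- function(x, nbytes = 4L) {
  x <- as.numeric(x)
  out <- raw(nbytes)
  for (i in seq_len(nbytes)) {
    out[nbytes - i + 1L] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(int_to_be(length(data)), body, int_to_be(.crc32_bytes(body)))
}

# mat: integer matrix (rows = image rows top-down), values 0..65535
write_depth_png <- function(mat, path) {
  stopifnot(is.matrix(mat))
  h <- nrow(mat); w <- ncol(mat)
  v <- as.integer(t(mat))              # row-major scan order
  if (anyNA(v) || any(v < 0L) || any(v > 65535L))
    stop("depth values must be integers in [0, 65535]", call. = FALSE)
  hi <- as.raw(v %/% 256L)
  lo <- as.raw(v %% 256L)
  pix <- as.vector(rbind(hi, lo))      # big-endian 16-bit samples
  scan <- rbind(as.raw(0L), matrix(pix, nrow = 2L * w))  # filter byte 0
  ihdr <- c(int_to_be(w), int_to_be(h),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # bit depth 16, grayscale
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", .zlib_deflate(as.vector(scan), 6L)),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

# returns integer matrix in millimeters; errors unless the file is a
# 16-bit grayscale PNG
read_depth_png <- function(path) {
  img <- png::readPNG(path, info = TRUE)
  info <- attr(img, "info")
  if (is.null(info) || !identical(as.integer(info$bit.depth), 16L))
    stop(sprintf("depth frame %s: bit depth %s, expected 16",
                 basename(path), info$bit.depth %||% "unknown"), call. = FALSE)
  if (length(dim(img)) != 2L)
    stop(sprintf("depth frame %s: expected grayscale, got %d channels",
                 basename(path), dim(img)[3]), call. = FALSE)
  m <- round(img * 65535)
  storage.mode(m) <- "integer"
  attr(m, "info") <- NULL
  m
}
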