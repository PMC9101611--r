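# Minimal uncompressed BMP codec. No BMP reader ships with the available R
# stack, and 8-bit grayscale bitmaps are the working format of this analysis,
# so the two variants that occur in practice are handled here: 8-bit paletted
# and 24-bit BGR, both BI_RGB (compression 0), bottom-up or top-down row order.

read_u16 <- function(con) readBin(con, "integer", 1L, size = 2L, endian = "little", signed = FALSE)
read_u32 <- function(con) {
  # BMP offsets fit comfortably in a double; avoid signed 32-bit overflow
  b <- as.integer(readBin(con, "raw", 4L))
  b[1] + b[2] * 256 + b[3] * 65536 + b[4] * 16777216
}
read_s32 <- function(con) readBin(con, "integer", 1L, size = 4L, endian = "little")

# Returns an integer matrix in [0,255] (rows top-down).
read_bmp <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2L)
  if (!identical(as.integer(magic), c(0x42L, 0x4DL)))
    stop(sprintf("cannot read BMP '%s': bad signature", path))
  read_u32(con)                      # file size
  readBin(con, "raw", 4L)            # reserved
  data_offset <- read_u32(con)
  header_size <- read_u32(con)
  if (header_size < 40)
    stop(sprintf("cannot read BMP '%s': unsupported header (size %d)", path, header_size))
  width <- read_s32(con)
  height <- read_s32(con)            # negative => top-down
  read_u16(con)                      # planes
  bpp <- read_u16(con)
  compression <- read_u32(con)
  if (compression != 0)
    stop(sprintf("cannot read BMP '%s': only uncompressed (BI_RGB) supported", path))
  if (!bpp %in% c(8L, 24L))
    stop(sprintf("unsupported bit depth (%d bpp) in '%s'; expected 8 or 24", bpp, path))
  top_down <- height < 0
  height <- abs(height)
  read_u32(con); read_s32(con); read_s32(con)  # image size, x/y ppm
  colors_used <- read_u32(con)
  read_u32(con)                      # important colors
  # skip any extended header bytes
  if (header_size > 40) readBin(con, "raw", header_size - 40)

  palette <- NULL
  if (bpp == 8L) {
    n_pal <- if (colors_used > 0) colors_used else 256
    pal_raw <- readBin(con, "raw", n_pal * 4L)
    pm <- matrix(as.integer(pal_raw), nrow = 4L)  # B, G, R, reserved
    palette <- if (all(pm[1, ] == pm[2, ]) && all(pm[2, ] == pm[3, ])) {
      pm[1, ]
    } else {
      w <- luminance_weights("bt709")
      round_half_up(w[1] * pm[3, ] + w[2] * pm[2, ] + w[3] * pm[1, ])
    }
  }

  seek(con, data_offset)
  bytes_per_row <- if (bpp == 8L) width else 3L * width
  stride <- 4L * ((bytes_per_row + 3L) %/% 4L)
  raw_rows <- readBin(con, "raw", stride * height)
  if (length(raw_rows) < stride * height)
    stop(sprintf("cannot read BMP '%s': truncated pixel data", path))
  rows <- matrix(as.integer(raw_rows), nrow = stride)[seq_len(bytes_per_row), , drop = FALSE]

  px <- if (bpp == 8L) {
    matrix(palette[rows + 1L], nrow = width, ncol = height)
  } else {
    b <- rows[seq(1L, bytes_per_row, by = 3L), , drop = FALSE]
    g <- rows[seq(2L, bytes_per_row, by = 3L), , drop = FALSE]
    r <- rows[seq(3L, bytes_per_row, by = 3L), , drop = FALSE]
    if (all(r == g) && all(g == b)) {
      matrix(r, nrow = width, ncol = height)
    } else {
      w <- luminance_weights("bt709")
      matrix(round_half_up(w[1] * r + w[2] * g + w[3] * b), nrow = width, ncol = height)
    }
  }
  m <- t(px)                         # rows of the file, bottom-up unless top_down
  if (!top_down) m <- m[rev(seq_len(height)), , drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

write_u16 <- function(con, x) writeBin(as.integer(x), con, size = 2L, endian = "little")
write_u32 <- function(con, x) {
  x <- as.numeric(x)
  b <- as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
  writeBin(b, con)
}

# Writes an 8-bit paletted grayscale BMP (identity palette), bottom-up.
write_bmp <- function(pixels, path) {
  stopifnot(is.matrix(pixels))
  h <- nrow(pixels); w <- ncol(pixels)
  stride <- 4L * ((w + 3L) %/% 4L)
  data_offset <- 14L + 40L + 256L * 4L
  file_size <- data_offset + stride * h
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x42, 0x4D)), con)             # 'BM'
  write_u32(con, file_size)
  write_u32(con, 0)
  write_u32(con, data_offset)
  write_u32(con, 40)                               # BITMAPINFOHEADER
  writeBin(as.integer(w), con, size = 4L, endian = "little")
  writeBin(as.integer(h), con, size = 4L, endian = "little")
  write_u16(con, 1); write_u16(con, 8)             # planes, bpp
  write_u32(con, 0)                                # BI_RGB
  write_u32(con, stride * h)
  write_u32(con, 2835); write_u32(con, 2835)       # 72 dpi
  write_u32(con, 256); write_u32(con, 0)
  pal <- as.raw(rbind(0:255, 0:255, 0:255, rep(0L, 256)))  # B,G,R,0
  writeBin(pal, con)
  pad <- raw(stride - w)
  for (r in rev(seq_len(h)))                       # bottom-up
    writeBin(c(as.raw(pixels[r, ]), pad), con)
  invisible(path)
}
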