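# Raster loading, grayscale conversion, ROI extraction.

#' In-memory 8-bit grayscale image
#'
#' Light container for a 2-D integer intensity raster plus provenance. All
#' pixel values are integers in \[0, 255\]; the matrix is indexed
#' \code{pixels[row, col]} with row 1 at the top of the image.
#'
#' @param pixels numeric or integer matrix of intensities in \[0, 255\].
#' @param source_id free-text identifier carried through the pipeline.
#' @param lighting `"polarized"` or `"nonpolarized"`.
#' @return An object of class `gray_image` with fields `pixels`, `width`,
#'   `height`, `source_id` and `lighting`.
#' @export
gray_image <- function(pixels, source_id = "", lighting = c("polarized", "nonpolarized")) {
  lighting <- match.arg(lighting)
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("gray_image: pixel matrix must be at least 1x1")
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255))
    stop("gray_image: intensities must lie in [0, 255]")
  if (any(pixels != round(pixels)))
    stop("gray_image: intensities must be integers (8-bit)")
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, width = ncol(pixels), height = nrow(pixels),
         source_id = as.character(source_id), lighting = lighting),
    class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %dx%d (h x w), lighting=%s, source_id='%s'\n",
              x$height, x$width, x$lighting, x$source_id))
  invisible(x)
}

# Luminance weights used to collapse RGB to one channel. The study converted
# images in an external editor without stating the formula, so the weights are
# explicit and configurable here.
luminance_weights <- function(colorimetry = c("bt709", "bt601")) {
  colorimetry <- match.arg(colorimetry)
  switch(colorimetry,
         bt709 = c(0.2126, 0.7152, 0.0722),
         bt601 = c(0.299, 0.587, 0.114))
}

# round-half-up on the 0..255 scale (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

# Map a [0,1]-scaled channel array back to exact 8-bit integers; values that
# are not multiples of 1/255 indicate a deeper bit depth we do not handle.
as_8bit <- function(x, path) {
  v <- x * 255
  if (max(abs(v - round(v))) > 1e-6)
    stop(sprintf("unsupported bit depth (> 8 bits per channel) in '%s'", path))
  round(v)
}

#' Load a raster image as 8-bit grayscale
#'
#' Reads PNG, JPEG or uncompressed BMP rasters. RGB inputs are collapsed to
#' one channel by fixed luminance weighting (ITU-R BT.709 by default, with
#' round-half-up); images that are already single-channel 8-bit pass through
#' unchanged. JPEG input is accepted with a warning: lossy compression
#' artifacts perturb texture features, so lossless formats are recommended.
#' TIFF is not supported in this build (no reader available).
#'
#' @param path path to a PNG/JPEG/BMP file.
#' @param lighting lighting mode recorded in the provenance,
#'   `"polarized"` or `"nonpolarized"`.
#' @param source_id identifier for the image; defaults to the file name.
#' @param colorimetry luminance weights for RGB inputs, `"bt709"` (default)
#'   or `"bt601"`.
#' @return A [gray_image()].
#' @export
load_image <- function(path, lighting = c("polarized", "nonpolarized"),
                       source_id = NULL,
                       colorimetry = c("bt709", "bt601")) {
  lighting <- match.arg(lighting)
  colorimetry <- match.arg(colorimetry)
  if (!file.exists(path))
    stop(sprintf("cannot read image '%s': no such file", path))
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = tryCatch(png::readPNG(path),
                   error = function(e) stop(sprintf("cannot read PNG '%s': %s", path, conditionMessage(e)))),
    jpg = ,
    jpeg = {
      warning(sprintf("'%s' is JPEG: lossy artifacts can perturb texture features; prefer PNG/BMP", path))
      tryCatch(jpeg::readJPEG(path),
               error = function(e) stop(sprintf("cannot read JPEG '%s': %s", path, conditionMessage(e))))
    },
    bmp = read_bmp(path) / 255,
    tif = ,
    tiff = stop(sprintf("TIFF is not supported in this build: '%s'; convert to PNG or BMP", path)),
    stop(sprintf("unsupported image format '.%s' for '%s'", ext, path))
  )
  px <- collapse_to_gray(arr, path, colorimetry)
  gray_image(px, source_id = if (is.null(source_id)) basename(path) else source_id,
             lighting = lighting)
}

# arr: matrix (grayscale) or H x W x C array in [0,1]
collapse_to_gray <- function(arr, path, colorimetry) {
  if (is.matrix(arr)) return(as_8bit(arr, path))
  d <- dim(arr)
  if (length(d) != 3L)
    stop(sprintf("unsupported raster layout in '%s'", path))
  ch <- lapply(seq_len(d[3]), function(k) as_8bit(arr[, , k], path))
  if (d[3] %in% c(2L, 4L)) ch <- ch[-length(ch)]  # drop alpha
  if (length(ch) == 1L) return(ch[[1]])
  if (length(ch) != 3L)
    stop(sprintf("unsupported channel count (%d) in '%s'", d[3], path))
  if (identical(ch[[1]], ch[[2]]) && identical(ch[[2]], ch[[3]])) return(ch[[1]])
  w <- luminance_weights(colorimetry)
  round_half_up(w[1] * ch[[1]] + w[2] * ch[[2]] + w[3] * ch[[3]])
}

#' Write a grayscale image to disk
#'
#' PNG (via the png package) and uncompressed 8-bit BMP are supported; both
#' round-trip the pixel array bit-exactly through [load_image()].
#'
#' @param image a [gray_image()] or an integer matrix in \[0, 255\].
#' @param path destination; format chosen by extension (`.png` or `.bmp`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  px <- if (inherits(image, "gray_image")) image$pixels else {
    gray_image(image)$pixels
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(px / 255, target = path),
    bmp = write_bmp(px, path),
    stop(sprintf("unsupported output format '.%s' (use .png or .bmp)", ext)))
  invisible(path)
}

#' Extract a square region of interest
#'
#' Copies a `side` x `side` window out of a grayscale image. Coordinates are
#' 0-based `(row, col)` offsets of the window's top-left corner; the window is
#' half-open, covering rows `row .. row+side-1`.
#'
#' @param image a [gray_image()].
#' @param origin integer vector `c(row, col)`, 0-based.
#' @param side window side in pixels (default 450, the working ROI size).
#' @param group_label lesion class: `"BN"`, `"DN"`, `"MM"` or `"unknown"`.
#' @param roi_id identifier for this ROI; autogenerated when `NULL`.
#' @return An object of class `lesion_roi`: fields `pixels`, `side`, `origin`,
#'   `source_id`, `lighting`, `group_label`, `roi_id`.
#' @export
extract_roi <- function(image, origin, side = 450L,
                        group_label = c("unknown", "BN", "DN", "MM"),
                        roi_id = NULL) {
  stopifnot(inherits(image, "gray_image"))
  group_label <- match.arg(group_label)
  side <- as.integer(side)
  origin <- as.integer(origin)
  if (length(origin) != 2L || anyNA(origin))
    stop("origin must be an integer vector c(row, col)")
  if (side <= 0L) stop("side must be positive")
  r0 <- origin[1]; c0 <- origin[2]
  if (r0 < 0L || c0 < 0L || r0 + side > image$height || c0 + side > image$width)
    stop(sprintf(
      "ROI window out of bounds: origin=(%d,%d), side=%d, image is %dx%d (h x w)",
      r0, c0, side, image$height, image$width))
  px <- image$pixels[(r0 + 1L):(r0 + side), (c0 + 1L):(c0 + side), drop = FALSE]
  if (is.null(roi_id))
    roi_id <- sprintf("%s_r%d_c%d_s%d", image$source_id, r0, c0, side)
  structure(
    list(pixels = px, side = side, origin = c(row = r0, col = c0),
         source_id = image$source_id, lighting = image$lighting,
         group_label = group_label, roi_id = roi_id),
    class = "lesion_roi")
}

#' @export
print.lesion_roi <- function(x, ...) {
  cat(sprintf("<lesion_roi> %dx%d at (%d,%d) of '%s', %s, group=%s\n",
              x$side, x$side, x$origin[["row"]], x$origin[["col"]],
              x$source_id, x$lighting, x$group_label))
  invisible(x)
}

#' Uniform grid of ROI origins
#'
#' Helper for tiling an image with non-overlapping (or strided) ROI windows.
#' ROI placement inside the lesion border is a judgement call made upstream;
#' this helper only enumerates geometrically valid origins.
#'
#' @param image a [gray_image()].
#' @param side ROI side in pixels.
#' @param step stride between window origins; defaults to `side`
#'   (non-overlapping tiling).
#' @return data.frame with 0-based columns `roi_row`, `roi_col`.
#' @export
tile_roi_origins <- function(image, side = 450L, step = side) {
  stopifnot(inherits(image, "gray_image"))
  side <- as.integer(side); step <- as.integer(step)
  if (side > image$height || side > image$width)
    return(data.frame(roi_row = integer(0), roi_col = integer(0)))
  rows <- seq.int(0L, image$height - side, by = step)
  cols <- seq.int(0L, image$width - side, by = step)
  expand.grid(roi_row = rows, roi_col = cols, KEEP.OUT.ATTRS = FALSE)
}

roi_metadata_columns <- c("source_path", "source_id", "lighting",
                          "group_label", "roi_row", "roi_col", "roi_side")

#' Read an ROI metadata table
#'
#' The metadata CSV names each ROI window: columns `source_path`, `source_id`,
#' `lighting` (polarized/nonpolarized), `group_label` (BN/DN/MM/unknown),
#' `roi_row`, `roi_col` (0-based origin) and `roi_side`.
#'
#' @param path CSV file path.
#' @return data.frame with the validated columns.
#' @export
read_roi_metadata <- function(path) {
  if (!file.exists(path))
    stop(sprintf("metadata CSV '%s' does not exist", path))
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(roi_metadata_columns, names(md))
  if (length(missing))
    stop(sprintf("metadata CSV '%s' lacks column(s): %s",
                 path, paste(missing, collapse = ", ")))
  bad <- setdiff(unique(md$lighting), c("polarized", "nonpolarized"))
  if (length(bad))
    stop(sprintf("metadata CSV '%s': unknown lighting value(s): %s",
                 path, paste(bad, collapse = ", ")))
  bad <- setdiff(unique(md$group_label), c("BN", "DN", "MM", "unknown"))
  if (length(bad))
    stop(sprintf("metadata CSV '%s': unknown group_label value(s): %s",
                 path, paste(bad, collapse = ", ")))
  md
}

#' Load all ROIs named by a metadata table
#'
#' @param metadata data.frame from [read_roi_metadata()].
#' @param base_dir directory against which relative `source_path`s resolve.
#' @return list of `lesion_roi` objects, one per metadata row.
#' @export
load_rois <- function(metadata, base_dir = ".") {
  lapply(seq_len(nrow(metadata)), function(i) {
    row <- metadata[i, ]
    p <- row$source_path
    if (!file.exists(p)) p <- file.path(base_dir, row$source_path)
    img <- load_image(p, lighting = row$lighting, source_id = row$source_id)
    extract_roi(img, origin = c(row$roi_row, row$roi_col), side = row$roi_side,
                group_label = row$group_label,
                roi_id = sprintf("%s_r%d_c%d", row$source_id,
                                 as.integer(row$roi_row), as.integer(row$roi_col)))
  })
}
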