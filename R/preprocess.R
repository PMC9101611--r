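# Intensity normalization and gray-level quantization.

#' Normalize ROI intensities to the mean +/- 3 SD window and quantize
#'
#' Both texture matrices operate on a reduced-gray-level image. Raw 8-bit
#' intensities are windowed to \eqn{[\mu - 3\sigma, \mu + 3\sigma]}, where
#' \eqn{\mu} and \eqn{\sigma} are the mean and *population* standard deviation
#' of optical density over all ROI pixels, and then mapped linearly onto
#' `n_levels` gray levels:
#' \deqn{level(v) = clamp(1 + \lfloor (v - (\mu - 3\sigma)) / (6\sigma) \cdot N_g \rfloor,\ 1,\ N_g)}
#' Values at or below \eqn{\mu - 3\sigma} clamp to level 1, values at or above
#' \eqn{\mu + 3\sigma} clamp to level \eqn{N_g}. The window adapts per ROI, so
#' the mapping is invariant to affine intensity changes \eqn{a v + b}
#' (\eqn{a > 0}) except at exact quantization boundaries.
#'
#' A constant ROI (\eqn{\sigma = 0}) maps every pixel to the middle level
#' \eqn{round((N_g+1)/2)} (round half up), so constant images stay constant
#' after quantization.
#'
#' @param roi a [extract_roi()] result, a [gray_image()], or a plain numeric
#'   matrix of intensities.
#' @param n_levels number of gray levels \eqn{N_g} (default 64); must be >= 2.
#' @return An object of class `quantized_roi`: `levels` (integer matrix in
#'   `1..n_levels`), `n_levels`, `mu`, `sigma`, and provenance fields copied
#'   from the ROI (`roi_id`, `source_id`, `lighting`, `group_label`).
#' @export
normalize_and_quantize <- function(roi, n_levels = 64L) {
  n_levels <- as.integer(n_levels)
  if (is.na(n_levels) || n_levels < 2L)
    stop("n_levels must be an integer >= 2")
  prov <- list(roi_id = NA_character_, source_id = NA_character_,
               lighting = NA_character_, group_label = "unknown")
  if (inherits(roi, "lesion_roi")) {
    prov <- roi[c("roi_id", "source_id", "lighting", "group_label")]
    px <- roi$pixels
  } else if (inherits(roi, "gray_image")) {
    prov$source_id <- roi$source_id
    prov$lighting <- roi$lighting
    px <- roi$pixels
  } else {
    px <- as.matrix(roi)
  }
  if (length(px) == 0L) stop("empty ROI")
  v <- as.numeric(px)
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))    # population SD: a whole-ROI density statistic
  if (sigma == 0) {
    lev <- matrix(as.integer(floor((n_levels + 1) / 2 + 0.5)),
                  nrow = nrow(px), ncol = ncol(px))
  } else {
    lo <- mu - 3 * sigma
    lev <- 1L + floor((px - lo) / (6 * sigma) * n_levels)
    lev <- matrix(as.integer(pmin(pmax(lev, 1L), n_levels)),
                  nrow = nrow(px), ncol = ncol(px))
  }
  structure(
    c(list(levels = lev, n_levels = n_levels, side = nrow(px),
           mu = mu, sigma = sigma), prov),
    class = "quantized_roi")
}

#' @export
print.quantized_roi <- function(x, ...) {
  cat(sprintf("<quantized_roi> %dx%d, Ng=%d, mu=%.2f, sigma=%.2f, group=%s\n",
              nrow(x$levels), ncol(x$levels), x$n_levels, x$mu, x$sigma,
              x$group_label))
  invisible(x)
}

# Accept either a quantized_roi or something quantizable; used by the texture
# entry points so small matrices can be analyzed directly in examples/tests.
as_quantized <- function(q, n_levels = 64L) {
  if (inherits(q, "quantized_roi")) q else normalize_and_quantize(q, n_levels)
}
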