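# Synthetic lesion-like ROI textures: three classes x two lighting modes.
#
# The study's images are not publicly deposited, so this generator is the test
# substrate for the whole pipeline. A class preset is a *calibration
# artifact*: its values are frozen so that, at the study's group size
# (166 ROIs per class), the pipeline reproduces the published ordering and
# significance patterns. They are not biological claims.
#
# Texture model, per ROI:
#   1. white Gaussian noise smoothed at `correlation_length` (periodic
#      Gaussian kernel via FFT), standardized, scaled to a mid-gray band
#      (base_mean +/- base_sd) — the pigment/skin texture field;
#   2. `patch_count` random dark ellipses of one uniform intensity
#      (base_mean - patch_darkness) — homogeneous dark lesion areas, the
#      long-run signal;
#   3. non-polarized mode only: saturated bright glare blobs plus global
#      contrast compression toward mid-gray — surface reflection masking
#      subsurface structure;
#   4. i.i.d. Gaussian pixel noise (sd `noise_sd`), clamp to [0, 255], round.

#' Parameters of the synthetic ROI generator
#'
#' @param class_label `"BN"`, `"DN"` or `"MM"`.
#' @param lighting `"polarized"` or `"nonpolarized"`.
#' @param side ROI side in pixels (default 450, minimum 64).
#' @param correlation_length Gaussian smoothing scale (pixels) of the base
#'   random field; 0 leaves the field as white noise.
#' @param patch_count number of dark uniform ellipses.
#' @param patch_radius_range length-2 range (pixels) the two semi-axes of
#'   each ellipse are drawn from.
#' @param patch_darkness intensity drop of patches below `base_mean`
#'   (patch value is `base_mean - patch_darkness`, clamped at 0).
#' @param glare_count,glare_amplitude,glare_radius_range specular-highlight
#'   model, applied in non-polarized mode only: `glare_count` additive bright
#'   blobs of amplitude `glare_amplitude` with semi-axes from
#'   `glare_radius_range`.
#' @param contrast global contrast retained in non-polarized mode (1 = none
#'   lost); applied around mid-gray 128 after patches, before pixel noise.
#' @param noise_sd sd of the final i.i.d. Gaussian pixel noise (intensity
#'   units).
#' @param base_mean,base_sd intensity mean and sd of the base field band.
#' @param seed integer RNG seed; the generator is fully deterministic given
#'   the parameter set.
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(class_label = c("BN", "DN", "MM"),
                             lighting = c("polarized", "nonpolarized"),
                             side = 450L,
                             correlation_length = 2,
                             patch_count = 0L,
                             patch_radius_range = c(5, 12),
                             patch_darkness = 120,
                             glare_count = 0L,
                             glare_amplitude = 0,
                             glare_radius_range = c(8, 20),
                             contrast = 1,
                             noise_sd = 6,
                             base_mean = 150,
                             base_sd = 25,
                             seed = 1L) {
  class_label <- match.arg(class_label)
  lighting <- match.arg(lighting)
  side <- as.integer(side)
  if (side < 64L) stop("side must be >= 64")
  if (correlation_length < 0) stop("correlation_length must be >= 0")
  if (patch_count < 0) stop("patch_count must be >= 0")
  if (length(patch_radius_range) != 2L || any(patch_radius_range <= 0) ||
      diff(patch_radius_range) < 0)
    stop("patch_radius_range must be an increasing positive length-2 range")
  if (!(contrast > 0 && contrast <= 1)) stop("contrast must lie in (0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (base_mean < 0 || base_mean > 255 || base_sd < 0)
    stop("base_mean must lie in [0,255] and base_sd be >= 0")
  structure(
    list(class_label = class_label, lighting = lighting, side = side,
         correlation_length = correlation_length,
         patch_count = as.integer(patch_count),
         patch_radius_range = as.numeric(patch_radius_range),
         patch_darkness = patch_darkness,
         glare_count = as.integer(glare_count),
         glare_amplitude = glare_amplitude,
         glare_radius_range = as.numeric(glare_radius_range),
         contrast = contrast, noise_sd = noise_sd,
         base_mean = base_mean, base_sd = base_sd,
         seed = as.integer(seed)),
    class = "generator_params")
}

#' Frozen class presets
#'
#' Returns the calibrated [generator_params()] for one lesion class and
#' lighting mode. Polarized presets differ in the spatial correlation length
#' of the pigment field (the subsurface structure polarized light reveals)
#' and in the area of uniformly dark patches, both increasing from BN to DN
#' to MM. Non-polarized presets share one surface correlation length and one
#' expected dark-patch area; only the patch *granularity* differs (melanomas
#' carry few large black blotches, nevi many small dots), and saturated
#' glare plus contrast compression mask the rest — which is what makes
#' entropy and difference entropy uninformative in that mode.
#'
#' @inheritParams generator_params
#' @param seed RNG seed stored in the preset.
#' @return A `generator_params` object.
#' @export
lesion_preset <- function(class_label = c("BN", "DN", "MM"),
                          lighting = c("polarized", "nonpolarized"),
                          side = 450L, seed = 1L) {
  class_label <- match.arg(class_label)
  lighting <- match.arg(lighting)
  if (lighting == "polarized") {
    p <- switch(class_label,
      BN = list(correlation_length = 1.5, patch_count = 6L,
                patch_radius_range = c(3, 9), patch_darkness = 130),
      DN = list(correlation_length = 3.0, patch_count = 8L,
                patch_radius_range = c(5, 13), patch_darkness = 140),
      MM = list(correlation_length = 5.0, patch_count = 8L,
                patch_radius_range = c(9, 22), patch_darkness = 150))
    generator_params(class_label, lighting, side = side,
                     correlation_length = p$correlation_length,
                     patch_count = p$patch_count,
                     patch_radius_range = p$patch_radius_range,
                     patch_darkness = p$patch_darkness,
                     glare_count = 0L, glare_amplitude = 0,
                     contrast = 1, noise_sd = 6, seed = seed)
  } else {
    p <- switch(class_label,
      BN = list(correlation_length = 2.0, patch_count = 13L,
                patch_radius_range = c(5, 12)),
      DN = list(correlation_length = 2.0, patch_count = 13L,
                patch_radius_range = c(5, 12.1)),
      MM = list(correlation_length = 1.84, patch_count = 2L,
                patch_radius_range = c(12, 30)))
    generator_params(class_label, lighting, side = side,
                     correlation_length = p$correlation_length,
                     patch_count = p$patch_count,
                     patch_radius_range = p$patch_radius_range,
                     patch_darkness = 150,
                     glare_count = 4L, glare_amplitude = 200,
                     glare_radius_range = c(4, 32),
                     contrast = 0.75, noise_sd = 8, seed = seed)
  }
}

# Periodic Gaussian smoothing by FFT; kernel normalized to sum 1 so the
# field keeps its mean. Wrap-around at the borders is acceptable for a
# stationary texture model.
gaussian_smooth <- function(mat, ell) {
  if (ell <= 0) return(mat)
  n <- nrow(mat); m <- ncol(mat)
  dx <- 0:(n - 1); dx <- pmin(dx, n - dx)
  dy <- 0:(m - 1); dy <- pmin(dy, m - dy)
  k <- outer(exp(-dx^2 / (2 * ell^2)), exp(-dy^2 / (2 * ell^2)))
  k <- k / sum(k)
  Re(stats::fft(stats::fft(mat) * stats::fft(k), inverse = TRUE)) / (n * m)
}

# Adds `count` random ellipses to `img`: overwrite with `value` when
# value_mode = "set" (dark patches), or additive clamp-later bumps when
# value_mode = "add" (glare). Consumes 5 uniforms per ellipse.
stamp_ellipses <- function(img, count, radius_range, value, value_mode) {
  if (count < 1L) return(img)
  side_r <- nrow(img); side_c <- ncol(img)
  rows <- matrix(seq_len(side_r), side_r, side_c)
  cols <- matrix(seq_len(side_c), side_r, side_c, byrow = TRUE)
  for (i in seq_len(count)) {
    cy <- stats::runif(1, 1, side_r)
    cx <- stats::runif(1, 1, side_c)
    r1 <- stats::runif(1, radius_range[1], radius_range[2])
    r2 <- stats::runif(1, radius_range[1], radius_range[2])
    th <- stats::runif(1, 0, pi)
    dy <- rows - cy; dx <- cols - cx
    u <- (dx * cos(th) + dy * sin(th)) / r1
    v <- (-dx * sin(th) + dy * cos(th)) / r2
    inside <- (u * u + v * v) <= 1
    if (value_mode == "set") img[inside] <- value
    else img[inside] <- img[inside] + value
  }
  img
}

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Generate one synthetic lesion-like ROI
#'
#' Deterministic given the parameter set (including its `seed`); two calls
#' with the same params return bit-identical pixels.
#'
#' @param params a [generator_params()] (e.g. from [lesion_preset()]).
#' @param roi_id identifier for the ROI; autogenerated when `NULL`.
#' @return A `lesion_roi` (same class as [extract_roi()] returns) whose
#'   provenance records the class label and lighting mode.
#' @export
generate_roi <- function(params, roi_id = NULL) {
  stopifnot(inherits(params, "generator_params"))
  side <- params$side
  px <- with_local_seed(params$seed, {
    f <- matrix(stats::rnorm(side * side), side, side)
    f <- gaussian_smooth(f, params$correlation_length)
    f <- (f - mean(f)) / stats::sd(f)
    img <- params$base_mean + params$base_sd * f
    img <- stamp_ellipses(img, params$patch_count, params$patch_radius_range,
                          max(0, params$base_mean - params$patch_darkness),
                          "set")
    if (params$lighting == "nonpolarized") {
      img <- stamp_ellipses(img, params$glare_count, params$glare_radius_range,
                            params$glare_amplitude, "add")
      img <- 128 + (img - 128) * params$contrast
    }
    if (params$noise_sd > 0)
      img <- img + stats::rnorm(side * side, sd = params$noise_sd)
    round_half_up(pmin(pmax(img, 0), 255))
  })
  if (all(px == px[1]))
    warning("degenerate synthetic ROI: every pixel saturated to one value")
  if (is.null(roi_id))
    roi_id <- sprintf("synth_%s_%s_seed%d", params$class_label,
                      params$lighting, params$seed)
  px <- matrix(as.integer(px), side, side)
  structure(
    list(pixels = px, side = side, origin = c(row = 0L, col = 0L),
         source_id = roi_id, lighting = params$lighting,
         group_label = params$class_label, roi_id = roi_id),
    class = "lesion_roi")
}

# Hierarchical per-image seed: mixes base_seed with class, lighting and index
# so any single image (or group) can be regenerated without the whole cohort.
# Kept below 2^31 - 1; arithmetic stays exact in doubles.
derive_seed <- function(base_seed, ...) {
  h <- as.numeric(base_seed) %% 2147483647
  for (x in c(...)) h <- (h * 131 + as.numeric(x) + 17) %% 2147483647
  as.integer(h)
}

#' Generate a full synthetic cohort
#'
#' Produces `n_per_group` ROIs for each lesion class (BN, DN, MM) and each
#' requested lighting mode, using the frozen [lesion_preset()]s and
#' hierarchically derived per-image seeds, so the cohort is reproducible as
#' a whole and piecewise. The study-scale default is 166 ROIs per class per
#' mode.
#'
#' @param n_per_group ROIs per class per lighting mode.
#' @param lighting_modes subset of `c("polarized", "nonpolarized")`.
#' @param base_seed integer master seed.
#' @param out_dir when non-`NULL`, PNG images plus a `metadata.csv` in the
#'   ROI-metadata schema are written there and paths are returned; otherwise
#'   ROIs are returned in memory.
#' @param side ROI side in pixels.
#' @return When `out_dir` is `NULL`: list with `rois` (list of `lesion_roi`)
#'   and `metadata` (data.frame). Otherwise: list with `image_paths` and
#'   `metadata_path`.
#' @export
generate_cohort <- function(n_per_group = 166L,
                            lighting_modes = c("polarized", "nonpolarized"),
                            base_seed = 1L, out_dir = NULL, side = 450L) {
  n_per_group <- as.integer(n_per_group)
  if (n_per_group < 1L) stop("n_per_group must be >= 1")
  lighting_modes <- match.arg(lighting_modes, several.ok = TRUE)
  classes <- c("BN", "DN", "MM")
  rois <- list()
  meta <- list()
  for (li in seq_along(lighting_modes)) {
    lt <- lighting_modes[li]
    for (ci in seq_along(classes)) {
      cl <- classes[ci]
      for (i in seq_len(n_per_group)) {
        sd_i <- derive_seed(base_seed, ci, li, i)
        preset <- lesion_preset(cl, lt, side = side, seed = sd_i)
        id <- sprintf("synth_%s_%s_%03d", cl, lt, i)
        roi <- generate_roi(preset, roi_id = id)
        rois[[length(rois) + 1L]] <- roi
        meta[[length(meta) + 1L]] <- data.frame(
          source_path = paste0(id, ".png"), source_id = id, lighting = lt,
          group_label = cl, roi_row = 0L, roi_col = 0L, roi_side = side,
          stringsAsFactors = FALSE)
      }
    }
  }
  metadata <- do.call(rbind, meta)
  if (is.null(out_dir))
    return(list(rois = rois, metadata = metadata))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop(sprintf("cannot create output directory '%s'", out_dir))
  paths <- vapply(rois, function(r) {
    p <- file.path(out_dir, paste0(r$roi_id, ".png"))
    write_image(r$pixels, p)
    p
  }, "")
  metadata_path <- file.path(out_dir, "metadata.csv")
  utils::write.csv(metadata, metadata_path, row.names = FALSE)
  list(image_paths = paths, metadata_path = metadata_path)
}
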