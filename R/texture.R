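# Co-occurrence and run-length matrices and the five per-ROI statistics.

#' Gray-level co-occurrence matrix at a fixed displacement
#'
#' Counts every ordered pixel pair `(x, x + offset)` that falls inside the
#' image, in both orders (symmetric accumulation, the standard Haralick
#' convention), and normalizes the counts to a joint probability matrix
#' `p(i, j)` with `sum(p) == 1`. Symmetric accumulation makes
#' `p(i, j) == p(j, i)` and the sign of the offset irrelevant.
#'
#' @param q a `quantized_roi` (or a matrix, quantized on the fly with
#'   default settings).
#' @param offset integer `c(drow, dcol)` pixel displacement; must be nonzero
#'   and smaller than the image in magnitude. The working displacement of the
#'   analysis is distance 5: `(5,0)`, `(0,5)`, `(5,5)`, `(5,-5)`.
#' @return An object of class `glcm`: `p` (n_levels x n_levels probability
#'   matrix), `offset`, `n_levels`, `pair_count` (ordered pairs counted).
#' @export
compute_glcm <- function(q, offset) {
  q <- as_quantized(q)
  L <- q$levels
  ng <- q$n_levels
  dr <- as.integer(offset[1]); dc <- as.integer(offset[2])
  if (dr == 0L && dc == 0L) stop("offset must be nonzero")
  nr <- nrow(L); nc <- ncol(L)
  if (abs(dr) >= nr || abs(dc) >= nc)
    stop(sprintf("offset (%d,%d) leaves no valid pixel pair in a %dx%d image",
                 dr, dc, nr, nc))
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  a <- L[r1, c1, drop = FALSE]
  b <- L[r1 + dr, c1 + dc, drop = FALSE]
  counts <- tabulate((a - 1L) * ng + b, nbins = ng * ng)
  cm <- matrix(counts, nrow = ng, ncol = ng, byrow = TRUE)
  cm <- cm + t(cm)                        # both pair orders
  total <- sum(cm)
  structure(list(p = cm / total, offset = c(drow = dr, dcol = dc),
                 n_levels = ng, pair_count = total),
            class = "glcm")
}

check_glcm <- function(m) {
  if (!inherits(m, "glcm")) stop("expected a 'glcm' object")
  if (abs(sum(m$p) - 1) > 1e-8)
    stop("co-occurrence matrix is not normalized (sum(p) != 1)")
  invisible(m)
}

# -x log x with the 0 log 0 := 0 limit convention
xlogx_entropy <- function(p, log_base) {
  p <- p[p > 0]
  -sum(p * log(p)) / log(log_base)
}

#' Entropy of a co-occurrence matrix
#'
#' \eqn{-\sum_{i,j} p(i,j) \log p(i,j)}, with zero-probability cells
#' contributing 0. The logarithm is natural by default (values in nats);
#' `log_base = 10` switches to decimal digits — a global scale factor that
#' leaves all group orderings unchanged.
#'
#' @param m a `glcm` from [compute_glcm()].
#' @param log_base base of the logarithm (default `exp(1)`).
#' @return Nonnegative scalar entropy.
#' @export
glcm_entropy <- function(m, log_base = exp(1)) {
  check_glcm(m)
  xlogx_entropy(m$p, log_base)
}

#' Difference histogram of a co-occurrence matrix
#'
#' Marginal distribution \eqn{p_{x-y}} of the absolute gray-level difference:
#' \eqn{q(m) = \sum_{|i-j|=m} p(i,j)} for \eqn{m = 0..N_g-1}.
#'
#' @param m a `glcm`.
#' @return Numeric vector of length `n_levels`; element `m+1` is `q(m)`.
#' @export
difference_histogram <- function(m) {
  check_glcm(m)
  d <- as.integer(abs(row(m$p) - col(m$p)))
  sums <- rowsum(as.numeric(m$p), d)          # one row per observed |i-j|
  q <- numeric(m$n_levels)
  q[as.integer(rownames(sums)) + 1L] <- sums
  q
}

#' Difference entropy of a co-occurrence matrix
#'
#' Entropy of the difference histogram:
#' \eqn{-\sum_m p_{x-y}(m) \log p_{x-y}(m)}.
#'
#' @inheritParams glcm_entropy
#' @return Nonnegative scalar.
#' @export
glcm_difference_entropy <- function(m, log_base = exp(1)) {
  q <- difference_histogram(m)
  xlogx_entropy(q, log_base)
}

rlm_directions <- c("horizontal", "vertical", "diag45", "diag135")

#' Gray-level run-length matrix
#'
#' Decomposes every scan line of the image along one direction into maximal
#' runs of equal gray level and counts them: `r[i, k]` is the number of runs
#' of level `i` with length `k`. No run-length cap is applied
#' (`Nr = ROI side`): capping would silently truncate the long uniform runs
#' that carry the key signal of dark homogeneous lesion areas.
#'
#' Directions: `"horizontal"` (rows), `"vertical"` (columns), `"diag45"`
#' (anti-diagonals, 45 degrees) and `"diag135"` (main diagonals).
#'
#' @param q a `quantized_roi` (or matrix, quantized with defaults).
#' @param direction one of `"horizontal"`, `"vertical"`, `"diag45"`,
#'   `"diag135"`.
#' @return An object of class `rlm`: `r` (n_levels x Nr integer count matrix),
#'   `direction`, `n_levels`, `max_run_length`, `total_runs`.
#' @export
compute_rlm <- function(q, direction = rlm_directions) {
  q <- as_quantized(q)
  direction <- match.arg(direction)
  L <- q$levels
  ng <- q$n_levels
  nr_max <- max(nrow(L), ncol(L))
  lines <- switch(direction,
    horizontal = split(t(L), rep(seq_len(nrow(L)), each = ncol(L))),
    vertical   = split(L, rep(seq_len(ncol(L)), each = nrow(L))),
    diag45     = split(L, row(L) + col(L)),
    diag135    = split(L, col(L) - row(L)))
  vals <- vector("list", length(lines))
  lens <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    r <- rle(lines[[i]])
    vals[[i]] <- r$values
    lens[[i]] <- r$lengths
  }
  v <- unlist(vals, use.names = FALSE)
  k <- unlist(lens, use.names = FALSE)
  counts <- tabulate((k - 1L) * ng + v, nbins = ng * nr_max)
  rm <- matrix(counts, nrow = ng, ncol = nr_max)
  structure(list(r = rm, direction = direction, n_levels = ng,
                 max_run_length = nr_max, total_runs = sum(rm)),
            class = "rlm")
}

#' Long-run emphasis of a run-length matrix
#'
#' \deqn{LngREmph = \frac{\sum_{i,k} k^2\, r(i,k)}{\sum_{i,k} r(i,k)}}
#' The second-moment weighting makes the statistic large for images with
#' extended uniform regions; its minimum, 1, is attained when every run has
#' length 1 and its maximum is the squared line length.
#'
#' @param R an `rlm` from [compute_rlm()].
#' @return Scalar >= 1.
#' @export
long_run_emphasis <- function(R) {
  if (!inherits(R, "rlm")) stop("expected an 'rlm' object")
  if (R$total_runs == 0) stop("degenerate run-length matrix: no runs")
  k2 <- (seq_len(R$max_run_length))^2
  sum(colSums(R$r) * k2) / R$total_runs
}

#' Texture index and bone index
#'
#' The two indices divide a measure of structural diversity by the measure of
#' uniform longitudinal structure: `TI = Entropy / LngREmph` and
#' `BI = DifEntrp / LngREmph`. Low values flag images dominated by large
#' homogeneous (dark) areas rather than fine chaotic pattern.
#'
#' @param entropy co-occurrence entropy.
#' @param difentrp co-occurrence difference entropy.
#' @param lngremph long-run emphasis; must be >= 1.
#' @return Named list with elements `TI` and `BI`.
#' @export
compute_indices <- function(entropy, difentrp, lngremph) {
  if (!is.finite(lngremph) || lngremph < 1)
    stop("lngremph must be finite and >= 1")
  list(TI = entropy / lngremph, BI = difentrp / lngremph)
}

feature_names <- c("LngREmph", "Entropy", "DifEntrp", "TI", "BI")

#' Per-ROI texture feature vector
#'
#' Computes the five per-ROI statistics. Entropy and difference entropy are
#' evaluated on co-occurrence matrices at the four distance-`d` offsets
#' `(d,0)`, `(0,d)`, `(d,d)`, `(d,-d)` (Chebyshev distance `d` on the
#' diagonals); long-run emphasis is evaluated along the four run directions.
#' Each feature is then aggregated over directions by the arithmetic mean
#' (the default reducer), and TI and BI are derived from the aggregated
#' values — per ROI, never from group means.
#'
#' @param q a `quantized_roi`, or anything [normalize_and_quantize()] accepts
#'   (then quantized with `n_levels` levels).
#' @param distance pixel displacement of the co-occurrence pairs (default 5,
#'   the working distance of the analysis).
#' @param n_levels gray levels used if `q` still needs quantizing.
#' @param log_base entropy logarithm base (default natural).
#' @param reducer `"mean"` to aggregate over directions (default);
#'   `"max"`/`"min"` are available for sensitivity checks.
#' @return An object of class `feature_vector`: the five aggregated features,
#'   a `per_direction` data.frame of the directional values, and provenance.
#' @export
feature_vector <- function(q, distance = 5L, n_levels = 64L,
                           log_base = exp(1), reducer = c("mean", "max", "min")) {
  reducer <- match.arg(reducer)
  q <- as_quantized(q, n_levels)
  d <- as.integer(distance)
  if (d < 1L) stop("distance must be >= 1")
  offsets <- list(c(d, 0L), c(0L, d), c(d, d), c(d, -d))
  ent <- dif <- numeric(4)
  for (i in seq_along(offsets)) {
    m <- compute_glcm(q, offsets[[i]])
    ent[i] <- glcm_entropy(m, log_base)
    dif[i] <- glcm_difference_entropy(m, log_base)
  }
  lre <- vapply(rlm_directions,
                function(dir) long_run_emphasis(compute_rlm(q, dir)),
                numeric(1))
  agg <- switch(reducer, mean = mean, max = max, min = min)
  lngremph <- agg(lre)
  entropy <- agg(ent)
  difentrp <- agg(dif)
  idx <- compute_indices(entropy, difentrp, lngremph)
  per_dir <- data.frame(
    direction = rlm_directions,
    offset = vapply(offsets, function(o) sprintf("(%d,%d)", o[1], o[2]), ""),
    Entropy = ent, DifEntrp = dif, LngREmph = unname(lre))
  structure(
    list(LngREmph = lngremph, Entropy = entropy, DifEntrp = difentrp,
         TI = idx$TI, BI = idx$BI, per_direction = per_dir,
         roi_id = q$roi_id, source_id = q$source_id,
         lighting = q$lighting, group_label = q$group_label),
    class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %s [%s/%s]\n",
              if (is.na(x$roi_id)) "(unnamed ROI)" else x$roi_id,
              x$group_label, x$lighting))
  print(round(unlist(x[feature_names]), 4))
  invisible(x)
}

#' @export
as.data.frame.feature_vector <- function(x, ...) {
  data.frame(roi_id = x$roi_id, source_id = x$source_id,
             group_label = x$group_label, lighting = x$lighting,
             LngREmph = x$LngREmph, Entropy = x$Entropy,
             DifEntrp = x$DifEntrp, TI = x$TI, BI = x$BI,
             stringsAsFactors = FALSE)
}

#' Feature table for a set of ROIs
#'
#' Applies [normalize_and_quantize()] and [feature_vector()] to each ROI and
#' binds the results into the canonical feature table (one row per ROI,
#' columns `roi_id`, `source_id`, `group_label`, `lighting`, `LngREmph`,
#' `Entropy`, `DifEntrp`, `TI`, `BI`).
#'
#' @param rois list of `lesion_roi` objects (e.g. from [load_rois()] or
#'   [generate_cohort()]).
#' @inheritParams feature_vector
#' @return data.frame, one row per ROI.
#' @export
compute_features <- function(rois, distance = 5L, n_levels = 64L,
                             log_base = exp(1), reducer = "mean") {
  rows <- lapply(rois, function(r) {
    q <- normalize_and_quantize(r, n_levels)
    as.data.frame(feature_vector(q, distance = distance, log_base = log_base,
                                 reducer = reducer))
  })
  do.call(rbind, rows)
}
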