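# Independent brute-force oracles for the texture matrices and features.
# These deliberately use naive double loops so they share no code path with
# the vectorized implementations they check.

oracle_glcm <- function(levels, ng, offset) {
  cm <- matrix(0, ng, ng)
  dr <- offset[1]; dc <- offset[2]
  nr <- nrow(levels); nc <- ncol(levels)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
      i <- levels[r, c]; j <- levels[r2, c2]
      cm[i, j] <- cm[i, j] + 1   # ordered pair (x, x+o)
      cm[j, i] <- cm[j, i] + 1   # and its reverse
    }
  }
  cm / sum(cm)
}

oracle_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

oracle_difentrp <- function(p) {
  ng <- nrow(p)
  q <- numeric(ng)
  for (i in seq_len(ng)) for (j in seq_len(ng))
    q[abs(i - j) + 1] <- q[abs(i - j) + 1] + p[i, j]
  oracle_entropy(q)
}

# run scan of one vector, returning a two-column matrix (level, length)
oracle_runs_line <- function(x) {
  out <- NULL
  i <- 1
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[j + 1] == x[i]) j <- j + 1
    out <- rbind(out, c(x[i], j - i + 1))
    i <- j + 1
  }
  out
}

oracle_rlm <- function(levels, ng, direction) {
  nr <- nrow(levels); nc <- ncol(levels)
  nrl <- max(nr, nc)
  lines <- switch(direction,
    horizontal = lapply(seq_len(nr), function(r) levels[r, ]),
    vertical   = lapply(seq_len(nc), function(c) levels[, c]),
    diag45     = lapply(2:(nr + nc), function(s) {
      rr <- seq_len(nr); cc <- s - rr
      ok <- cc >= 1 & cc <= nc
      levels[cbind(rev(rr[ok]), rev(cc[ok]))]
    }),
    diag135    = lapply((1 - nr):(nc - 1), function(d) {
      rr <- seq_len(nr); cc <- rr + d
      ok <- cc >= 1 & cc <= nc
      levels[cbind(rr[ok], cc[ok])]
    }))
  rm <- matrix(0, ng, nrl)
  for (ln in lines) {
    if (!length(ln)) next
    runs <- oracle_runs_line(ln)
    for (k in seq_len(nrow(runs)))
      rm[runs[k, 1], runs[k, 2]] <- rm[runs[k, 1], runs[k, 2]] + 1
  }
  rm
}

oracle_lre <- function(rm) {
  tot <- sum(rm)
  acc <- 0
  for (i in seq_len(nrow(rm))) for (k in seq_len(ncol(rm)))
    acc <- acc + k^2 * rm[i, k]
  acc / tot
}

# random quantized ROI for property tests
random_levels <- function(side_r, side_c = side_r, ng = 8L) {
  matrix(sample.int(ng, side_r * side_c, replace = TRUE), side_r, side_c)
}

# wrap a plain level matrix as a quantized_roi without renormalizing
as_qroi <- function(levels, ng) {
  structure(list(levels = matrix(as.integer(levels), nrow(levels), ncol(levels)),
                 n_levels = as.integer(ng), side = nrow(levels),
                 mu = NA_real_, sigma = NA_real_,
                 roi_id = NA_character_, source_id = NA_character_,
                 lighting = NA_character_, group_label = "unknown"),
            class = "quantized_roi")
}
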