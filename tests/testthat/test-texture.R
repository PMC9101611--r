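# helper: glcm object with a prescribed probability matrix
glcm_from_p <- function(p) {
  structure(list(p = p, offset = c(drow = 0L, dcol = 1L),
                 n_levels = nrow(p), pair_count = 1L), class = "glcm")
}

test_that("co-occurrence counting matches the enumerated pairs", {
  # 2x2 levels [[1,2],[1,2]], offset (0,1): two ordered pairs (1,2); with
  # symmetric accumulation p(1,2) = p(2,1) = 0.5
  q <- as_qroi(rbind(c(1, 2), c(1, 2)), 2)
  m <- compute_glcm(q, c(0, 1))
  expect_equal(m$p, rbind(c(0, 0.5), c(0.5, 0)))
  expect_equal(m$pair_count, 4)

  # constant image: all mass on one diagonal cell
  mc <- compute_glcm(as_qroi(matrix(3, 4, 4), 5), c(1, 1))
  expect_equal(mc$p[3, 3], 1)
  expect_equal(sum(mc$p), 1)
})

test_that("glcm offsets are validated", {
  q <- as_qroi(random_levels(6, 6, 4), 4)
  expect_error(compute_glcm(q, c(0, 0)), "nonzero")
  expect_error(compute_glcm(q, c(6, 0)), "no valid pixel pair")
})

test_that("entropy and difference entropy reproduce hand-evaluated cases", {
  # two equal off-diagonal cells: -2 * 0.5 log 0.5 = log 2
  m <- glcm_from_p(rbind(c(0, 0.5), c(0.5, 0)))
  expect_equal(glcm_entropy(m), log(2))
  expect_equal(glcm_difference_entropy(m), 0)  # every pair differs by 1

  # certainty has zero entropy
  m1 <- glcm_from_p(rbind(c(1, 0), c(0, 0)))
  expect_equal(glcm_entropy(m1), 0)
  expect_equal(glcm_difference_entropy(m1), 0)

  # q(0) = q(1) = 0.5 -> difference entropy log 2
  m2 <- glcm_from_p(matrix(0.25, 2, 2))
  expect_equal(glcm_difference_entropy(m2), log(2))
  expect_equal(glcm_entropy(m2), log(4))       # uniform: the maximum

  # base-10 logarithm is a pure rescaling
  expect_equal(glcm_entropy(m2, log_base = 10), log10(4))

  # unnormalized matrices are rejected
  expect_error(glcm_entropy(glcm_from_p(matrix(0.5, 2, 2))), "not normalized")
})

test_that("difference histogram is a probability distribution over |i-j|", {
  set.seed(31)
  for (ng in c(4, 8)) {
    m <- compute_glcm(as_qroi(random_levels(12, 12, ng), ng), c(1, 2))
    q <- difference_histogram(m)
    expect_length(q, ng)
    expect_equal(sum(q), 1)
    expect_true(all(q >= 0))
  }
})

test_that("run decomposition matches a brute-force scan", {
  # single row 1,1,2,2,2,1 -> runs (1, len 2), (2, len 3), (1, len 1)
  R <- compute_rlm(as_qroi(matrix(c(1, 1, 2, 2, 2, 1), 1, 6), 2), "horizontal")
  expect_equal(R$r[1, 2], 1)
  expect_equal(R$r[2, 3], 1)
  expect_equal(R$r[1, 1], 1)
  expect_equal(R$total_runs, 3)
  expect_equal(long_run_emphasis(R), (4 + 9 + 1) / 3)

  # 2-level checkerboard: every horizontal/vertical run has length 1
  cb <- as_qroi(outer(1:8, 1:8, function(i, j) 1 + (i + j) %% 2), 2)
  for (dir in c("horizontal", "vertical")) {
    R2 <- compute_rlm(cb, dir)
    expect_equal(R2$total_runs, 64)
    expect_equal(long_run_emphasis(R2), 1)
  }

  # constant W x W: W horizontal runs of length W
  Rc <- compute_rlm(as_qroi(matrix(2, 7, 7), 3), "horizontal")
  expect_equal(Rc$r[2, 7], 7)
  expect_equal(long_run_emphasis(Rc), 49)
})

test_that("run-length pixel mass is conserved in every direction", {
  set.seed(41)
  for (i in 1:5) {
    lv <- random_levels(sample(5:20, 1), sample(5:20, 1), 6)
    q <- as_qroi(lv, 6)
    for (dir in c("horizontal", "vertical", "diag45", "diag135")) {
      R <- compute_rlm(q, dir)
      expect_equal(sum(sweep(R$r, 2, seq_len(R$max_run_length), "*")),
                   length(lv), label = dir)
    }
  }
})

test_that("matrix builders agree with the naive oracles on random images", {
  set.seed(51)
  for (i in 1:12) {
    ng <- sample(c(4L, 8L, 16L), 1)
    lv <- random_levels(sample(8:24, 1), sample(8:24, 1), ng)
    q <- as_qroi(lv, ng)
    off <- list(c(0, 1), c(1, 0), c(2, 3), c(1, -2))[[sample(4, 1)]]
    expect_equal(compute_glcm(q, off)$p, oracle_glcm(lv, ng, off))
    dir <- sample(c("horizontal", "vertical", "diag45", "diag135"), 1)
    R <- compute_rlm(q, dir)
    expect_equal(unname(R$r), unname(oracle_rlm(lv, ng, dir)))
  }
})

test_that("symmetric accumulation makes the offset sign irrelevant", {
  set.seed(61)
  lv <- random_levels(15, 15, 8)
  q <- as_qroi(lv, 8)
  for (off in list(c(0, 5), c(5, 0), c(5, 5), c(5, -5), c(2, 3))) {
    m1 <- compute_glcm(q, off)
    m2 <- compute_glcm(q, -off)
    expect_equal(m1$p, m2$p)
    expect_equal(m1$p, t(m1$p))   # symmetry of the matrix itself
  }
})

test_that("index construction and its guards", {
  expect_equal(compute_indices(0, 0, 5)$TI, 0)
  expect_equal(compute_indices(2, 0.9, 4)$TI, 0.5)
  expect_equal(compute_indices(2, 0.9, 3)$BI, 0.3)
  expect_error(compute_indices(1, 1, 0.5), "lngremph")
})

test_that("feature_vector aggregates the per-direction values by their mean", {
  set.seed(71)
  lv <- random_levels(32, 32, 8)
  q <- as_qroi(lv, 8)
  fv <- feature_vector(q, distance = 5)
  # oracle recomputation, one offset/direction at a time
  offs <- list(c(5, 0), c(0, 5), c(5, 5), c(5, -5))
  ent <- vapply(offs, function(o) oracle_entropy(oracle_glcm(lv, 8, o)), 0)
  dif <- vapply(offs, function(o) oracle_difentrp(oracle_glcm(lv, 8, o)), 0)
  lre <- vapply(c("horizontal", "vertical", "diag45", "diag135"),
                function(d) oracle_lre(oracle_rlm(lv, 8, d)), 0)
  expect_equal(fv$Entropy, mean(ent), tolerance = 1e-12)
  expect_equal(fv$DifEntrp, mean(dif), tolerance = 1e-12)
  expect_equal(fv$LngREmph, mean(lre), tolerance = 1e-12)
  expect_equal(fv$TI, fv$Entropy / fv$LngREmph)
  expect_equal(fv$BI, fv$DifEntrp / fv$LngREmph)
})

test_that("feature bounds hold on random inputs", {
  set.seed(81)
  for (i in 1:8) {
    ng <- sample(c(4L, 8L, 16L), 1)
    n <- sample(12:32, 1)
    fv <- feature_vector(as_qroi(random_levels(n, n, ng), ng), distance = 2)
    expect_gte(fv$Entropy, 0); expect_lte(fv$Entropy, log(ng^2))
    expect_gte(fv$DifEntrp, 0); expect_lte(fv$DifEntrp, log(ng))
    expect_gte(fv$LngREmph, 1); expect_lte(fv$LngREmph, n^2)
  }
})

test_that("rotating the image by 90 degrees leaves the mean features unchanged", {
  set.seed(91)
  lv <- random_levels(24, 24, 8)
  rot <- t(lv)[, rev(seq_len(nrow(lv)))]     # 90-degree rotation
  f1 <- feature_vector(as_qroi(lv, 8), distance = 3)
  f2 <- feature_vector(as_qroi(rot, 8), distance = 3)
  for (f in c("LngREmph", "Entropy", "DifEntrp", "TI", "BI"))
    expect_equal(f1[[f]], f2[[f]], tolerance = 1e-12, label = f)
  # and the per-direction values permute: horizontal <-> vertical
  expect_equal(sort(f1$per_direction$LngREmph), sort(f2$per_direction$LngREmph))
})

test_that("constant ROI gives the closed-form feature vector", {
  n <- 64L
  fv <- feature_vector(as_qroi(matrix(4, n, n), 8))
  expect_equal(fv$Entropy, 0)
  expect_equal(fv$DifEntrp, 0)
  expect_equal(fv$TI, 0)
  expect_equal(fv$BI, 0)
  # horizontal/vertical LRE is n^2; a diagonal scan sees lines of lengths
  # 1..n..1, so its LRE is (2*sum(k^2, k<n) + n^2) / (2n - 1)
  diag_lre <- (2 * sum((1:(n - 1))^2) + n^2) / (2 * n - 1)
  expect_equal(fv$LngREmph, (2 * n^2 + 2 * diag_lre) / 4)
})
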