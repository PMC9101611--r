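test_that("normality check enforces the sample-size range", {
  expect_error(test_normality(c(1, 2)), "3 <= n")
  expect_error(test_normality(rep(0, 6000)), "3 <= n")
  expect_error(test_normality(c(1, 2, NA)), "finite")
})

test_that("normality check separates Gaussian from exponential samples", {
  set.seed(2205)
  expect_gt(test_normality(rnorm(166)), 0.05)
  expect_lt(test_normality(rexp(166)), 0.05)
})

test_that("routing: any non-normal group sends the comparison to Kruskal-Wallis", {
  set.seed(42)
  v_norm <- rnorm(166 * 3)
  g <- rep(c("BN", "DN", "MM"), each = 166)
  expect_equal(compare_groups(v_norm, g)$test_used, "anova")

  v_mixed <- c(rnorm(166), rnorm(166), rexp(166))
  expect_equal(compare_groups(v_mixed, g)$test_used, "kruskal_wallis")
  # deterministic routing: same input, same route
  expect_equal(compare_groups(v_mixed, g)$test_used, "kruskal_wallis")
})

test_that("input contracts are enforced", {
  expect_error(compare_groups(1:5, rep("a", 5)), "2 groups")
  expect_error(compare_groups(1:4, c("a", "a", "b", "b")), "n >= 3")
  expect_error(compare_groups(1:6, rep(c("a", "b"), 3), alpha = 1.2), "alpha")
  expect_error(compare_groups(1:5, rep("a", 4)), "same length")
})

test_that("Dunn's test reproduces the hand-derived tied-free case", {
  # groups {1,2,3}, {4,5,6}, {7,8,9}: pooled ranks are the values themselves;
  # mean ranks 2, 5, 8; N = 9, N(N+1)/12 = 7.5, no ties. Hand derivation:
  # z(A,C) = (2 - 8) / sqrt(7.5 * (2/3)) = -6/sqrt(5); z(A,B) = z(B,C) =
  # -3/sqrt(5); two-sided p, Bonferroni x 3.
  d <- lesiontex:::dunn_test(c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                             rep(c("A", "B", "C"), each = 3))
  ac <- d[d$group_a == "A" & d$group_b == "C", ]
  expect_equal(ac$statistic, -6 / sqrt(5), tolerance = 1e-12)
  expect_equal(ac$p_adjusted, min(1, 3 * 2 * pnorm(-6 / sqrt(5))), tolerance = 1e-12)
  expect_equal(ac$direction, "<")
  ab <- d[d$group_a == "A" & d$group_b == "B", ]
  expect_equal(ab$statistic, -3 / sqrt(5), tolerance = 1e-12)
})

test_that("Dunn z statistics are standard normal under the null", {
  set.seed(99)
  z <- replicate(300, {
    v <- rnorm(45)
    g <- rep(c("A", "B", "C"), each = 15)
    lesiontex:::dunn_test(v, g)$statistic[1]
  })
  expect_equal(mean(z), 0, tolerance = 0.2)
  expect_equal(sd(z), 1, tolerance = 0.15)
})

test_that("strong separations yield the full ordering chain", {
  set.seed(7)
  v <- c(rnorm(50, 0), rnorm(50, 3), rnorm(50, 6))
  g <- rep(c("low", "mid", "high"), each = 50)
  cg <- compare_groups(v, g)
  expect_lt(cg$p_value, 0.001)
  expect_equal(cg$ordering, "high > mid > low")
  expect_equal(nrow(cg$pairwise), 3)
})

test_that("identical groups come back not significant, without pairwise lines", {
  set.seed(8)
  v <- rnorm(90)
  cg <- compare_groups(v, rep(c("a", "b", "c"), each = 30))
  expect_equal(cg$ordering, "n.s.")
  expect_equal(nrow(cg$pairwise), 0)
  expect_equal(cg$posthoc, "none")
})

test_that("partial separation lists only the significant pairs", {
  set.seed(9)
  # one far group, two coincident groups
  v <- c(rnorm(60, 0), rnorm(60, 0), rnorm(60, 4))
  cg <- compare_groups(v, rep(c("BN", "DN", "MM"), each = 60))
  expect_lt(cg$p_value, 0.001)
  expect_match(cg$ordering, "MM > ")
  expect_false(grepl("MM > DN > BN", cg$ordering, fixed = TRUE))
})

test_that("two-group comparisons route to t test or Mann-Whitney", {
  set.seed(10)
  v <- c(rnorm(40, 0), rnorm(40, 2))
  g <- rep(c("in_situ", "invasive"), each = 40)
  cg <- compare_groups(v, g)
  expect_equal(cg$test_used, "anova")
  expect_equal(cg$posthoc, "t_test")
  expect_equal(cg$ordering, "invasive > in_situ")

  v2 <- c(rexp(40), rexp(40) + 2)
  cg2 <- compare_groups(v2, g)
  expect_equal(cg2$test_used, "kruskal_wallis")
  expect_equal(cg2$posthoc, "mann_whitney")
})

test_that("Gaussian groups at the published polarized long-run means usually rank melanoma on top", {
  # means/SDs (7.84/4.69, 6.20/3.29, 5.28/4.32), n = 166 per group. The
  # MM-vs-nevus contrasts are well powered; the DN-vs-BN contrast is not,
  # so the *full* chain appears only in a minority of repetitions.
  set.seed(166)
  n <- 166
  res <- replicate(25, {
    v <- c(rnorm(n, 7.84, 4.69), rnorm(n, 6.20, 3.29), rnorm(n, 5.28, 4.32))
    g <- rep(c("MM", "DN", "BN"), each = n)
    cg <- compare_groups(v, g)
    pw <- cg$pairwise
    sig <- function(a, b) {
      r <- pw[(pw$group_a == a & pw$group_b == b) |
                (pw$group_a == b & pw$group_b == a), ]
      nrow(r) == 1 && r$p_adjusted < 0.05
    }
    c(mm_top = nrow(pw) > 0 && sig("MM", "BN") && sig("MM", "DN"),
      mean_order = mean(v[g == "MM"]) > mean(v[g == "DN"]) &&
        mean(v[g == "DN"]) > mean(v[g == "BN"]))
  })
  expect_gte(mean(res["mm_top", ]), 0.7)
  expect_gte(mean(res["mean_order", ]), 0.7)
})

test_that("the assembled report mirrors the feature x lighting grid", {
  set.seed(11)
  # small synthetic feature table: 2 lighting modes x 3 groups x 12 ROIs
  mk <- function(lt) {
    do.call(rbind, lapply(c("BN", "DN", "MM"), function(cl) {
      shift <- match(cl, c("BN", "DN", "MM"))
      data.frame(roi_id = paste0(lt, cl, 1:12), source_id = "s",
                 group_label = cl, lighting = lt,
                 LngREmph = rnorm(12, shift), Entropy = rnorm(12, -shift),
                 DifEntrp = rnorm(12, -shift), TI = rnorm(12, -shift),
                 BI = rnorm(12, -shift), stringsAsFactors = FALSE)
    }))
  }
  features <- rbind(mk("polarized"), mk("nonpolarized"))
  results <- compare_all_features(features)
  expect_length(results, 10)            # five features x two lighting modes
  report <- summarize_table(results, group_summary(features))
  expect_length(report$entries, 10)

  # n.s. comparisons carry no pairwise lines
  ns <- Filter(function(e) e$p_value >= 0.05, report$entries)
  for (e in ns) expect_null(e$pairwise)

  # group means/SDs equal an independent recomputation from the raw table
  gs <- report$group_stats
  row <- gs[gs$lighting == "polarized" & gs$feature == "Entropy" &
              gs$group_label == "MM", ]
  v <- features$Entropy[features$lighting == "polarized" &
                          features$group_label == "MM"]
  expect_equal(row$mean, mean(v))
  expect_equal(row$sd, sd(v))

  # completeness is enforced
  expect_error(summarize_table(results[-1], group_summary(features)),
               "incomplete")
})
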