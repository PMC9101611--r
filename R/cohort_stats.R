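# Normality-routed group comparison and Table-style reporting.

#' Shapiro-Wilk normality check for one group sample
#'
#' @param values numeric vector of per-ROI feature values; the test is defined
#'   for 3 to 5000 observations.
#' @return The Shapiro-Wilk p-value.
#' @export
test_normality <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values)))
    stop("values must be finite and non-missing")
  n <- length(values)
  if (n < 3L || n > 5000L)
    stop(sprintf("Shapiro-Wilk requires 3 <= n <= 5000 (got n=%d)", n))
  stats::shapiro.test(values)$p.value
}

# Dunn's rank-based post hoc after Kruskal-Wallis, with a tie correction and
# Bonferroni adjustment. No installed package provides it, so it is written
# out here: for groups A, B with mean ranks Rbar over the pooled sample of
# size N,  z = (RbarA - RbarB) / sqrt((N(N+1)/12 - T) (1/nA + 1/nB)),
# T = sum(t^3 - t) / (12 (N - 1)) over tie groups t.
dunn_test <- function(values, groups) {
  groups <- as.character(groups)
  n_tot <- length(values)
  rk <- rank(values)
  mean_rank <- tapply(rk, groups, mean)
  n_g <- tapply(rk, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  labs <- names(mean_rank)
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  n_pairs <- length(pairs)
  out <- lapply(pairs, function(ab) {
    a <- ab[1]; b <- ab[2]
    se <- sqrt((n_tot * (n_tot + 1) / 12 - tie_term) *
                 (1 / n_g[[a]] + 1 / n_g[[b]]))
    z <- (mean_rank[[a]] - mean_rank[[b]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group_a = a, group_b = b, statistic = z,
               p_adjusted = min(1, p * n_pairs),
               direction = if (z > 0) ">" else if (z < 0) "<" else "=",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Tukey HSD pairwise table in the same layout as dunn_test; direction from
# group means.
tukey_pairs <- function(values, groups) {
  g <- factor(groups)
  fit <- stats::aov(values ~ g)
  tk <- stats::TukeyHSD(fit)$g
  means <- tapply(values, g, mean)
  cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
  out <- lapply(seq_along(cmp), function(i) {
    a <- cmp[[i]][1]; b <- cmp[[i]][2]
    d <- means[[a]] - means[[b]]
    data.frame(group_a = a, group_b = b, statistic = tk[i, "diff"],
               p_adjusted = tk[i, "p adj"],
               direction = if (d > 0) ">" else if (d < 0) "<" else "=",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Ordering string: full chain "MM > DN > BN" when every adjacent pair of the
# center-sorted groups is significant with a consistent direction; otherwise
# the list of significant pairs ("MM > DN; MM > BN"); "n.s." when nothing is.
build_ordering <- function(pairwise, centers, alpha) {
  ord <- names(sort(centers, decreasing = TRUE))
  sig_at <- function(a, b) {
    row <- pairwise[(pairwise$group_a == a & pairwise$group_b == b) |
                      (pairwise$group_a == b & pairwise$group_b == a), ]
    nrow(row) == 1 && row$p_adjusted < alpha
  }
  adjacent_ok <- all(vapply(seq_len(length(ord) - 1L),
                            function(i) sig_at(ord[i], ord[i + 1L]), logical(1)))
  all_ok <- all(pairwise$p_adjusted < alpha)
  if (adjacent_ok && all_ok)
    return(paste(ord, collapse = " > "))
  sig <- pairwise[pairwise$p_adjusted < alpha, , drop = FALSE]
  if (nrow(sig) == 0L) return("n.s.")
  lines <- vapply(seq_len(nrow(sig)), function(i) {
    a <- sig$group_a[i]; b <- sig$group_b[i]
    if (centers[[a]] >= centers[[b]]) paste(a, ">", b) else paste(a, "<", b)
  }, "")
  paste(lines, collapse = "; ")
}

#' Normality-routed comparison of feature values across groups
#'
#' Reproduces the statistical stage of the analysis: every group is checked
#' with Shapiro-Wilk; if *all* groups look normal at `alpha` the omnibus test
#' is classic one-way ANOVA (equal variances; two groups degenerate to the
#' pooled t test), otherwise Kruskal-Wallis (two groups: Mann-Whitney).
#' When the omnibus p-value is below `alpha`, the matching post hoc runs —
#' Tukey HSD after ANOVA, Dunn's test with Bonferroni correction after
#' Kruskal-Wallis — and an ordering string such as `"MM > DN > BN"` is
#' assembled when all pairwise comparisons are consistent at `alpha`
#' (partial orderings list the significant pairs; `"n.s."` otherwise).
#'
#' @param values numeric vector of per-ROI feature values.
#' @param groups group labels, same length as `values`; >= 2 groups with
#'   >= 3 observations each.
#' @param alpha significance level for the normality gate, the omnibus test
#'   and the post hoc (default 0.05).
#' @param feature optional feature name carried into the result.
#' @return An object of class `group_comparison`: `feature`, `test_used`
#'   (`"anova"` or `"kruskal_wallis"`), `p_value`, `normality_p` (per group),
#'   `pairwise` (data.frame `group_a`, `group_b`, `statistic`, `p_adjusted`,
#'   `direction`), `posthoc` (`"tukey_hsd"`, `"dunn_bonferroni"` or `"none"`),
#'   `ordering`, `group_n`, `alpha`.
#' @export
compare_groups <- function(values, groups, alpha = 0.05, feature = NA_character_) {
  values <- as.numeric(values)
  groups <- as.character(groups)
  if (length(values) != length(groups))
    stop("values and groups must have the same length")
  if (anyNA(values) || any(!is.finite(values)))
    stop("values must be finite and non-missing")
  if (anyNA(groups)) stop("groups must be non-missing")
  labs <- unique(groups)
  if (length(labs) < 2L) stop("need at least 2 groups")
  n_g <- table(groups)
  if (any(n_g < 3L))
    stop(sprintf("every group needs n >= 3 (got: %s)",
                 paste(sprintf("%s=%d", names(n_g), n_g), collapse = ", ")))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")

  norm_p <- vapply(labs, function(l) test_normality(values[groups == l]),
                   numeric(1))
  names(norm_p) <- labs
  all_normal <- all(norm_p > alpha)
  g <- factor(groups)

  if (all_normal) {
    test_used <- "anova"
    if (length(labs) == 2L) {
      p <- stats::t.test(values ~ g, var.equal = TRUE)$p.value
    } else {
      fit <- stats::aov(values ~ g)
      p <- summary(fit)[[1]][["Pr(>F)"]][1]
    }
    centers <- tapply(values, g, mean)
  } else {
    test_used <- "kruskal_wallis"
    if (length(labs) == 2L) {
      p <- stats::wilcox.test(values ~ g, exact = FALSE)$p.value
    } else {
      p <- stats::kruskal.test(values, g)$p.value
    }
    centers <- tapply(rank(values), g, mean)   # mean ranks
  }

  pairwise <- data.frame(group_a = character(0), group_b = character(0),
                         statistic = numeric(0), p_adjusted = numeric(0),
                         direction = character(0), stringsAsFactors = FALSE)
  posthoc <- "none"
  ordering <- "n.s."
  if (p < alpha) {
    if (length(labs) == 2L) {
      # the omnibus *is* the pairwise test
      a <- labs[1]; b <- labs[2]
      d <- centers[[a]] - centers[[b]]
      pairwise <- data.frame(group_a = a, group_b = b, statistic = d,
                             p_adjusted = p,
                             direction = if (d > 0) ">" else "<",
                             stringsAsFactors = FALSE)
      posthoc <- if (test_used == "anova") "t_test" else "mann_whitney"
    } else if (test_used == "anova") {
      pairwise <- tukey_pairs(values, groups)
      posthoc <- "tukey_hsd"
    } else {
      pairwise <- dunn_test(values, groups)
      posthoc <- "dunn_bonferroni"
    }
    ordering <- build_ordering(pairwise, centers, alpha)
  }

  structure(
    list(feature = feature, test_used = test_used, p_value = p,
         normality_p = norm_p, pairwise = pairwise, posthoc = posthoc,
         ordering = ordering, group_n = as.list(n_g), alpha = alpha,
         group_center = as.list(centers)),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s p=%.3g -> %s\n",
              if (is.na(x$feature)) "(feature)" else x$feature,
              x$test_used, x$p_value, x$ordering))
  invisible(x)
}

#' Group mean and SD per feature, lighting mode and lesion class
#'
#' Independent descriptive pass over the canonical feature table; sample SD.
#'
#' @param features feature data.frame from [compute_features()].
#' @return data.frame with columns `lighting`, `feature`, `group_label`, `n`,
#'   `mean`, `sd`.
#' @export
group_summary <- function(features) {
  check_feature_table(features)
  out <- list()
  for (lt in unique(features$lighting)) {
    sub <- features[features$lighting == lt, ]
    for (f in feature_names) {
      agg <- tapply(sub[[f]], sub$group_label, function(v)
        c(n = length(v), mean = mean(v), sd = stats::sd(v)))
      for (glab in names(agg)) {
        out[[length(out) + 1L]] <- data.frame(
          lighting = lt, feature = f, group_label = glab,
          n = agg[[glab]][["n"]], mean = agg[[glab]][["mean"]],
          sd = agg[[glab]][["sd"]], stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

check_feature_table <- function(features) {
  need <- c("roi_id", "group_label", "lighting", feature_names)
  missing <- setdiff(need, names(features))
  if (length(missing))
    stop(sprintf("feature table lacks column(s): %s",
                 paste(missing, collapse = ", ")))
  invisible(features)
}

#' Run the comparison stage for every feature and lighting mode
#'
#' @param features feature data.frame from [compute_features()].
#' @param alpha significance level (default 0.05).
#' @return Named list of `group_comparison` objects, one per
#'   `lighting:feature` combination.
#' @export
compare_all_features <- function(features, alpha = 0.05) {
  check_feature_table(features)
  res <- list()
  for (lt in unique(features$lighting)) {
    sub <- features[features$lighting == lt, ]
    for (f in feature_names) {
      key <- paste(lt, f, sep = ":")
      res[[key]] <- compare_groups(sub[[f]], sub$group_label, alpha = alpha,
                                   feature = f)
      res[[key]]$lighting <- lt
    }
  }
  res
}

#' Assemble the summary report
#'
#' Combines the per-feature comparison results with the per-group
#' descriptive statistics into one report object mirroring the layout of a
#' results table: per lighting mode and feature, group mean +/- SD, the
#' omnibus test and p-value, and the pairwise ordering note (`"n.s."` when
#' the omnibus is not significant).
#'
#' @param results list of `group_comparison` objects from
#'   [compare_all_features()] (each carrying a `lighting` field).
#' @param group_stats data.frame from [group_summary()].
#' @return An object of class `texture_report` with fields `entries` (list),
#'   `group_stats`, `alpha`.
#' @export
summarize_table <- function(results, group_stats) {
  if (!length(results)) stop("no comparison results supplied")
  lightings <- unique(vapply(results, function(r) r$lighting, ""))
  want <- as.vector(outer(lightings, feature_names, paste, sep = ":"))
  have <- names(results)
  missing <- setdiff(want, have)
  if (length(missing))
    stop(sprintf("incomplete results: missing %s",
                 paste(missing, collapse = ", ")))
  entries <- lapply(results, function(r) {
    gs <- group_stats[group_stats$lighting == r$lighting &
                        group_stats$feature == r$feature, , drop = FALSE]
    list(lighting = r$lighting, feature = r$feature,
         groups = lapply(seq_len(nrow(gs)), function(i)
           list(group_label = gs$group_label[i], n = gs$n[i],
                mean = gs$mean[i], sd = gs$sd[i])),
         test_used = r$test_used, posthoc = r$posthoc,
         p_value = r$p_value, ordering = r$ordering,
         pairwise = if (nrow(r$pairwise)) r$pairwise else NULL)
  })
  structure(list(entries = entries, group_stats = group_stats,
                 alpha = results[[1]]$alpha),
            class = "texture_report")
}

#' Write a report as JSON and Markdown
#'
#' @param report a `texture_report` from [summarize_table()].
#' @param json_path,md_path output paths; `NULL` skips that format.
#' @return `report`, invisibly.
#' @export
write_report <- function(report, json_path = NULL, md_path = NULL) {
  stopifnot(inherits(report, "texture_report"))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      lapply(report$entries, function(e) {
        e$pairwise <- if (is.null(e$pairwise)) NULL else e$pairwise
        e
      }),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  }
  if (!is.null(md_path)) {
    writeLines(format_report_md(report), md_path)
  }
  invisible(report)
}

format_report_md <- function(report) {
  lines <- c("# Texture feature group comparison", "",
             sprintf("alpha = %g; omnibus: ANOVA when all groups pass Shapiro-Wilk, else Kruskal-Wallis.", report$alpha), "")
  for (lt in unique(vapply(report$entries, `[[`, "", "lighting"))) {
    lines <- c(lines, sprintf("## %s light", lt), "",
               "| Feature | Group | n | mean ± SD | Test | p | Note |",
               "|---|---|---|---|---|---|---|")
    for (e in Filter(function(e) e$lighting == lt, report$entries)) {
      first <- TRUE
      for (g in e$groups) {
        lines <- c(lines, sprintf(
          "| %s | %s | %d | %.3f ± %.3f | %s | %s | %s |",
          if (first) e$feature else "", g$group_label, g$n, g$mean, g$sd,
          if (first) e$test_used else "",
          if (first) format(signif(e$p_value, 3)) else "",
          if (first) e$ordering else ""))
        first <- FALSE
      }
    }
    lines <- c(lines, "")
  }
  lines
}
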