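# End-to-end orchestration: input -> features -> statistics -> report.

#' Pipeline configuration
#'
#' Collects every knob of an end-to-end run. Defaults mirror the working
#' choices of the analysis: 450-pixel ROIs, 64 gray levels, pixel distance 5,
#' natural-log entropies, alpha 0.05.
#'
#' @param input `"synthetic"` or the path of an ROI metadata CSV
#'   (see [read_roi_metadata()]).
#' @param n_per_group synthetic cohort size per class per lighting mode.
#' @param lighting_modes lighting modes of a synthetic run.
#' @param side synthetic ROI side in pixels.
#' @param n_levels quantization levels.
#' @param distance co-occurrence pixel distance.
#' @param log_base entropy logarithm base.
#' @param reducer direction aggregation (`"mean"`).
#' @param alpha significance level of the statistics stage.
#' @param seed master seed for every random draw of the run.
#' @param image_dir base directory for relative image paths in the metadata.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = "synthetic",
                            n_per_group = 166L,
                            lighting_modes = c("polarized", "nonpolarized"),
                            side = 450L,
                            n_levels = 64L,
                            distance = 5L,
                            log_base = exp(1),
                            reducer = "mean",
                            alpha = 0.05,
                            seed = 1L,
                            image_dir = ".") {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (as.integer(distance) < 1L) stop("distance must be >= 1")
  structure(
    list(input = input, n_per_group = as.integer(n_per_group),
         lighting_modes = lighting_modes, side = as.integer(side),
         n_levels = as.integer(n_levels), distance = as.integer(distance),
         log_base = log_base, reducer = reducer, alpha = alpha,
         seed = as.integer(seed), image_dir = image_dir),
    class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' Any key of [pipeline_config()] may appear; missing keys take the default.
#'
#' @param path JSON file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file '%s' does not exist", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop(sprintf("unknown config key(s) in '%s': %s",
                 path, paste(unknown, collapse = ", ")))
  do.call(pipeline_config, raw)
}

#' Run the full pipeline
#'
#' Resolves the input (synthetic cohort or metadata-listed images), computes
#' the per-ROI feature table, runs the group-comparison stage, and writes
#' `features.csv`, `report.json`, `report.md` and `run.log` into
#' `output_dir`. Identical config and seed give a byte-identical
#' `features.csv`.
#'
#' @param config a [pipeline_config()].
#' @param output_dir directory for the run artifacts (created if needed).
#' @return Invisibly, a list with `features`, `report` and the artifact
#'   paths.
#' @export
run_pipeline <- function(config, output_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  # resolve inputs before writing anything
  if (identical(config$input, "synthetic")) {
    cohort <- generate_cohort(n_per_group = config$n_per_group,
                              lighting_modes = config$lighting_modes,
                              base_seed = config$seed, side = config$side)
    rois <- cohort$rois
    input_desc <- sprintf("synthetic cohort: %d per group, modes [%s]",
                          config$n_per_group,
                          paste(config$lighting_modes, collapse = ", "))
  } else {
    md <- read_roi_metadata(config$input)
    rois <- load_rois(md, base_dir = config$image_dir)
    input_desc <- sprintf("metadata CSV '%s': %d ROIs", config$input, nrow(md))
  }

  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir))
    stop(sprintf("cannot create output directory '%s'", output_dir))
  log_lines <- c(
    sprintf("lesiontex %s | R %s.%s", as.character(utils::packageVersion("lesiontex")),
            R.version$major, R.version$minor),
    sprintf("seed: %d", config$seed),
    sprintf("input: %s", input_desc),
    sprintf("config: n_levels=%d distance=%d log_base=%g reducer=%s alpha=%g side=%d",
            config$n_levels, config$distance, config$log_base, config$reducer,
            config$alpha, config$side))

  features <- compute_features(rois, distance = config$distance,
                               n_levels = config$n_levels,
                               log_base = config$log_base,
                               reducer = config$reducer)
  features_path <- file.path(output_dir, "features.csv")
  write_features_csv(features, features_path)
  log_lines <- c(log_lines, sprintf("features: %d ROIs -> %s",
                                    nrow(features), features_path))

  results <- compare_all_features(features, alpha = config$alpha)
  report <- summarize_table(results, group_summary(features))
  json_path <- file.path(output_dir, "report.json")
  md_path <- file.path(output_dir, "report.md")
  write_report(report, json_path = json_path, md_path = md_path)
  log_lines <- c(log_lines,
                 vapply(results, function(r)
                   sprintf("stats: %s %s: %s p=%.3g -> %s", r$lighting,
                           r$feature, r$test_used, r$p_value, r$ordering), ""),
                 sprintf("report: %s, %s", json_path, md_path))
  log_path <- file.path(output_dir, "run.log")
  writeLines(log_lines, log_path)

  invisible(list(features = features, report = report,
                 features_path = features_path, report_json = json_path,
                 report_md = md_path, log_path = log_path))
}

# Deterministic CSV serialization of the feature table: fixed column order,
# full double precision (17 significant digits survive a read round-trip).
write_features_csv <- function(features, path) {
  check_feature_table(features)
  cols <- c("roi_id", "source_id", "group_label", "lighting", feature_names)
  out <- features[, cols]
  for (f in feature_names) out[[f]] <- sprintf("%.17g", out[[f]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by the pipeline
#'
#' @param path `features.csv` path.
#' @return data.frame in the canonical feature-table layout.
#' @export
read_features_csv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("feature CSV '%s' does not exist", path))
  f <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_feature_table(f)
  f
}
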