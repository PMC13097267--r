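#' Pipeline run configuration
#'
#' @param bins Histogram bins for cohort thresholding (default 256).
#' @param pooling Threshold pooling mode, `"all_timepoints"` (default) or
#'   `"per_timepoint"`.
#' @param marker_features Features entering the response model (default: the
#'   absolute change in myosteatosis volume and the percent change in
#'   whole-region volume).
#' @param seed Optional integer recorded in the run log (the analysis stages
#'   themselves are deterministic).
#' @param write_labelmaps Write per-patient habitat label maps (default TRUE).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(bins = 256L,
                       pooling = c("all_timepoints", "per_timepoint"),
                       marker_features = c("d_volume_LH", "dpct_volume_whole"),
                       seed = NULL,
                       write_labelmaps = TRUE) {
  pooling <- match.arg(pooling)
  bins <- as.integer(bins)
  stopifnot(bins >= 2, is.character(marker_features), length(marker_features) >= 1,
            is.logical(write_labelmaps))
  structure(list(bins = bins, pooling = pooling,
                 marker_features = marker_features, seed = seed,
                 write_labelmaps = write_labelmaps),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

read_stage_meta <- function(dir) {
  meta_path <- file.path(dir, "run_meta.json")
  if (!file.exists(meta_path)) {
    stop(sprintf("no run_meta.json in %s: not a pipeline output directory", dir),
         call. = FALSE)
  }
  jsonlite::read_json(meta_path)
}

check_config_hash <- function(dir, hash) {
  meta <- read_stage_meta(dir)
  if (!identical(meta$config_hash, hash)) {
    stop(sprintf("config hash mismatch in %s: outputs were produced under a different configuration",
                 dir), call. = FALSE)
  }
  invisible(meta)
}

#' Run the full habitat pipeline
#'
#' Executes every stage against a cohort manifest: cohort thresholding,
#' habitat partition and label-map export, feature extraction, group
#' statistics, and response-marker evaluation. All artifacts land in
#' `out_dir`:
#' \itemize{
#'   \item `thresholds.json` - water/fat Otsu thresholds and provenance
#'   \item `labelmaps/` - per-patient habitat label maps (NIfTI + sidecar)
#'   \item `features.csv` - one row per patient (see
#'     [feature_table_columns()])
#'   \item `stats_report.json` / `stats_report.csv` - per-feature group
#'     comparisons
#'   \item `roc_report.csv` - marker evaluation (cutoff, AUC, CI,
#'     sensitivity, specificity)
#'   \item `run_meta.json`, `run_log.txt` - config hash, versions, per-stage
#'     log
#' }
#' Re-running with identical inputs and configuration reproduces
#' `features.csv` byte-identically.
#'
#' @param manifest_path Path to the cohort manifest CSV.
#' @param out_dir Output directory (created if needed).
#' @param config A [run_config()].
#' @return Invisibly, a list with the thresholds, the feature table, the
#'   stats report and the marker report.
#' @export
run_all <- function(manifest_path, out_dir, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hash <- config_hash(config)
  log_path <- file.path(out_dir, "run_log.txt")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                                       sprintf(fmt, ...)))
  }
  say("eomhabitat %s; config hash %s; seed %s",
      as.character(utils::packageVersion("eomhabitat")), hash,
      if (is.null(config$seed)) "none" else config$seed)

  manifest <- read_manifest(manifest_path)
  say("manifest: %d patients (%d responsive, %d unresponsive)",
      nrow(manifest), sum(manifest$response == "responsive"),
      sum(manifest$response == "unresponsive"))

  thresholds <- compute_cohort_thresholds(manifest, bins = config$bins,
                                          pooling = config$pooling)
  thr_json <- if (inherits(thresholds, "threshold_pair")) {
    unclass(thresholds)
  } else {
    lapply(thresholds, unclass)
  }
  jsonlite::write_json(c(thr_json, list(config_hash = hash)),
                       file.path(out_dir, "thresholds.json"),
                       auto_unbox = TRUE, digits = NA)
  say("thresholds: %s", if (inherits(thresholds, "threshold_pair"))
    sprintf("t_water=%.6g t_fat=%.6g", thresholds$t_water, thresholds$t_fat)
    else "per-timepoint pairs")

  labelmap_dir <- if (config$write_labelmaps) file.path(out_dir, "labelmaps") else NULL
  features <- cohort_feature_table(manifest, thresholds, labelmap_dir = labelmap_dir)
  utils::write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)
  for (i in seq_len(nrow(features))) {
    say("features %s: pre %d voxel-equivalents %.3f mL, post %.3f mL",
        features$patient_id[i], i, features$pre_volume_whole[i],
        features$post_volume_whole[i])
  }

  stats_report <- stats_stage_table(features)
  utils::write.csv(stats_report, file.path(out_dir, "stats_report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(stats_report, file.path(out_dir, "stats_report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null")
  say("stats: %d feature comparisons", nrow(stats_report))

  markers <- tryCatch(evaluate_response_markers(features, config$marker_features),
                      error = function(e) e)
  if (inherits(markers, "error")) {
    say("markers: skipped (%s)", conditionMessage(markers))
    markers <- NULL
  } else {
    utils::write.csv(as.data.frame(markers), file.path(out_dir, "roc_report.csv"),
                     row.names = FALSE)
    say("markers: combined AUC %.3f", markers$auc[markers$parameter == "combined_model"])
  }

  jsonlite::write_json(list(config = unclass(config), config_hash = hash,
                            package_version = as.character(utils::packageVersion("eomhabitat")),
                            n_patients = nrow(manifest)),
                       file.path(out_dir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(log_lines, log_path)
  invisible(list(thresholds = thresholds, features = features,
                 stats = stats_report, markers = markers, config_hash = hash))
}

#' Group-comparison table over every habitat feature
#'
#' Applies [compare_feature()] to every feature column of the cohort table
#' and flattens the results into one row per feature: test used, statistic,
#' p-value and the per-group summaries.
#'
#' @param features Feature table from [cohort_feature_table()].
#' @return A `data.frame` with columns `feature`, `test`, `statistic`,
#'   `p_value`, `responsive`, `unresponsive`, `n_responsive`,
#'   `n_unresponsive`.
#' @export
stats_stage_table <- function(features) {
  feature_cols <- setdiff(feature_table_columns(), c("patient_id", "response"))
  rows <- lapply(feature_cols, function(f) {
    res <- tryCatch(compare_feature(features, f), error = function(e) NULL)
    if (is.null(res)) {
      return(data.frame(feature = f, test = NA_character_, statistic = NA_real_,
                        p_value = NA_real_, responsive = NA_character_,
                        unresponsive = NA_character_,
                        n_responsive = NA_integer_, n_unresponsive = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    gs <- res$group_summaries
    ns <- vapply(split(features[[f]], features$response),
                 function(v) sum(!is.na(v)), 1L)
    data.frame(feature = f, test = res$test_used, statistic = res$statistic,
               p_value = res$p_value,
               responsive = gs$responsive$text, unresponsive = gs$unresponsive$text,
               n_responsive = ns[["responsive"]], n_unresponsive = ns[["unresponsive"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
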