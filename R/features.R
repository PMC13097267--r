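habitat_feature_names <- c("volume_whole",
                           paste0("volume_", names(habitat_levels)),
                           paste0("vp_", names(habitat_levels)))

#' Extract volumetric habitat features from a label map
#'
#' Converts voxel counts into physical volumes,
#' `volume = count * dx*dy*dz / 1000` (mm^3 to mL), for the whole muscle
#' region and each habitat, and volume percentages
#' `vp = volume / whole_volume * 100`. The four habitat volumes sum to the
#' whole-region volume and the four VPs to 100 by construction.
#'
#' @param labels A [habitat_labels()] object with at least one in-mask voxel.
#' @return A named list of class `habitat_features` with elements
#'   `volume_whole`, `volume_LL` .. `volume_HH` (mL) and `vp_LL` .. `vp_HH`
#'   (percent).
#' @export
extract_features <- function(labels) {
  counts <- habitat_counts(labels)
  total <- sum(counts)
  if (total == 0) stop("empty mask: whole-region volume is zero", call. = FALSE)
  voxel_ml <- prod(labels$spacing) / 1000
  vols <- counts * voxel_ml
  whole <- total * voxel_ml
  out <- c(list(volume_whole = whole),
           as.list(stats::setNames(vols, paste0("volume_", names(counts)))),
           as.list(stats::setNames(100 * vols / whole, paste0("vp_", names(counts)))))
  structure(out, class = "habitat_features")
}

#' Longitudinal change features
#'
#' For every feature (whole volume, habitat volumes, habitat VPs) computes
#' the absolute change `delta = post - pre` and the relative change
#' `delta_pct = (post - pre) / pre * 100`. Where the pre value is zero the
#' relative change is undefined and reported as `NA` (not 0, not infinite);
#' downstream statistics drop such values pairwise.
#'
#' @param pre,post [extract_features()] results for the same patient before
#'   and after therapy.
#' @return A list of class `longitudinal_features` with elements `pre`,
#'   `post`, `delta`, `delta_pct` (the latter two named numeric vectors over
#'   the feature names).
#' @export
longitudinal_changes <- function(pre, post) {
  stopifnot(inherits(pre, "habitat_features"), inherits(post, "habitat_features"))
  pv <- unlist(pre[habitat_feature_names])
  qv <- unlist(post[habitat_feature_names])
  delta <- qv - pv
  delta_pct <- ifelse(pv > 0, delta / pv * 100, NA_real_)
  names(delta_pct) <- names(delta)
  structure(list(pre = pre, post = post, delta = delta, delta_pct = delta_pct),
            class = "longitudinal_features")
}

flatten_longitudinal <- function(lf) {
  pv <- unlist(lf$pre[habitat_feature_names])
  qv <- unlist(lf$post[habitat_feature_names])
  out <- c(stats::setNames(pv, paste0("pre_", habitat_feature_names)),
           stats::setNames(qv, paste0("post_", habitat_feature_names)),
           stats::setNames(lf$delta, paste0("d_", habitat_feature_names)),
           stats::setNames(lf$delta_pct, paste0("dpct_", habitat_feature_names)))
  as.list(out)
}

#' Column names of the cohort feature table
#'
#' @return Character vector: `patient_id`, `response`, then `pre_`, `post_`,
#'   `d_` and `dpct_` versions of every habitat feature.
#' @export
feature_table_columns <- function() {
  c("patient_id", "response",
    paste0("pre_", habitat_feature_names),
    paste0("post_", habitat_feature_names),
    paste0("d_", habitat_feature_names),
    paste0("dpct_", habitat_feature_names))
}

#' Per-patient habitat feature table for a cohort
#'
#' Runs the habitat partition for every patient and time point in the
#' manifest under the given cohort thresholds and assembles one row per
#' patient: group label plus the full set of pre/post/delta/delta-percent
#' features (see [feature_table_columns()]). Per-patient failures are
#' collected and reported together; the run aborts if any patient fails.
#'
#' @param manifest A [read_manifest()] result.
#' @param thresholds A [threshold_pair()], or a list with `pre` and `post`
#'   pairs as returned by [compute_cohort_thresholds()] with
#'   `pooling = "per_timepoint"`.
#' @param labelmap_dir Optional directory; when given, the habitat label map
#'   of every patient/time point is written there as NIfTI + JSON sidecar.
#' @return A `data.frame`, one row per patient, columns as in
#'   [feature_table_columns()].
#' @export
cohort_feature_table <- function(manifest, thresholds, labelmap_dir = NULL) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  pair_for <- function(tp) {
    if (inherits(thresholds, "threshold_pair")) thresholds else thresholds[[tp]]
  }
  if (!is.null(labelmap_dir) && !dir.exists(labelmap_dir)) {
    dir.create(labelmap_dir, recursive = TRUE)
  }
  rows <- vector("list", nrow(manifest))
  failures <- character(0)
  for (i in seq_len(nrow(manifest))) {
    pid <- manifest$patient_id[i]
    res <- tryCatch({
      imgs <- load_patient_images(manifest[i, , drop = FALSE])
      feats <- lapply(c(pre = "pre", post = "post"), function(tp) {
        tpimg <- imgs[[tp]]
        pair <- pair_for(tp)
        wb <- binarize(tpimg$water, tpimg$mask, pair$t_water)
        fb <- binarize(tpimg$fat, tpimg$mask, pair$t_fat)
        lab <- combine_habitats(wb, fb, tpimg$mask, pair)
        if (!is.null(labelmap_dir)) {
          write_labelmap(lab, file.path(labelmap_dir,
                                        sprintf("%s_%s_habitats.nii.gz", pid, tp)))
        }
        extract_features(lab)
      })
      lf <- longitudinal_changes(feats$pre, feats$post)
      c(list(patient_id = pid, response = manifest$response[i]),
        flatten_longitudinal(lf))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", pid, conditionMessage(res)))
    } else {
      rows[[i]] <- res
    }
  }
  if (length(failures) > 0) {
    stop(sprintf("feature extraction failed for %d patient(s):\n%s",
                 length(failures), paste(failures, collapse = "\n")), call. = FALSE)
  }
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[, feature_table_columns()]
}
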