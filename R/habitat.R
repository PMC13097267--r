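#' Resample a volume onto a reference grid
#'
#' Maps the reference voxel centres into the moving image's index space
#' (both grids axis-aligned) and interpolates. `mode = "linear"` does
#' trilinear interpolation and is meant for intensity channels;
#' `mode = "nearest"` must be used for masks so values stay in `{0, 1}`.
#' Reference voxels falling outside the moving grid are set to 0.
#'
#' @param moving [scalar_volume()] or [seg_mask()] to be resampled.
#' @param reference [scalar_volume()] or [seg_mask()] defining the target grid.
#' @param mode `"linear"` or `"nearest"`.
#' @return A volume/mask of the same class as `moving`, on the reference grid.
#' @export
resample_to_reference <- function(moving, reference, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  if (inherits(moving, "seg_mask") && mode != "nearest") {
    stop("masks must be resampled with mode = 'nearest'", call. = FALSE)
  }
  rd <- dim(reference$data)
  md <- dim(moving$data)
  if (any(rd < 1L)) stop("degenerate reference grid", call. = FALSE)
  # continuous (1-based) voxel coordinate of each reference centre in the
  # moving grid, per axis
  u <- lapply(1:3, function(k) {
    w <- reference$origin[k] + (seq_len(rd[k]) - 1) * reference$spacing[k]
    (w - moving$origin[k]) / moving$spacing[k] + 1
  })
  expand_axis <- function(v, k) {
    if (k == 1) array(rep(v, times = rd[2] * rd[3]), dim = rd)
    else if (k == 2) array(rep(rep(v, each = rd[1]), times = rd[3]), dim = rd)
    else array(rep(v, each = rd[1] * rd[2]), dim = rd)
  }
  # gather with zero fill outside the moving grid
  gather <- function(ix, iy, iz, w = NULL) {
    ok <- ix >= 1L & ix <= md[1] & iy >= 1L & iy <= md[2] & iz >= 1L & iz <= md[3]
    out <- numeric(length(ix))
    lin <- (ix[ok] - 1L) + (iy[ok] - 1L) * md[1] + (iz[ok] - 1L) * md[1] * md[2] + 1
    out[ok] <- moving$data[lin]
    if (!is.null(w)) out <- out * w
    out
  }
  if (mode == "nearest") {
    ix <- round(expand_axis(u[[1]], 1))
    iy <- round(expand_axis(u[[2]], 2))
    iz <- round(expand_axis(u[[3]], 3))
    res <- array(gather(ix, iy, iz), dim = rd)
  } else {
    ux <- expand_axis(u[[1]], 1); uy <- expand_axis(u[[2]], 2); uz <- expand_axis(u[[3]], 3)
    fx <- floor(ux); fy <- floor(uy); fz <- floor(uz)
    tx <- ux - fx; ty <- uy - fy; tz <- uz - fz
    res <- numeric(prod(rd))
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      w <- (if (cx) tx else 1 - tx) * (if (cy) ty else 1 - ty) * (if (cz) tz else 1 - tz)
      res <- res + gather(fx + cx, fy + cy, fz + cz, w)
    }
    res <- array(res, dim = rd)
  }
  res[res < 0] <- 0  # guard against tiny negative interpolation round-off
  if (inherits(moving, "seg_mask")) {
    seg_mask(res, reference$spacing, reference$origin)
  } else {
    scalar_volume(res, reference$spacing, reference$origin)
  }
}

#' Equal-width intensity histogram
#'
#' @param bin_edges Strictly increasing numeric vector of length `B + 1`;
#'   bins must be equal-width within `1e-9`.
#' @param counts Non-negative counts of length `B`.
#' @return An `intensity_histogram` object.
#' @export
intensity_histogram <- function(bin_edges, counts) {
  bin_edges <- as.numeric(bin_edges)
  counts <- as.numeric(counts)
  if (length(bin_edges) != length(counts) + 1L) {
    stop("bin_edges must have length(counts) + 1 entries", call. = FALSE)
  }
  widths <- diff(bin_edges)
  if (any(widths <= 0)) stop("bin_edges must be strictly increasing", call. = FALSE)
  if (diff(range(widths)) > 1e-9 * max(widths)) {
    stop("bins must be equal-width", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(list(bin_edges = bin_edges, counts = counts),
            class = "intensity_histogram")
}

#' Pooled in-mask histogram over a cohort
#'
#' Pools the in-mask voxel intensities of every volume/mask pair and bins
#' them into `bins` equal-width bins spanning the pooled intensity range.
#' This is the voxel pool from which cohort-level thresholds are derived:
#' all delineated muscle voxels of all subjects, per channel.
#'
#' @param volumes List of [scalar_volume()]s.
#' @param masks List of [seg_mask()]s, pairwise aligned with `volumes`.
#' @param bins Number of bins (default 256).
#' @return An [intensity_histogram()].
#' @export
pooled_histogram <- function(volumes, masks, bins = 256L) {
  if (length(volumes) != length(masks)) {
    stop("'volumes' and 'masks' must have the same length", call. = FALSE)
  }
  if (length(volumes) == 0) stop("empty voxel pool", call. = FALSE)
  bins <- as.integer(bins)
  if (bins < 1L) stop("'bins' must be positive", call. = FALSE)
  vals <- unlist(lapply(seq_along(volumes), function(i) {
    v <- volumes[[i]]; m <- masks[[i]]
    if (!validate_aligned(v, m)) {
      stop(sprintf("volume/mask pair %d is not aligned", i), call. = FALSE)
    }
    v$data[m$data == 1]
  }), use.names = FALSE)
  if (length(vals) == 0) stop("empty voxel pool (no in-mask voxels)", call. = FALSE)
  rng <- range(vals)
  if (diff(rng) <= 0) stop("zero-width intensity range in voxel pool", call. = FALSE)
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  idx <- findInterval(vals, edges, rightmost.closed = TRUE)
  idx[idx > bins] <- bins
  intensity_histogram(edges, tabulate(idx, nbins = bins))
}

#' Otsu threshold of an intensity histogram
#'
#' Scans every cut position between adjacent bins and returns the threshold
#' maximizing the between-class variance
#' \eqn{\sigma^2_B(t) = \omega_0 \omega_1 (\mu_0 - \mu_1)^2}, where
#' \eqn{\omega} are the class probabilities and \eqn{\mu} the class mean
#' intensities (bin centres) of the histogram split at \eqn{t}. Because the
#' total variance is constant in \eqn{t}, this equivalently minimizes the
#' within-class variance. The returned threshold is the upper edge of the
#' last "low" bin, so downstream binarization does not depend on how values
#' were binned; exact ties are broken toward the smallest threshold.
#'
#' @param hist An [intensity_histogram()] with positive total count and at
#'   least two non-empty bins.
#' @return A single numeric threshold, strictly inside the histogram range.
#' @export
otsu_threshold <- function(hist) {
  stopifnot(inherits(hist, "intensity_histogram"))
  counts <- hist$counts
  if (sum(counts) <= 0) stop("histogram has no mass", call. = FALSE)
  if (sum(counts > 0) < 2L) {
    stop("all histogram mass in one bin: no valid split", call. = FALSE)
  }
  sigma <- otsu_between_class_variance(hist)
  k <- which.max(sigma)        # first maximum = smallest threshold
  hist$bin_edges[k + 1L]
}

# between-class variance at every cut position k (low = bins 1..k),
# -Inf where one class is empty; shared by otsu_threshold and its tests
otsu_between_class_variance <- function(hist) {
  counts <- hist$counts
  B <- length(counts)
  p <- counts / sum(counts)
  mids <- (hist$bin_edges[-1] + hist$bin_edges[-(B + 1L)]) / 2
  w0 <- cumsum(p)[-B]
  s0 <- cumsum(p * mids)[-B]
  mu_tot <- sum(p * mids)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- ifelse(valid, s0 / w0, 0)
  mu1 <- ifelse(valid, (mu_tot - s0) / w1, 0)
  sigma <- w0 * w1 * (mu0 - mu1)^2
  sigma[!valid] <- -Inf
  if (!any(is.finite(sigma))) stop("no valid split position", call. = FALSE)
  sigma
}

#' Threshold pair for the water and fat channels
#'
#' @param t_water,t_fat Otsu thresholds in the intensity units of the
#'   respective channel.
#' @param provenance Free-form descriptor of the voxel pool used.
#' @return A `threshold_pair` object.
#' @export
threshold_pair <- function(t_water, t_fat, provenance = "") {
  stopifnot(is.numeric(t_water), is.numeric(t_fat),
            length(t_water) == 1, length(t_fat) == 1)
  structure(list(t_water = as.numeric(t_water), t_fat = as.numeric(t_fat),
                 provenance = provenance),
            class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf("<threshold_pair> t_water = %.6g, t_fat = %.6g (%s)\n",
              x$t_water, x$t_fat, x$provenance))
  invisible(x)
}

# Load one manifest row into aligned water/fat/mask triples per time point.
# The water grid is the reference: fat is resampled linearly onto it and the
# mask with nearest-neighbour, when not already aligned.
load_patient_images <- function(row) {
  one_tp <- function(water_path, fat_path, mask_path) {
    water <- read_volume(water_path)
    fat <- read_volume(fat_path)
    mask <- read_mask(mask_path)
    if (!validate_aligned(fat, water)) {
      fat <- resample_to_reference(fat, water, mode = "linear")
    }
    if (!validate_aligned(mask, water)) {
      mask <- resample_to_reference(mask, water, mode = "nearest")
    }
    if (sum(mask$data) == 0) {
      stop(sprintf("mask %s has no foreground voxels", mask_path), call. = FALSE)
    }
    list(water = water, fat = fat, mask = mask)
  }
  list(pre = one_tp(row$pre_water, row$pre_fat, row$mask_pre),
       post = one_tp(row$post_water, row$post_fat, row$mask_post))
}

#' Cohort-level water and fat thresholds
#'
#' Computes the Otsu threshold of the water channel and of the fat channel
#' independently, from the pooled in-mask voxels of every subject in the
#' manifest. By default both time points are pooled into a single pair of
#' thresholds, so that longitudinal changes are measured against a common
#' intensity partition; `pooling = "per_timepoint"` instead derives one pair
#' per time point.
#'
#' @param manifest A [read_manifest()] result.
#' @param bins Histogram bins (default 256).
#' @param pooling `"all_timepoints"` (default) or `"per_timepoint"`.
#' @return A [threshold_pair()], or for `"per_timepoint"` a list with
#'   elements `pre` and `post`, each a [threshold_pair()].
#' @export
compute_cohort_thresholds <- function(manifest, bins = 256L,
                                      pooling = c("all_timepoints", "per_timepoint")) {
  pooling <- match.arg(pooling)
  stopifnot(inherits(manifest, "cohort_manifest"))
  pools <- list(pre = list(water = list(), fat = list(), mask = list()),
                post = list(water = list(), fat = list(), mask = list()))
  for (i in seq_len(nrow(manifest))) {
    imgs <- load_patient_images(manifest[i, , drop = FALSE])
    for (tp in c("pre", "post")) {
      pools[[tp]]$water <- c(pools[[tp]]$water, list(imgs[[tp]]$water))
      pools[[tp]]$fat <- c(pools[[tp]]$fat, list(imgs[[tp]]$fat))
      pools[[tp]]$mask <- c(pools[[tp]]$mask, list(imgs[[tp]]$mask))
    }
  }
  pair_from <- function(waters, fats, masks, tag) {
    tw <- otsu_threshold(pooled_histogram(waters, masks, bins))
    tf <- otsu_threshold(pooled_histogram(fats, masks, bins))
    threshold_pair(tw, tf,
                   sprintf("%d subject-timepoints, %d bins, %s", length(waters), bins, tag))
  }
  if (pooling == "all_timepoints") {
    pair_from(c(pools$pre$water, pools$post$water),
              c(pools$pre$fat, pools$post$fat),
              c(pools$pre$mask, pools$post$mask),
              "all timepoints pooled")
  } else {
    list(pre = pair_from(pools$pre$water, pools$pre$fat, pools$pre$mask, "pre only"),
         post = pair_from(pools$post$water, pools$post$fat, pools$post$mask, "post only"))
  }
}

#' Binarize a channel inside the muscle mask
#'
#' In-mask voxels become 1 ("high") when their intensity is strictly above
#' the threshold, 0 otherwise; the threshold value itself counts as "low".
#' Out-of-mask voxels are always 0.
#'
#' @param vol A [scalar_volume()].
#' @param mask A [seg_mask()] aligned with `vol`.
#' @param t Intensity threshold.
#' @return A [seg_mask()] of the "high" voxels.
#' @export
binarize <- function(vol, mask, t) {
  if (!validate_aligned(vol, mask)) stop("volume and mask are not aligned", call. = FALSE)
  out <- (vol$data > t) & (mask$data == 1)
  seg_mask(array(as.numeric(out), dim = dim(vol$data)), vol$spacing, vol$origin)
}

#' Combine water and fat binarizations into habitat labels
#'
#' Each in-mask voxel is labelled by its (water, fat) high/low pair:
#' low/low = LL (1), high/low = HL (2), low/high = LH (3), high/high = HH (4).
#' Voxels outside the mask are 0. The partition is exhaustive: every in-mask
#' voxel receives exactly one habitat label.
#'
#' @param water_bin,fat_bin [seg_mask()]s from [binarize()] on the water and
#'   fat channels.
#' @param mask The muscle [seg_mask()].
#' @param thresholds Optional [threshold_pair()] recorded on the result.
#' @return A `habitat_labels` object: `data` (3D integer labels),
#'   geometry, and `thresholds`.
#' @export
combine_habitats <- function(water_bin, fat_bin, mask, thresholds = NULL) {
  if (!validate_aligned(water_bin, mask) || !validate_aligned(fat_bin, mask)) {
    stop("binarized channels and mask are not aligned", call. = FALSE)
  }
  w <- water_bin$data * mask$data
  f <- fat_bin$data * mask$data
  labels <- (1 + w + 2 * f) * mask$data
  habitat_labels(labels, mask$spacing, mask$origin, thresholds)
}

#' Habitat label map
#'
#' @param data 3D array with values in `{0, 1, 2, 3, 4}` (see
#'   [habitat_levels]).
#' @inheritParams scalar_volume
#' @param thresholds Optional [threshold_pair()] used to produce the labels.
#' @return A `habitat_labels` object.
#' @export
habitat_labels <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                           thresholds = NULL) {
  vol <- scalar_volume(data, spacing, origin)
  if (!all(vol$data %in% 0:4)) {
    stop("habitat labels must be integers 0..4", call. = FALSE)
  }
  structure(list(data = vol$data, spacing = vol$spacing, origin = vol$origin,
                 thresholds = thresholds),
            class = "habitat_labels")
}

#' @export
print.habitat_labels <- function(x, ...) {
  tab <- habitat_counts(x)
  cat(sprintf("<habitat_labels> %s voxels; LL %d, HL %d, LH %d, HH %d\n",
              paste(dim(x$data), collapse = "x"),
              tab["LL"], tab["HL"], tab["LH"], tab["HH"]))
  invisible(x)
}

#' Voxel counts per habitat
#'
#' @param labels A [habitat_labels()] object.
#' @return Named integer vector `c(LL=, HL=, LH=, HH=)`.
#' @export
habitat_counts <- function(labels) {
  stopifnot(inherits(labels, "habitat_labels"))
  counts <- tabulate(labels$data[labels$data > 0], nbins = 4L)
  names(counts) <- names(habitat_levels)
  counts
}

#' Write a habitat label map with its JSON sidecar
#'
#' The label map goes out as 8-bit integer NIfTI; a sidecar
#' `<path-with-.json>` records the label dictionary and, when known, the
#' thresholds used.
#'
#' @param labels A [habitat_labels()] object.
#' @param path Output NIfTI path.
#' @return `path`, invisibly.
#' @export
write_labelmap <- function(labels, path) {
  stopifnot(inherits(labels, "habitat_labels"))
  m <- seg_mask(array(0, dim = dim(labels$data)), labels$spacing, labels$origin)
  m$data <- labels$data  # reuse uint8 writing path for small integer labels
  write_volume(m, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- list(labels = as.list(habitat_levels))
  if (!is.null(labels$thresholds)) {
    meta$t_water <- labels$thresholds$t_water
    meta$t_fat <- labels$thresholds$t_fat
  }
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a habitat label map written by [write_labelmap()]
#'
#' @param path NIfTI path.
#' @return A [habitat_labels()] object (thresholds restored from the sidecar
#'   when present).
#' @export
read_labelmap <- function(path) {
  vol <- read_volume(path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  thr <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (!is.null(meta$t_water)) {
      thr <- threshold_pair(meta$t_water, meta$t_fat, "restored from sidecar")
    }
  }
  habitat_labels(vol$data, vol$spacing, vol$origin, thr)
}
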