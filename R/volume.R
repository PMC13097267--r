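#' Scalar signal-intensity volume
#'
#' A `scalar_volume` holds one channel (water or fat signal intensity) at one
#' time point: a 3D array of non-negative intensities plus the grid geometry
#' (voxel spacing in mm and world origin) needed to test alignment between
#' channels and masks.
#'
#' @param data 3D numeric array of non-negative signal intensities.
#' @param spacing Numeric length-3 voxel spacing `(dx, dy, dz)` in mm, all > 0.
#' @param origin Numeric length-3 world coordinate of the first voxel centre.
#' @return An object of class `scalar_volume` with elements `data`, `spacing`
#'   and `origin`.
#' @export
scalar_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as_volume_array(data)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("'spacing' must be three finite positive values (mm)", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("'origin' must be three finite values", call. = FALSE)
  }
  n_neg <- sum(data < 0)
  if (n_neg > 0) {
    stop(sprintf("volume contains %d negative-intensity voxel(s); signal intensities must be non-negative",
                 n_neg), call. = FALSE)
  }
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "scalar_volume")
}

#' Binary segmentation mask
#'
#' A `seg_mask` is a 3D array of 0/1 voxels (1 = extraocular-muscle tissue)
#' on the same grid-geometry descriptor as [scalar_volume()].
#'
#' @param data 3D array with values in `{0, 1}`.
#' @inheritParams scalar_volume
#' @return An object of class `seg_mask`.
#' @export
seg_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as_volume_array(data)
  if (!all(data %in% c(0, 1))) {
    stop("mask values must all be 0 or 1", call. = FALSE)
  }
  vol <- scalar_volume(data, spacing, origin)
  structure(list(data = vol$data, spacing = vol$spacing, origin = vol$origin),
            class = "seg_mask")
}

as_volume_array <- function(data) {
  if (is.null(dim(data)) || length(dim(data)) != 3L) {
    stop("volume data must be a 3-dimensional array", call. = FALSE)
  }
  if (any(dim(data) < 1L)) stop("every dimension must be >= 1", call. = FALSE)
  storage.mode(data) <- "double"
  data <- unclass(data)
  attributes(data) <- list(dim = dim(data))
  data
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume> %s voxels, spacing (%s) mm, intensity range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("<seg_mask> %s voxels, spacing (%s) mm, %d foreground\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              sum(x$data)))
  invisible(x)
}

geometry_of <- function(x) {
  list(dim = dim(x$data), spacing = x$spacing, origin = x$origin)
}

#' Read a NIfTI volume
#'
#' Reads a 3D NIfTI-1 image (`.nii` or `.nii.gz`). Spacing is taken from the
#' header `pixdim` and the origin from the translation column of the stored
#' transform. Negative intensities are rejected: water and fat
#' signal-intensity images are magnitude data.
#'
#' @param path Path to a NIfTI file.
#' @return A [scalar_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) {
    stop(sprintf("%s: expected a 3D image, got %d dimensions", path, length(dim(img))),
         call. = FALSE)
  }
  geo <- nifti_geometry(img)
  arr <- array(as.numeric(img), dim = dim(img))
  n_neg <- sum(arr < 0)
  if (n_neg > 0) {
    stop(sprintf("%s: %d voxel(s) with negative intensity; refusing to load", path, n_neg),
         call. = FALSE)
  }
  scalar_volume(arr, geo$spacing, geo$origin)
}

#' Read a NIfTI segmentation mask
#'
#' @param path Path to a NIfTI file whose voxels are all 0 or 1.
#' @return A [seg_mask()].
#' @export
read_mask <- function(path) {
  vol <- read_volume(path)
  seg_mask(vol$data, vol$spacing, vol$origin)
}

#' Write a volume or mask as NIfTI-1
#'
#' Volumes are written as 32-bit float, masks as 8-bit unsigned integer.
#' Spacing goes to `pixdim`, the origin to the qform translation.
#'
#' @param x A [scalar_volume()] or [seg_mask()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "scalar_volume") || inherits(x, "seg_mask"))
  img <- RNifti::asNifti(x$data)
  RNifti::pixdim(img) <- x$spacing
  m <- diag(4)
  m[1:3, 1:3] <- diag(x$spacing)
  m[1:3, 4] <- x$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  dtype <- if (inherits(x, "seg_mask")) "uint8" else "float"
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

nifti_geometry <- function(img) {
  spacing <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  list(spacing = abs(as.numeric(spacing)), origin = as.numeric(xf[1:3, 4]))
}

#' Test grid alignment of two volumes/masks
#'
#' Two images are aligned when their array shapes match and their voxel
#' spacings and origins agree within `tol` mm. Alignment is required before
#' any voxelwise combination of channels and masks, mirroring the voxel-level
#' registration check done after resampling.
#'
#' @param a,b [scalar_volume()] or [seg_mask()] objects.
#' @param tol Geometric tolerance in mm (default `1e-4`; header floats differ
#'   at machine precision across writers).
#' @return `TRUE` or `FALSE`.
#' @export
validate_aligned <- function(a, b, tol = 1e-4) {
  ga <- geometry_of(a)
  gb <- geometry_of(b)
  identical(ga$dim, gb$dim) &&
    all(abs(ga$spacing - gb$spacing) <= tol) &&
    all(abs(ga$origin - gb$origin) <= tol)
}

manifest_required_cols <- c("patient_id", "response",
                            "pre_water", "pre_fat", "post_water", "post_fat",
                            "mask_pre", "mask_post")
manifest_path_cols <- manifest_required_cols[-(1:2)]

#' Read and validate a cohort manifest
#'
#' The manifest is a CSV with one row per patient and the columns
#' `patient_id`, `response` (exactly `"responsive"` or `"unresponsive"`),
#' and the six file paths `pre_water`, `pre_fat`, `post_water`, `post_fat`,
#' `mask_pre`, `mask_post`. Relative paths are resolved against the
#' manifest's own directory. Extra columns (clinical covariates) pass
#' through untouched.
#'
#' @param path Path to the manifest CSV.
#' @param check_paths If `TRUE` (default) every referenced file must exist.
#' @return A `data.frame` with class `cohort_manifest`; row order preserved,
#'   path columns resolved to absolute paths.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(manifest_required_cols, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("manifest is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0) stop("manifest has no rows", call. = FALSE)
  dup <- duplicated(df$patient_id)
  if (any(dup)) {
    stop(sprintf("duplicate patient_id at row(s) %s: %s",
                 paste(which(dup), collapse = ", "),
                 paste(unique(df$patient_id[dup]), collapse = ", ")), call. = FALSE)
  }
  bad_lab <- !df$response %in% c("responsive", "unresponsive")
  if (any(bad_lab)) {
    stop(sprintf("unknown response label at row(s) %s: %s (allowed: responsive, unresponsive)",
                 paste(which(bad_lab), collapse = ", "),
                 paste(unique(df$response[bad_lab]), collapse = ", ")), call. = FALSE)
  }
  base_dir <- dirname(normalizePath(path))
  extra_path_cols <- intersect(c("truth_pre", "truth_post"), names(df))
  for (col in c(manifest_path_cols, extra_path_cols)) {
    rel <- !grepl("^(/|[A-Za-z]:)", df[[col]])
    df[[col]][rel] <- file.path(base_dir, df[[col]][rel])
  }
  if (check_paths) {
    for (col in manifest_path_cols) {
      missing <- !file.exists(df[[col]])
      if (any(missing)) {
        stop(sprintf("manifest column '%s': file(s) not found at row(s) %s: %s",
                     col, paste(which(missing), collapse = ", "),
                     paste(df[[col]][missing], collapse = ", ")), call. = FALSE)
      }
    }
  }
  class(df) <- c("cohort_manifest", "data.frame")
  df
}
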