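#' Specification of a synthetic orbital phantom
#'
#' Describes one water/fat phantom: grid, voxel spacing, an ellipsoidal
#' "muscle" mask, per-tissue-class mean intensities in the two channels,
#' additive Gaussian noise, and the volume fraction of each habitat class.
#' The class means must respect the habitat semantics (edema = high water /
#' low fat, myosteatosis = low water / high fat, and so on).
#'
#' @param shape Grid dimensions (default `c(48, 48, 15)`; 15 slices echoes a
#'   coronal orbital acquisition).
#' @param spacing Voxel spacing in mm (default `c(0.625, 0.625, 3.6)`:
#'   0.625 mm in-plane, 3 mm slices + 0.6 mm gap).
#' @param radii_mm Ellipsoid semi-axes of the mask in mm (default
#'   `c(9, 9, 11.5)`, giving a muscle volume of about 3.9 mL).
#' @param class_means 4 x 2 matrix of mean intensities, rows `LL, HL, LH,
#'   HH`, columns `water, fat` (defaults: low = 30, high = 80).
#' @param noise_sd Gaussian noise SD added to both channels (default 5, i.e.
#'   a 10-SD separation between low and high class means).
#' @param fractions Volume fractions of `LL, HL, LH, HH`, summing to 1.
#' @param background_mean Mean intensity outside the mask (default 5).
#' @param layout `"slabs"` (contiguous compartments along the slice axis,
#'   default) or `"mixed"` (voxelwise random class assignment, for
#'   threshold stress tests).
#' @param seed Optional integer; when non-NULL, [generate_phantom()] seeds
#'   the RNG with it.
#' @return A validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(48L, 48L, 15L),
                         spacing = c(0.625, 0.625, 3.6),
                         radii_mm = c(9, 9, 11.5),
                         class_means = default_class_means(),
                         noise_sd = 5,
                         fractions = c(LL = 0.25, HL = 0.25, LH = 0.25, HH = 0.25),
                         background_mean = 5,
                         layout = c("slabs", "mixed"),
                         seed = NULL) {
  layout <- match.arg(layout)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1),
            length(spacing) == 3, all(spacing > 0),
            length(radii_mm) == 3, all(radii_mm > 0),
            is.matrix(class_means), all(dim(class_means) == c(4, 2)),
            length(noise_sd) == 1, noise_sd >= 0,
            length(fractions) == 4)
  fractions <- as.numeric(fractions)
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be non-negative and sum to 1", call. = FALSE)
  }
  names(fractions) <- names(habitat_levels)
  rownames(class_means) <- names(habitat_levels)
  colnames(class_means) <- c("water", "fat")
  w <- class_means[, "water"]; f <- class_means[, "fat"]
  if (!(w["HL"] > w["LL"] && w["HL"] > w["LH"] &&
        w["HH"] > w["LL"] && w["HH"] > w["LH"] &&
        f["LH"] > f["LL"] && f["LH"] > f["HL"] &&
        f["HH"] > f["LL"] && f["HH"] > f["HL"])) {
    stop("class means violate habitat semantics (water high for HL/HH, fat high for LH/HH)",
         call. = FALSE)
  }
  if (any(class_means < 0) || background_mean < 0) {
    stop("mean intensities must be non-negative", call. = FALSE)
  }
  structure(list(shape = shape, spacing = spacing, radii_mm = radii_mm,
                 class_means = class_means, noise_sd = noise_sd,
                 fractions = fractions, background_mean = background_mean,
                 layout = layout, seed = seed),
            class = "phantom_spec")
}

#' Default habitat class mean intensities
#'
#' @return 4 x 2 matrix (rows LL, HL, LH, HH; columns water, fat) with low
#'   means of 30 and high means of 80 arbitrary signal-intensity units.
#' @export
default_class_means <- function() {
  m <- rbind(LL = c(30, 30), HL = c(80, 30), LH = c(30, 80), HH = c(80, 80))
  colnames(m) <- c("water", "fat")
  m
}

ellipsoid_mask_array <- function(shape, spacing, radii_mm) {
  centre <- (shape - 1) / 2 * spacing
  ax <- lapply(1:3, function(k) ((seq_len(shape[k]) - 1) * spacing[k] - centre[k]) / radii_mm[k])
  d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  array(as.numeric(d2 <= 1), dim = shape)
}

# largest-remainder apportionment of n voxels to the class fractions;
# fractions too small for even half a voxel quantize to zero voxels
largest_remainder_counts <- function(fractions, n) {
  if (n < sum(fractions > 0)) {
    stop("mask too small to represent every nonzero class fraction", call. = FALSE)
  }
  exact <- fractions * n
  counts <- floor(exact)
  short <- n - sum(counts)
  if (short > 0) {
    ord <- order(exact - counts, decreasing = TRUE)
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  as.integer(counts)
}

#' Generate one synthetic water/fat phantom
#'
#' Builds an ellipsoidal muscle mask, partitions its voxels into the four
#' habitat classes at the spec's volume fractions (largest-remainder
#' rounding to whole voxels; contiguous slabs along the slice axis unless
#' `layout = "mixed"`), and simulates both channels as class mean plus
#' Gaussian noise. Negative simulated intensities are clipped to 0, as in
#' magnitude MR images.
#'
#' @param spec A [phantom_spec()].
#' @return List with `water` and `fat` ([scalar_volume()]s), `mask`
#'   ([seg_mask()]) and `truth` (a [habitat_labels()] map of the planted
#'   classes).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  mask_arr <- ellipsoid_mask_array(spec$shape, spec$spacing, spec$radii_mm)
  idx <- which(mask_arr == 1)  # linear order: x fastest, slice index slowest
  n <- length(idx)
  if (n == 0) stop("ellipsoid mask is empty on this grid", call. = FALSE)
  counts <- largest_remainder_counts(spec$fractions, n)
  class_of <- rep.int(1:4, counts)
  if (spec$layout == "mixed") class_of <- sample(class_of)
  truth_arr <- array(0, dim = spec$shape)
  truth_arr[idx] <- class_of
  simulate_channel <- function(col) {
    arr <- array(spec$background_mean, dim = spec$shape)
    arr[idx] <- spec$class_means[class_of, col]
    if (spec$noise_sd > 0) arr <- arr + stats::rnorm(length(arr), 0, spec$noise_sd)
    arr[arr < 0] <- 0
    arr
  }
  water <- simulate_channel("water")
  fat <- simulate_channel("fat")
  list(water = scalar_volume(water, spec$spacing),
       fat = scalar_volume(fat, spec$spacing),
       mask = seg_mask(mask_arr, spec$spacing),
       truth = habitat_labels(truth_arr, spec$spacing))
}

#' Longitudinal remodeling archetype
#'
#' Captures how a patient's habitat composition and overall muscle volume
#' change from the pre- to the post-therapy scan. The responder archetype
#' must shrink its edema (HL) fraction, grow its myosteatosis (LH) fraction
#' and shrink overall; the non-responder archetype must grow overall with a
#' growing fibrosis-like (LL) compartment.
#'
#' @param name `"responder"` or `"non_responder"`.
#' @param pre_fractions,post_fractions Habitat fractions (LL, HL, LH, HH)
#'   at the two time points, each summing to 1.
#' @param whole_volume_change Ratio of post to pre whole-muscle volume.
#' @return A validated list of class `remodeling_archetype`.
#' @export
remodeling_archetype <- function(name = c("responder", "non_responder"),
                                 pre_fractions, post_fractions,
                                 whole_volume_change) {
  name <- match.arg(name)
  chk <- function(fr, what) {
    fr <- as.numeric(fr)
    if (length(fr) != 4 || any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
      stop(sprintf("%s must be 4 non-negative fractions summing to 1", what), call. = FALSE)
    }
    stats::setNames(fr, names(habitat_levels))
  }
  pre_fractions <- chk(pre_fractions, "pre_fractions")
  post_fractions <- chk(post_fractions, "post_fractions")
  stopifnot(length(whole_volume_change) == 1, whole_volume_change > 0)
  if (name == "responder") {
    ok <- post_fractions["HL"] < pre_fractions["HL"] &&
      post_fractions["LH"] > pre_fractions["LH"] &&
      whole_volume_change < 1
    if (!ok) stop("responder archetype must shrink HL, grow LH and shrink overall",
                  call. = FALSE)
  } else {
    ok <- whole_volume_change > 1 &&
      post_fractions["LL"] * whole_volume_change > pre_fractions["LL"]
    if (!ok) stop("non_responder archetype must grow overall with growing LL volume",
                  call. = FALSE)
  }
  structure(list(name = name, pre_fractions = pre_fractions,
                 post_fractions = post_fractions,
                 whole_volume_change = whole_volume_change),
            class = "remodeling_archetype")
}

#' Default responder archetype
#'
#' Starts edema-dominant (HL 38% of the muscle), ends with edema collapsed
#' to 12%, myosteatosis more than doubled (7% to 16%) and the whole muscle
#' 11% smaller - the remodeling pattern of a treated patient whose orbital
#' inflammation resolves.
#'
#' @return A [remodeling_archetype()].
#' @export
responder_archetype <- function() {
  remodeling_archetype("responder",
                       pre_fractions = c(0.50, 0.38, 0.07, 0.05),
                       post_fractions = c(0.68, 0.12, 0.16, 0.04),
                       whole_volume_change = 0.89)
}

#' Default non-responder archetype
#'
#' The muscle keeps swelling (+11% volume) and the inactive/fibrosis-like
#' LL compartment expands, with little net change elsewhere.
#'
#' @return A [remodeling_archetype()].
#' @export
nonresponder_archetype <- function() {
  remodeling_archetype("non_responder",
                       pre_fractions = c(0.740, 0.155, 0.090, 0.015),
                       post_fractions = c(0.865, 0.054, 0.079, 0.002),
                       whole_volume_change = 1.11)
}

#' Generate the pre/post image pair of one synthetic patient
#'
#' The pre-therapy phantom uses the archetype's pre fractions; the
#' post-therapy phantom uses its post fractions with the mask volume scaled
#' by `whole_volume_change` (semi-axes scaled by its cube root).
#'
#' @param archetype A [remodeling_archetype()].
#' @param spec Base [phantom_spec()]; its `fractions` are ignored. When
#'   `spec$seed` is non-NULL the RNG is seeded once before the pre phantom.
#' @return List with `pre` and `post`, each a [generate_phantom()] result.
#' @export
generate_patient <- function(archetype, spec = phantom_spec()) {
  stopifnot(inherits(archetype, "remodeling_archetype"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  pre_spec <- spec
  pre_spec$fractions <- archetype$pre_fractions
  pre_spec$seed <- NULL
  post_spec <- pre_spec
  post_spec$fractions <- archetype$post_fractions
  post_spec$radii_mm <- spec$radii_mm * archetype$whole_volume_change^(1 / 3)
  list(pre = generate_phantom(pre_spec), post = generate_phantom(post_spec))
}

# one draw from Dirichlet(alpha); zero alphas stay exactly zero
rdirichlet_one <- function(alpha) {
  g <- numeric(length(alpha))
  pos <- alpha > 0
  g[pos] <- stats::rgamma(sum(pos), shape = alpha[pos])
  if (sum(g) == 0) g[pos] <- 1  # degenerate guard; keeps the simplex valid
  g / sum(g)
}

#' Generate a longitudinal synthetic cohort on disk
#'
#' Simulates `n_responsive` patients from the responder archetype and
#' `n_unresponsive` from the non-responder archetype, writes every volume,
#' mask and ground-truth label map as NIfTI under `out_dir`, and writes a
#' `manifest.csv` consumable by [read_manifest()].
#'
#' Per-patient heterogeneity has three seeded components: habitat fractions
#' are drawn from a Dirichlet distribution centred on the archetype
#' fractions (concentration `jitter`; larger = tighter around the
#' archetype), the whole-volume change factor gets log-normal jitter
#' (`volume_jitter_sd` on the log scale), and the baseline muscle size gets
#' log-normal jitter (`size_jitter_sd`).
#'
#' @param n_responsive,n_unresponsive Patients per group (each >= 1).
#' @param out_dir Output directory (created if needed).
#' @param base_spec Base [phantom_spec()] shared by all patients.
#' @param responder,non_responder The two [remodeling_archetype()]s.
#' @param jitter Dirichlet concentration for fraction jitter (default 120;
#'   0 disables jitter).
#' @param volume_jitter_sd Log-scale SD of the whole-volume-change factor
#'   (default 0.05).
#' @param size_jitter_sd Log-scale SD of the baseline muscle volume
#'   (default 0.10).
#' @param seed Integer RNG seed for the whole cohort.
#' @return Path of the written manifest CSV, invisibly; the manifest also
#'   gains `truth_pre`/`truth_post` columns pointing at the planted label
#'   maps.
#' @export
generate_cohort <- function(n_responsive, n_unresponsive, out_dir,
                            base_spec = phantom_spec(),
                            responder = responder_archetype(),
                            non_responder = nonresponder_archetype(),
                            jitter = 120, volume_jitter_sd = 0.05,
                            size_jitter_sd = 0.10, seed = 1L) {
  stopifnot(n_responsive >= 1, n_unresponsive >= 1)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(seed)
  labels <- c(rep("responsive", n_responsive), rep("unresponsive", n_unresponsive))
  archetypes <- list(responsive = responder, unresponsive = non_responder)
  rows <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    pid <- sprintf("P%03d", i)
    arch <- archetypes[[labels[i]]]
    pre_fr <- if (jitter > 0) rdirichlet_one(jitter * arch$pre_fractions) else arch$pre_fractions
    post_fr <- if (jitter > 0) rdirichlet_one(jitter * arch$post_fractions) else arch$post_fractions
    wvc <- arch$whole_volume_change *
      (if (volume_jitter_sd > 0) exp(stats::rnorm(1, 0, volume_jitter_sd)) else 1)
    size <- if (size_jitter_sd > 0) exp(stats::rnorm(1, 0, size_jitter_sd)) else 1
    pre_spec <- base_spec
    pre_spec$seed <- NULL
    pre_spec$fractions <- stats::setNames(pre_fr, names(habitat_levels))
    pre_spec$radii_mm <- base_spec$radii_mm * size^(1 / 3)
    post_spec <- pre_spec
    post_spec$fractions <- stats::setNames(post_fr, names(habitat_levels))
    post_spec$radii_mm <- pre_spec$radii_mm * wvc^(1 / 3)
    pre <- generate_phantom(pre_spec)
    post <- generate_phantom(post_spec)
    paths <- c(pre_water = sprintf("%s_pre_water.nii.gz", pid),
               pre_fat = sprintf("%s_pre_fat.nii.gz", pid),
               post_water = sprintf("%s_post_water.nii.gz", pid),
               post_fat = sprintf("%s_post_fat.nii.gz", pid),
               mask_pre = sprintf("%s_mask_pre.nii.gz", pid),
               mask_post = sprintf("%s_mask_post.nii.gz", pid),
               truth_pre = sprintf("%s_truth_pre.nii.gz", pid),
               truth_post = sprintf("%s_truth_post.nii.gz", pid))
    write_volume(pre$water, file.path(out_dir, paths["pre_water"]))
    write_volume(pre$fat, file.path(out_dir, paths["pre_fat"]))
    write_volume(post$water, file.path(out_dir, paths["post_water"]))
    write_volume(post$fat, file.path(out_dir, paths["post_fat"]))
    write_volume(pre$mask, file.path(out_dir, paths["mask_pre"]))
    write_volume(post$mask, file.path(out_dir, paths["mask_post"]))
    write_labelmap(pre$truth, file.path(out_dir, paths["truth_pre"]))
    write_labelmap(post$truth, file.path(out_dir, paths["truth_post"]))
    rows[[i]] <- data.frame(patient_id = pid, response = labels[i],
                            t(paths), stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)
  invisible(manifest_path)
}
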