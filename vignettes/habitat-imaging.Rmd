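---
title: "Water–fat habitat imaging of extraocular muscles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water–fat habitat imaging of extraocular muscles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eomhabitat)
```

## The problem

Thyroid eye disease swells and remodels the extraocular muscles (EOMs).
Histologically the remodeling is heterogeneous: hydrophilic
glycosaminoglycan accumulation (edema) during the active phase, adipogenic
differentiation (myosteatosis) and collagen deposition (fibrosis) as the
disease evolves. Water–fat separation MRI observes this mix indirectly: a
voxel rich in free water is bright in the water-signal image, a voxel rich
in fat is bright in the fat-signal image. Habitat imaging turns that
observation into a quantitative tissue partition. `eomhabitat` implements
the full analysis — cohort-level thresholding, four-way partition,
longitudinal volumetrics, and response-marker statistics — plus a synthetic
phantom generator that provides voxel-level ground truth for all of it.

## The habitat model

Each muscle voxel carries a pair (SI~water~, SI~fat~). Two cohort-level
thresholds, one per channel, classify each coordinate as low or high, and
the four combinations define the habitats:

| habitat | water | fat | reading |
|---------|-------|-----|---------|
| LL | low | low | inactive / fibrosis-like tissue |
| HL | high | low | edema |
| LH | low | high | myosteatosis |
| HH | high | high | water–fat interface |

The biological identification of HL with edema and LH with myosteatosis
follows the established correlations between water-image signal and
glycosaminoglycan content, and between fat fraction and fatty infiltration,
in these muscles. LL is intentionally ambiguous: both fibrotic tissue and
muscle in post-inflammatory resolution are dark in both channels, and the
method cannot separate them — a recognized limitation of
intensity-threshold habitats.

Thresholds are computed by Otsu's criterion on the pooled in-mask histogram
of each channel **independently**: the cut maximizing
$\sigma^2_B(t)=\omega_0\omega_1(\mu_0-\mu_1)^2$, with class probabilities
$\omega$ and class means $\mu$ taken from the histogram split at $t$. Since
the total variance is constant in $t$, this is equivalent to minimizing the
within-class variance — a fact the test suite exploits.

## Tunable parameters

* **`bins` (default 256).** Equal-width bins spanning the pooled in-mask
  range. 256 is the classical choice for Otsu on 8-bit-like data; on the
  phantoms, recovery is insensitive between 64 and 1024 bins because the
  channel histograms are strongly bimodal.
* **`pooling` (default `"all_timepoints"`).** Whether the threshold pool
  contains both the pre- and post-therapy scans. Pooling both is the
  default because longitudinal Δ features are only comparable when the same
  intensity partition is applied at both time points; `"per_timepoint"` is
  available for sensitivity analyses.
* **Geometry tolerance (1e-4 mm).** Spacings and origins from different
  NIfTI writers differ at float precision; anything below a tenth of a
  micron is treated as identical.
* **Marker features (default `d_volume_LH`, `dpct_volume_whole`).** The
  absolute change in myosteatosis volume and the relative change in
  whole-region volume, the two features entering the logistic response
  model.

## Numerical conventions

* **Boundary rule.** A voxel is "high" iff its intensity is strictly
  greater than the threshold; the threshold value itself is low. One side
  must be closed, and closing the low side keeps a constant image at the
  threshold entirely low.
* **Threshold placement.** The returned threshold is the upper edge of the
  last low bin, so binarization does not depend on within-bin
  interpolation. Exact ties in $\sigma^2_B$ resolve to the smallest
  threshold — deterministic and reproducible across platforms.
* **Resampling.** When a patient's channels or mask are not on the water
  grid, they are resampled onto it (the water image is the delineation
  reference): trilinear for intensities, nearest-neighbour for masks, zero
  fill outside the source grid. No registration beyond grid resampling is
  attempted; inputs are assumed co-registered, as water–fat reconstructions
  are by construction.
* **Degenerate inputs.** Empty masks, single-spike histograms (no valid
  split), zero-width intensity ranges and constant statistical groups all
  raise informative errors or route to the conservative branch
  (constant groups go to the nonparametric test, since Shapiro–Wilk is
  undefined for them).
* **Missing Δ%.** Where a pre-therapy value is 0, the relative change is
  reported as missing (`NA`) — not 0, not infinite — and downstream
  statistics drop such values pairwise, preserving the patient's other
  features.

## Statistical stage

* **Gated comparisons.** Shapiro–Wilk at α = 0.05 in every group decides
  between Student's t-test (mean ± SD summaries) and the Mann–Whitney U
  test (median (IQR) summaries), mirroring standard radiology practice.
  No multiple-testing correction is applied anywhere, matching the
  univariable screening design this pipeline reproduces.
* **ICC.** Measurement agreement uses the two-way random-effects,
  absolute-agreement, single-measure form (ICC(2,1)) with the F-based
  95% CI — the standard choice for intra-/inter-observer agreement when
  the variant is not otherwise specified. No R package for this form is
  among the package's dependencies, so the variance-component formulas are
  implemented directly and are verified in the tests against an
  independently computed fixture.
* **Correlation bands.** |r| < 0.40 poor, 0.40–0.60 moderate, 0.60–0.80
  good, ≥ 0.80 excellent; the band is a pure step function of |r|, tested
  exactly at the cut points.
* **ROC.** The AUC is the tie-aware concordance fraction (identical to the
  trapezoidal area under the empirical curve); the CI uses the DeLong
  variance, cross-checked against `pROC`. The operating cutoff is the
  observed score maximizing the Youden index, ties broken toward higher
  specificity, and is reported with its direction operator ("> c" when
  larger scores indicate response, "≤ c" otherwise). The combined logistic
  model is scored by fitted probability; it reports no cutoff because a
  probability threshold has no feature-unit interpretation, and AUC,
  sensitivity and specificity do not depend on the choice of fusion scale.
* **Separation.** Unpenalized logistic fits under (quasi-)separated designs
  are flagged (fitted probabilities numerically at 0/1) and marked
  non-converged rather than silently reported.
* **Evaluation is in-sample** — no cross-validation — because the pipeline
  reproduces a marker-screening analysis, not a prediction claim. Permuted
  labels therefore do not push the combined model's in-sample AUC all the
  way to 0.5: refitting on permuted labels keeps a small overfitting bias
  (about +0.06–0.11 at n = 40–100 with two features), which the acceptance
  checks account for by averaging over permutations.

## Bilateral muscles

Clinical manifests carry one mask per patient per time point. Both orbits'
muscles are assumed merged into that single mask, so all features represent
the summed bilateral musculature. Per-orbit analyses would require
multi-label masks, which are out of scope.

## The synthetic phantom generator

The generator is first-class, tested code: it is the package's only source
of ground truth.

* **Geometry.** A 48×48×15 grid at (0.625, 0.625, 3.6) mm — in-plane
  resolution and a 15-slice coronal stack with 3 mm slices + 0.6 mm gap,
  echoing a typical orbital acquisition. The "muscle" is an ellipsoid of
  semi-axes (9, 9, 11.5) mm ≈ 3.9 mL, matching reported whole-EOM volumes
  of 3–4 mL.
* **Classes.** Low/high class means are 30/80 arbitrary units with noise
  SD 5 per channel (a 10-SD separation). These are free parameters: real
  scanner units are arbitrary, and what matters for the method is the
  separation-to-noise ratio. Compartments are contiguous slabs along the
  slice axis so resampling tests see spatially coherent structure; a
  `"mixed"` voxelwise layout exists for threshold stress tests. Class
  fractions are apportioned to whole voxels by largest remainder; fractions
  smaller than half a voxel quantize to zero.
* **Remodeling archetypes.** The responder starts edema-dominant
  (LL/HL/LH/HH = 0.50/0.38/0.07/0.05), ends at 0.68/0.12/0.16/0.04 with the
  whole muscle at 0.89× its baseline volume — edema collapsing, myosteatosis
  roughly doubling, overall shrinkage. The non-responder grows (1.11×) with
  the LL compartment expanding (0.740/0.155/0.090/0.015 →
  0.865/0.054/0.079/0.002). These compositions and volume factors echo the
  median habitat compositions reported for treated TED cohorts.
* **Per-patient jitter.** Three seeded components: Dirichlet jitter of the
  class fractions around the archetype (concentration 120), log-normal
  jitter of the volume-change factor (SD 0.05) and of baseline muscle size
  (SD 0.10). The concentrations were chosen once, by design, so that a
  sampled patient keeps the archetype's remodeling directions (edema down,
  myosteatosis up for responders; net growth for non-responders) with
  roughly 98% probability — the generator's defining property. The
  consequence is deliberate: the synthetic cohort is **more homogeneous
  than a clinical one**, so group separations (AUCs near 1 for the
  whole-volume feature) are stronger than clinically reported values.
  Passing tests on these phantoms demonstrates correctness of the
  measurement chain, not clinical effect sizes.
* **What the phantoms do not emulate.** MRI physics (partial-volume
  averaging, bias fields, chemical-shift artifacts), anatomically realistic
  muscle shapes, per-muscle variation, and the broad, skewed heterogeneity
  of real TED cohorts. Results on real data will show wider IQRs and lower
  AUCs than the phantom suite.

## Problem sizes used in the checks

The test-suite and acceptance checks run at sizes chosen to exercise every
code path while completing comfortably on a laptop: 1,000 random histograms
for the Otsu oracle, 100 phantoms for volume-percentage recovery, 100
patients per archetype for remodeling directionality, a 20+20 cohort for
end-to-end discrimination with a 50+50 cohort for the permutation null, and
the full 84+54 study-scale cohort in `scripts/acceptance.R`.

## Known limitations

* Otsu thresholds are cohort-global; per-patient adaptive thresholds and
  multi-class Otsu are out of scope.
* The LL habitat conflates fibrosis with resolving inflammation (above).
* Recovery guarantees are probabilistic in the noise: at exactly 5-SD
  class-mean separation, the Gaussian overlap alone caps expected voxelwise
  label accuracy near 98.8%, even though volume percentages remain accurate
  to well under 2 points because misclassifications largely cancel.
* Bilateral sums only; no per-muscle breakdown; no texture/radiomics
  features beyond volumes and volume percentages.
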