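---
title: "Quantifying cell-shape signatures, YAP/TAZ translocation and adhesion dynamics with morphoscreen"
author: "morphoscreen maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell-shape signatures, YAP/TAZ translocation and adhesion dynamics with morphoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`morphoscreen` implements the downstream analysis of a multiplexed
high-content RNAi screen that relates perturbations of Rho-family GEFs and
GAPs to single-cell morphology and to the nuclear translocation of the
transcriptional co-activators YAP and TAZ, together with the bespoke
statistics used by the accompanying assays: a 3D collagen invasion index,
wound-heal Golgi polarity angles, focal-adhesion (FA) phase-rate fitting
with estimation statistics, and permutation-FDR differential proteomics.
Every stage can be exercised on synthetic data with exact ground truth;
nothing in the package requires the original microscopy or
mass-spectrometry files.

The analysis model, stage by stage:

1. **Single-cell quantification.** Nuclei are segmented from the smoothed
   DNA channel (Otsu threshold with a 6-MAD noise floor, distance-map
   watershed to split touching nuclei); cell bodies grow from nuclear
   seeds over the tubulin channel inside an automatic foreground mask
   (`EBImage::propagate`). Border-touching cells are flagged and removed.
   The perinuclear ring is the dilation of the nucleus minus the nucleus,
   clipped to the cell; the membrane band is the set of cell pixels within
   a fixed distance of the cell edge. The translocation readout is
   `log10(mean nuclear marker / mean ring marker)` after subtracting the
   field background (median of non-cell pixels).
2. **Features.** Per cell: area, perimeter (polygonal contour length),
   roundness `4*pi*A/P^2`, moment-based length/width/axial ratio,
   convex-hull solidity, a concavity-defect protrusion count, nucleus area
   and offset, and per channel a mean intensity plus eight SER-style
   texture responses from the scale-space Hessian. The registry holds 46
   named features; the published screen used 127, whose exact list is not
   public, so feature parity is not claimed — the classifier operates on
   whatever registry is configured.
3. **Shape classification.** A multinomial logistic (linear) rule with L2
   regularisation over standardised features, trained on labelled
   exemplar cells of the five reference shapes (spindly, large round,
   triangular, fan, small round). Marker-channel features are excluded so
   the translocation readout never informs the shape call. A "normal
   cell" filter is derived by PCA: the normal region is the axis-aligned
   1-SD box around the mean of (PC1, PC2); a binary linear classifier is
   trained with mock cells inside the box as normal. The per-well normal
   fraction is the penetrance readout.
4. **Screen scoring.** Per well: shape fractions over phenotypic
   (non-normal) cells, median ratio, normal fraction. Wells on the
   density-gradient columns (1, 2, 23, 24) and wells under the minimum
   cell count are excluded. Metrics are plate-normalised by subtracting
   the per-plate median of mock wells, then Z-scored against all mock
   wells of the screen: `Z = (x - mean_mock) / sd_mock`. The quantitative
   morphological signature (QMS) of a condition is the mean of its
   replicate-well Z-scores. Hits: ratio `Z >= +1.5` (high) or `<= -1.5`
   (low), thresholds inclusive; shape hits at normal-fraction `Z <= -1`.
5. **Phenoclusters.** Agglomerative clustering of QMS vectors on distance
   `1 - uncentered Pearson correlation` with average linkage; a
   phenocluster is a maximal subtree whose root merge similarity is
   strictly above 0.73. Singletons are allowed.
6. **Invasion.** Nuclei blobs per z-plane (planes 30 um apart, 0 um = plate
   bottom) are counted only when both the blob's nuclear and GFP mean
   intensities clear their thresholds; the invasion index is
   `sum(counts above bottom) / sum(all counts)`.
7. **FA dynamics.** Adhesions are thresholded per frame
   (background-subtracted; threshold = max(6 MAD, 5% of frame maximum))
   and linked by largest mask overlap, no gap closing; merges and splits
   terminate tracks. The peak frame is the argmax of the 3-frame
   median-smoothed intensity; assembly (birth to peak) and disassembly
   (peak to death) rates are least-squares slopes of `ln(intensity)`
   against time in minutes, disassembly reported positive; the stability
   phase is the contiguous run at or above 90% of peak. Tracks shorter
   than 5 frames or with mean axial ratio of 3 or more are discarded.
   Group comparisons use Hedges' g
   (`(mean_b - mean_a)/s_pooled * (1 - 3/(4(n_a+n_b)-9))`) with a BCa
   bootstrap 95% interval and a two-sided Mann-Whitney test; |g| bins:
   < 0.2 none, 0.2–0.5 S, 0.5–0.8 M, 0.8–1.2 L, >= 1.2 VL.
8. **Proteomics.** Protein abundances are log2-transformed, per-sample
   median-normalised and per-protein centred within each cell line; the
   log2 ratio is mean(perturbed) - mean(mock). Significance uses a Welch
   t statistic moderated by an additive fuzz `s0`, a permutation null
   over condition labels, and a SAM-style q-value (median permuted
   exceedance over observed exceedance, monotonised); proteins are called
   at `q < 0.05` and `|log2| > 0.5`, both bounds strict on the ratio.

# The synthetic-data generators

The generators are first-class, tested code and define the study
conditions under which the pipeline is validated.

* **Plates.** Each of the five shape archetypes is a parametric polar
  radius function: spindly = 26x8 px ellipse; large round = radius-20 px
  near-disk; triangular = three-lobed star (`0.4 + 0.6 max(cos 3phi, 0)`);
  fan = one-sided profile with the nucleus offset 0.25 of the cell radius
  toward the wide edge; small round = radius-11 px disk, all with ±10%
  size jitter and random orientation. Cells are laid on a jittered grid
  (border cells only when the margin is lowered). Class counts are
  multinomial in the well's mixture; the marker channel encodes
  `log10(nuclear/ring) = class baseline + well shift + N(0, 0.15)`, with
  class baselines (0.15, 0.05, 0.30, 0.20, 0.40) emulating
  shape-dependent translocation. Optics and camera: Gaussian blur
  (sigma 1 px), Poisson shot noise (500 photons at unit intensity) and
  Gaussian read noise (SD 0.005), giving SNR near 10 so that default
  segmentation succeeds — deliberately clean, so classifier accuracies
  here are upper bounds on real-data performance.
* **Screens (statistical layer).** `simulate_cell_table()` draws per-cell
  classes and ratios from exactly the model the renderer draws pixels
  from, adding a per-plate batch shift (SD 0.02 log10 units). Screen-scale
  experiments (hundreds of wells) use this layer; image-based checks use
  the renderer. Mock wells are interleaved across plates as in real
  screen layouts.
* **FA traces and movies.** Intensity rises as `exp(k_a t)` to a peak and
  decays as `exp(-k_d t)`, defaults k_a = 0.1/min, k_d = 0.05/min,
  frame interval 1.5 min, phase lengths 10–16 frames, additive noise SD
  0.1 of peak (SNR 10). Movies render each track as a small ellipse on a
  grid.
* **Invasion stacks** render nuclei + GFP blobs per plane with optional
  low-intensity decoys to exercise the dual filter.
* **Wound assays** place a fraction `polarity_bias` of Golgi on the
  inward wound normal (true angle 90 degrees) and the rest uniformly in
  [0, 180]; fronts move at a constant speed with optional noise.
* **Abundance tables** are log-normal with spiked log2 effects; defaults
  3 replicates per condition, measurement SD 0.2 on the log2 scale.

What the generators do **not** emulate: uneven illumination, debris and
apoptotic cells, segmentation-relevant cell-cell occlusion, stain
bleed-through, adhesion sub-populations with heterogeneous rates, and
missing values in proteomics. Passing tests therefore demonstrate
correctness of the computations and calibration of the statistics under
the stated model, not robustness to every real-data artefact.

# Numerical choices and edge cases

* Thresholds: Otsu on the smoothed linear-scale image with a
  median + 6 MAD noise floor; a constant image is an error ("unusable
  field"), a noise-only image yields an empty field.
* Coordinates are 1-based pixel centres in EBImage orientation (R
  convention); physical units come from `pixel_size` (um/px).
* The ratio of a cell whose ring is empty after clipping, or whose
  background-subtracted region mean is non-positive, is NA with a
  warning; a uniform marker field measured with background 0 gives
  exactly 0.
* Classifier ties are broken by the fixed class order; training and the
  hold-out split are seeded, so `classify o train` is deterministic.
* Peak detection in rate fitting uses the median-smoothed trace;
  including the peak frame in both phase fits keeps the estimator
  median-unbiased within about 1.5% at SNR 10, and recovery is exact in
  the noiseless limit (in the generator regime k_d < k_a). Constant
  tracks get zero rates with the stability phase spanning the track.
  Phases with fewer than 3 positive-intensity points yield NA rates.
* Angle bins are nearest-centre with ties to the lower bin (15 degrees
  falls in bin 0); the tangent sign convention fixing 30 vs 150 degrees
  is arbitrary but consistent, and cells with the Golgi on the far side
  of the nucleus from the wound are excluded before binning.
* BCa: z0 from the bootstrap distribution (clamped to ±4), acceleration
  from the pooled jackknife; degenerate resamples are dropped.
* The SAM q-value is monotonised (non-increasing in |t|) and clipped to
  [0, 1]; permutations exclude the observed labelling, and fewer than 10
  distinct assignments is an error.

# Design decisions where the procedure was open

* **Which population defines the normal box** (mock, perturbed or pooled)
  is ambiguous in the source procedure; it is a config choice,
  default pooled, because the box is meant to capture the region where
  classified shapes overlap, which is a property of the combined
  population.
* **Plate normalisation** ("normalized per plate") is implemented as
  subtracting the per-plate median of mock wells — it removes batch
  shifts while leaving the printed Z formula intact; `none` is
  selectable.
* **Linkage** for phenoclustering is average (complete selectable), the
  conventional default for correlation-based phenotype clustering; the
  0.73 cut is applied to the root merge similarity of a subtree, per the
  wording "grouped at the highest node".
* **Replicate hit rule**: both the all-replicates and any-replicate
  counts are reported; the QMS-level flag is the primary call. At the
  level of single wells a Z <= -1.5 rule necessarily flags about 6.7% of
  null wells (the one-sided normal tail), so specificity claims are made
  at the condition level where replicate averaging applies.
* **FA internals** (threshold rule, one-pixel overlap linking, no gap
  closing, 90%-of-peak stability plateau, 5000 BCa resamples) follow
  common practice of adhesion-tracking servers and estimation-statistics
  tools; all are parameters.
* **Proteomics** defaults s0 = 0.1, 1000 permutations, SAM-style FDR
  (BH on permutation p-values selectable); Welch t accommodates unequal
  replicate groups. Missing-value imputation is out of scope: proteins
  with missing abundances are dropped.
* **Phase lengths** count all in-phase frames (birth to peak, peak to
  death), not only the points used by the fit.

# Problem sizes used in validation

The shipped tests validate, among others: mixture recovery on a rendered
20-well plate at 504 cells/well (per-well shape-fraction error within 5
percentage points of ground truth, classifier hold-out accuracy >= 90%);
Z standardisation over 40 mock wells; hit calling over 500 null wells and
25 shifted conditions at 4 replicate wells each (sensitivity >= 0.9 at a
3-mock-SD shift, condition-level false positives <= 5%); brute-force
agreement of the phenocluster cut for up to 6 conditions over 100 random
matrices; FA rate recovery over 200 SNR-10 tracks (median relative error
<= 20%); BCa coverage over 500 replicates at n = 30/group (>= 90%,
nominal 95%); Mann-Whitney exactness up to n = 7; permutation-FDR null
calibration over 20 seeds and spike recovery at delta_log2 = 1, n = 3 per
group; Golgi geometry to 1e-9 degrees; and byte-identical outputs for
repeated runs of the full synthetic screen under one seed. The worked
example in the README and the `analysis/` scripts use a smaller 20-well,
42-cells-per-field plate so the complete workflow reruns in about a
minute.

# Known limitations

* The five archetype geometries are stylised; real LM2 cells are far more
  heterogeneous, and the published 127-feature set could not be
  reproduced feature-for-feature.
* The renderer's noise model is Poisson-Gaussian only, with no optical
  PSF beyond a Gaussian blur and no 3D rendering beyond sparse blob
  planes.
* The normal-cell filter inherits the limits of a single linear decision
  rule: an axis-aligned box in PC space is not linearly separable in
  feature space, so its classifier is only as good as the separation of
  the populations that define it.
* Published headline numbers from screens of this design — specific mock
  shape fractions, hit counts, phenocluster counts or effect sizes —
  require the corresponding microscopy and proteomics data and are not
  reproduced here; the package validates the machinery that produces such
  numbers.
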