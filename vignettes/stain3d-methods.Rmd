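---
title: "stain3d: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stain3d: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stain3d)
```

## Scope and model

`stain3d` reproduces, as reusable and tested code, the image-analysis
chain of a chromogenic fate-mapping study: X-gal (blue) staining on
eosin-pink counterstained serial heart sections is segmented by color
clustering, quantified left/right about an apex-to-base separation line,
and reconstructed into a 3D binary volume. Because the original slide
images were never deposited, every stage is exercised against a synthetic
phantom whose ground truth is known exactly. This vignette records the
model each stage implements, the parameters that matter, and the choices
made where the original description was interactive, manual, or silent.

## Segmentation: k-means in CIE L\*a\*b\*

Each section is converted from 8-bit sRGB to CIE L\*a\*b\* under the D65
reference white (closed-form sRGB → XYZ → Lab; `grDevices::convertColor`
serves as an independent oracle in the tests, not as the implementation).
The pixels' (L\*, a\*, b\*) vectors are clustered with Lloyd's k-means
under squared Euclidean distance. Parameters:

- **K (clusters), default 6 per section.** The upstream method initializes
  K at 6 and lets an operator retune it per slice; no acceptance criterion
  for that tuning was stated. Our `tune_k` replaces the interaction with a
  deterministic search over `k_min..k_max` (default 2..8, required to
  bracket 6): each candidate stain mask is scored by the mean L\*a\*b\*
  distance of its pixels to the stain reference plus a stability penalty —
  `stability_weight` (default 10 L\*a\*b\* units) times the symmetric
  difference rate between the masks at adjacent K. Ties break toward
  K = 6. The full trace is attached to the result so a fixed K can always
  be substituted (`--k` in the CLI). This score is a stand-in for the
  original interactive judgment, not a claim about the authors' intent.
- **Initialization and restarts.** Deterministic seeded initialization at
  K distinct pixel colors, `n_restarts = 10` by default, keeping the
  lowest-inertia fit; an empty cluster is re-seeded at the worst-fit
  pixel. The original description specifies neither; restarts make the
  best-of-restarts inertia non-increasing in K, which the tests assert.
- **Stain selection.** The cluster whose centroid is nearest the stain
  reference color (the L\*a\*b\* image of the default deep blue,
  RGB (49, 59, 125), i.e. approximately (27, 17, −39)) is extracted,
  subject to a blue guard: centroid b\* below `blue_guard = -10`. Bare
  negativity (the naive reading of "blue-shifted") is fragile: pixel noise
  can split the near-achromatic background into a subcluster with b\* a
  few units below zero, while a genuine blue chromogen sits tens of units
  below. If no centroid passes, the section is reported as stain-free
  (flagged empty mask), not an error — this is the expected outcome on
  reporter-negative control hearts.
- **Channels.** Clustering uses all three of (L\*, a\*, b\*); the upstream
  text says only "color feature". An a\*b\*-only variant was considered
  and rejected as a default because luminance separates stain from dark
  debris; the choice is isolated in one place (`cluster_colors`) should a
  user need to change it.
- **One detector for both paths.** The original 2D quantification used a
  manual magic-wand selection while the 3D path used k-means. This package
  deliberately uses the same k-means detector for both, rather than
  emulating a proprietary tolerance-flood tool: one defensible stain
  detector, recorded in the run logs.

## Quantification: left/right morphometry

- **Analysis frame.** Every image is standardized to exactly
  690 × 970 = 669300 pixels (nearest-neighbor resampling). Aspect
  distortion is permitted: it is the total pixel count that the upstream
  procedure normalizes, not the aspect ratio.
- **Separation line.** A y-monotone polyline from the apex toward the base
  (and through the aorta), in standardized coordinates. Each positive
  pixel is assigned by comparing its x with the line's x at its row;
  pixels exactly on the line go to the right. Any fixed half-open rule
  preserves count conservation (left + right = positives, asserted for
  every slice); the original manual tool stated no rule. A
  `side_convention` field covers mirrored images. Lines are supplied per
  slice in a JSON annotation; the phantom supplies its ground-truth line
  automatically.
- **Aggregation.** Per heart: means and SEMs (n−1 SD over √n) of per-slice
  left/right counts, and percentages computed **per slice then averaged**
  (mean of ratios). The published percentages are inconsistent with the
  ratio of the published means for one heart (ratio of means ≈ 93.7% vs a
  printed 87.9%), implying the authors averaged per-slice percentages;
  the pooled ratio-of-means is reported alongside for transparency
  (`pooled_pct_left`). Slices with zero positives are excluded from the
  percentage mean and counted (`n_pct_excluded`).
- **Comparison.** Two-sample Student's t-test on per-heart means, two
  tailed, α = 0.05. Pooled variance is the reported default; Welch and
  paired variants are always computed, because the original pairing (the
  two sides come from the same hearts) is statistically real but the
  published test's pairing and n are unstated. Indeed the published
  p = .0001 is not derivable from the published per-heart means (a pooled
  t on 3 vs 3 with those means gives p ≈ 0.07), so no numerical claim is
  made about it here.

## Reconstruction

- **Registration.** Mask-based (binary Dice), because it is the segmented
  stain regions that get aligned, not the raw color images. The search is
  exhaustive and deterministic: coarse grid ±`translation_max` px (default
  15) and ±`rotation_max`° (default 10) at 1 px / 1°, then local
  refinement at 0.1; ties break toward the smallest |tx| + |ty| + |θ|. The
  kernel is compiled (Rcpp) — a 20k-candidate × 10k-point search is not
  viable in interpreted R. Bounds must cover the expected misalignment:
  two independent ±10 px section jitters compose to pair-relative shifts
  of up to ~20 px, so recovery tests pass wider bounds explicitly.
- **Reference frame.** Each section is registered to its predecessor and
  the pairwise transforms are composed into the first section's frame (the
  upstream text does not state a reference); on a jitter-free phantom the
  composed chain returns to identity within 0.5 px / 0.5°, which the tests
  assert.
- **Stacking.** Each aligned mask contributes `replication_factor = 7`
  consecutive identical z-layers, simulating section thickness. The z
  spacing is `section_thickness / replication_factor` (default 14 µm / 7 =
  2 µm) so the seven replicated layers span one physical section;
  cryosections in the emulated preparation are 14–20 µm, and 14 is used as
  the nominal default. In-plane pixel size was never stated upstream, so
  in-plane spacing defaults to 1 arbitrary unit and voxel anisotropy is
  configurable but unverifiable.
- **Export.** MetaImage (`.mhd` text header + `.raw` 8-bit data, 255 =
  stain), written x-fastest, plus maximum-intensity projections along each
  axis (axial/coronal/sagittal). The round trip through the package's own
  minimal reader is bit-exact; the tests additionally parse the header
  with an independent scanner.

## The phantom: what it emulates, and what a green test establishes

`generate_stack` produces frontal-section-like images: a two-lobed tissue
silhouette (two overlapping ellipses with a basal notch and the apex of
the larger, left lobe at the bottom — a parametric shape, not an
anatomical atlas; only left/right partitionability and an apex→base axis
are required), eosin-pink tissue on white background, deep-blue circular
stain patches, per-slice rigid misalignment, and additive Gaussian pixel
noise (clipped to [0, 255] and rounded). Defaults and their rationale:

- **Frame 690 × 970**: the analysis frame itself; the acquisition
  resolution of the original sections was never stated, so the phantom
  works directly at analysis scale. All geometry scales with the frame, so
  tests run at reduced frames without changing anything but pixel count.
- **`left_fraction = 0.9`** (pipeline replica: 0.89): the lateralization
  the emulated study reports.
- **Patch layout**: one base configuration of `n_stain_patches = 10`
  disjoint disks (radius 1.5–4% of frame width) per stack, shared by all
  sections, radii scaled per section by a uniform 0.85–1.15 factor. The
  shared configuration is what gives consecutive sections the spatial
  continuity that makes inter-slice registration meaningful; the
  per-section scale gives realistic within-heart count variability.
  Sides are assigned by choosing the left subset of patch areas whose
  share best matches `left_fraction` (exhaustive subset search), because
  an i.i.d. Bernoulli assignment at ~10 patches cannot keep the pooled
  share within the ±0.03 recovery band the tests require. Patch count and
  radius range are set so the share granularity (smallest patch / total)
  sits below that band. Placement enforces a margin to the separation
  line at the largest per-section scale, so `left_fraction = 1` puts
  every stain pixel strictly left at every scale.
- **`noise_sd = 5`** (tests also run 8): the segmentation recovery
  criterion (Jaccard ≥ 0.95) is specified up to noise SD 8 with palette
  separation ≥ 30 L\*a\*b\* units; the defaults (blue/pink/white) are far
  more separated than that.
- **Jitter** defaults to 0 (quantification assumes the canonical frame);
  registration scenarios use ±10 px, ±5°.
- **Truth bookkeeping**: masks are stored post-jitter (matching the
  emitted images, for segmentation scoring); left/right counts are
  recorded pre-jitter against the canonical line (for quantification
  scoring), so for zero jitter `left + right` equals the mask's positive
  count exactly. Rigid perturbation uses nearest-neighbor interpolation so
  binary truth stays binary — no mask-thresholding rule has to be defined.

What a green suite does **not** establish: performance on real histology.
The phantom has flat-colored patches, no stain-intensity gradients, no
partial-volume mixing at patch borders, no tears, folds, illumination
fields, or out-of-plane deformation. Segmentation on real slides will be
strictly harder than Jaccard ≈ 1; the phantom's role is to verify the
machinery (color transform, clustering, selection, counting, alignment,
stacking, export) against exact ground truth, not to benchmark accuracy.

## Numerical and degenerate-input choices

- Same seed + same configuration ⇒ bit-identical stacks, models, reports
  and files (reports record paths relative to the output directory for
  this reason).
- k-means assignment ties go to the lowest cluster index; tuner ties go
  toward K = 6; registration ties toward the smallest transform.
- Empty masks: registration returns a flagged identity; quantification
  returns (0, 0); a heart whose every slice has zero positives gets `NA`
  percentages and a flag rather than an error. Single-slice hearts have
  `NA` SEM.
- Degenerate clustering input (fewer distinct colors than K) is an error
  by contract; a stain-free section is *not* an error (flagged empty
  mask).
- Power/null simulation sizes follow the stated scenarios (3 hearts × 5
  sections; 100 and 50 replicates) but run at reduced frames to keep the
  suite within its time budget; the frame size changes only pixel counts,
  not the statistical structure.

## Known limitations

- The registration search is exhaustive over a bounded grid: misalignments
  beyond the configured bounds are not recoverable, and the bounds must be
  chosen to cover the perturbation scale (see above).
- The deterministic K tuner is a reproducible surrogate for expert
  interaction, and its stability score is a design choice; a fixed K
  remains available everywhere.
- TIFF input is not supported (no TIFF reader in the dependency
  environment); PNG is.
- The interventricular-septum sub-partition (a third region between two
  polylines) is structurally supported by supplying additional lines, but
  no numerical claims are attached to it.
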