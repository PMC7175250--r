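---
title: "Image-based quantification of calcium oxalate crystallization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based quantification of calcium oxalate crystallization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crystalscreen)
```

# The assay and its quantities

Calcium oxalate (CaOx) crystallization screens monitor, by brightfield
microscopy, how candidate inhibitors change the amount, polymorph
composition and morphology of crystals formed in oxalate-spiked urine or
buffer. Two hydrate forms dominate: the monohydrate COM — small
(length on the order of 10 µm), compact, abundant — and the dihydrate
COD — larger (about 20 µm) tetragonal bipyramids whose projection is an
elongated diamond, which can grow into needle-like shapes under
face-specific inhibitor binding. `crystalscreen` reconstructs the full
analysis chain for such screens:

1. **Segmentation** of individual crystals in each field of view;
2. **Feature extraction** — 15 shape, intensity and texture descriptors per
   crystal;
3. **Classification** into COM (class 0), COD (class 1), not-defined
   structures (class 2) and background noise (class 3) with a cubic
   (degree-3 polynomial kernel) SVM, trained semi-supervised;
4. **Quantification**: per-condition class areas, normalization to the
   in-experiment no-inhibitor control, and minimal inhibitory
   concentrations (MIC) at a 5 % rule;
5. **Cell-assay readouts**: crystal-occupied area on DIC images and
   dead-cell dot counts on red-fluorescence images.

Because no public imaging data accompanies this assay class, the package
ships a first-class, seeded synthetic scene generator with exact ground
truth; every stage is validated against it.

# Segmentation

Crystals in brightfield appear as dark-rimmed, internally textured objects
on a bright background, so edges are the robust cue. The segmenter:

* smooths with a Gaussian (`edge_sigma`, default 1.5 px) and computes the
  Sobel gradient magnitude, normalized so a unit intensity step has
  gradient 1;
* thresholds the gradient automatically (Otsu) with an absolute floor
  (`edge_floor`, default 0.04). The floor matters: Otsu always splits
  whatever distribution it sees, so a featureless noise-only field would
  otherwise yield spurious edges. Featureless fields return zero segments,
  not an error;
* closes the edge map (disc of diameter `close_size` = 5 px), fills holes,
  and erodes by `shrink_px` = 2 px to compensate the outward widening of
  the gradient band (roughly the smoothing scale). Without this
  compensation, masks are dilated halos and the intersection-over-union
  with true object footprints drops from ~0.85 to ~0.55;
* discards detections below `min_object_area` (default 4 µm²) — smaller
  structures are left to the classifier's noise class rather than silently
  removed;
* splits touching objects by watershed on the Gaussian-smoothed
  (`distance_smooth_sigma` = 2 px), negated distance transform with an
  h-maxima-style `watershed_tolerance` of 1 px: each sufficiently deep
  distance maximum seeds one object, so a single convex crystal is never
  split while fused crystals are cut at the saddle.

`border_policy` defaults to `"keep"`: the screen's readout is total area
per field of view, and dropping border objects would bias it low. Focus
variability is deliberately not handled at segmentation time; it is part of
what the classifier must absorb.

# Features

The 15 descriptors per crystal (`feature_names()`):

* **Shape** — area (µm²), perimeter (µm; marching-squares contour length of
  the 0.5 level set, straight pieces weighted 1 and corner cuts
  $\sqrt{2}/2$), major and minor axis lengths and eccentricity of the
  equivalent ellipse from the second central moments of the pixel
  coordinates (the standard regionprops convention,
  $\text{axis} = 4\sqrt{\lambda_i}$), and circularity
  $4\pi A / P^2$, clamped to 1.
* **Intensity** — mean, variance, minimum, maximum, and a robust
  distribution-width scalar, `intensity_spread` = interquartile range
  divided by the bit-depth range. A single scalar was chosen for the
  "intensity distribution" feature so the vector stays fixed-length; the
  IQR is insensitive to the extreme-value tails that defocus produces.
* **Texture** — gray-level co-occurrence (GLCM) correlation, contrast,
  homogeneity and energy, with the Matlab `graycoprops` definitions
  (homogeneity $\sum p/(1+|i-j|)$, energy $\sum p^2$). The GLCM is
  quantized to 32 levels over the *full bit-depth range* (not per-region
  min–max), distance 1 px, the four standard angles averaged, symmetric and
  normalized. Fixed-range quantization makes the features analyzable under
  intensity shifts: adding a constant that is a multiple of one
  quantization bin leaves all four texture features exactly unchanged.
  Constant regions (and single-pixel segments) take the degenerate values
  energy 1, contrast 0, homogeneity 1, and correlation 1 (the
  zero-variance limit, matching common implementations).

# Semi-supervised classification

Within a single image, crystal types separate on a single feature (size,
maximum intensity, circularity, ...), even though no single threshold works
across images with different illumination and focus. Training labels are
therefore produced by *image-scoped single-feature threshold rules*
(`annotate()`): later rules override earlier ones; two rules with equal
explicit priority assigning different classes to the same crystal are a
hard error that lists the affected rows, since silent resolution of such
conflicts would corrupt the training set.

The classifier is a degree-3 polynomial-kernel SVM ("cubic SVM") with
C = 1, coef0 = 1, kernel scale $1/p$ on standardized features, one-vs-one
multiclass, hard labels, and no class weighting — imbalance is reported
through per-class precision/recall/F1 rather than reweighted away, because
the screen's dominant classes (COM, COD) are exactly the ones the
downstream quantification depends on. Performance is estimated by
stratified fivefold cross-validation with standardization fitted on the
training folds only; the reported confusion matrix pools the five test
folds and the final model is refit on all data. Rows are put into a
canonical content-derived order before fold assignment, so results are
independent of input row order for a fixed seed.

# Quantification and MIC calls

Per condition (experiment x compound x concentration), class areas are
summed over all fields (the layout unit being wells x fields per well; the
default layout is 2 wells x 5 fields, and N = 3 experiments). The crystal
total is COM + COD + n.d.; the noise class is tracked but excluded. Each
experiment is normalized to its own no-inhibitor control (100 %), which
removes inter-experimental variability in absolute crystallization; pooling
across experiments before normalization is never done.

The MIC at mode "complete" is the lowest *tested* concentration whose mean
normalized total area across experiments is strictly below 5 % of control;
concentrations are never interpolated, and a series that never crosses the
threshold returns the sentinel "> max tested". Two readings of the COM-only
rule are possible; the default compares COM area against the control's
*total* crystal area (the literal reading), and
`normalize_to_control(com_denominator = "class")` switches to the
control's COM area. The default MIC call operates on the across-experiment
mean series (matching mean + SD dose-response reporting);
`inhibition_result(per_experiment = TRUE)` instead calls per-experiment
MICs and averages them.

# The synthetic scene generator

`render_scene()` produces a calibrated 16-bit brightfield-like field with
exact per-instance ground truth. The appearance model is chosen so that
edge-based segmentation is the natural solver, as in real brightfield
crystal images: bright background (0.78 of range), dark object rims (0.22),
textured interiors, a linear illumination tilt (amplitude 0.05), per-scene
defocus blur (sigma 0.8 px + uniform jitter up to 0.5 px) and additive
sensor noise (sd 0.012). The classes:

* **COM**: compact diamonds, lognormal length with mean 10 µm
  (sdlog 0.25), aspect 0.45–0.7;
* **COD**: larger diamonds, lognormal mean 20 µm, with a bright refractile
  centre typical of thick bipyramids; an elongation factor >= 1 produces
  the needle phenotype of high inhibitor doses;
* **n.d.**: irregular star-convex blobs of intermediate contrast;
* **noise**: a mix of small dark specks and faint out-of-focus blobs, so
  the class is non-trivially separable and partly sub-detectable — exactly
  the character of real debris.

Placement is rejection-sampled; with overlap probability 0 objects keep a
margin larger than the morphological closing, so they never merge.
Ground-truth areas are the rasterized polygon pixel counts — there is no
analytic-vs-raster mismatch in the oracle. Everything derives from a single
integer seed; regeneration is bit-exact.

`generate_dose_series()` wraps this into the full plate layout with
per-concentration effect functions (total-crystallization scale, COM size
scale, COM-to-COD proportion shift, COD elongation) plus a lognormal
per-experiment multiplier (sdlog 0.15) emulating the inter-experimental
variability that control normalization must cancel. Object counts per field
are the deterministic rounded product of control counts and effect factors,
so the ground-truth normalized series tracks the effect function closely
and end-to-end MIC recovery has a well-defined expected answer.

`make_training_fixture()` emulates the screen's training set: 13 images of
varying conditions (per-image size multipliers 0.85–1.15, occasional
needle-phenotype images, illumination and focus jitter), class proportions
0.42/0.26/0.17/0.15 (so COM + COD dominate), non-touching placement
(annotated single crystals). Scenes are over-populated by ~6 % with a floor
of 7 rendered objects per class because a realistic fraction of the faint
debris class falls below the detection limit; the returned labeled table
then reaches the requested size (default 1710 crystals) with at least 5
examples per class, which stratified fivefold CV requires. Labels come from
ground-truth matching: a segment takes the class of the instance covering
the largest share of its pixels (>= 30 %), and uncovered segments are
labeled background noise.

## What the generator does and does not show

The synthetic classes are morphologically cleaner than real micrographs —
no crystal aggregates, no out-of-plane crystals, no urine matrix
particulates — so the cross-validated accuracy on the default fixture
(typically > 99 %) exceeds what the same classifier achieves on real data
(around 91 % in comparable screens). Passing the benchmark therefore
demonstrates that the pipeline is correctly wired and that the classifier
can exploit the declared feature set; it does not certify real-data
accuracy. Conversely, the geometry, calibration, layout arithmetic,
normalization and MIC logic are exercised exactly as they would be on real
data.

# Cell-assay readouts

The adhesion readout segments crystal-occupied area on DIC images by local
variance (7-px box window) thresholded on the local standard deviation
(0.03 of range), followed by closing, hole filling and an erosion matching
the window radius — the sliding window otherwise flags a margin of
background around each textured object. The viability readout counts red
dots as above-threshold (0.25 of range) components within a 6–400 px size
band, with touching dots split by the same distance-transform watershed as
the crystal segmenter. Both thresholds are configuration, not claims about
any particular instrument; the module's tests establish the estimators'
behaviour on generated ground truth (coverage tracking within ±0.03,
exact counts for separated dots, monotonicity, intensity-rescaling
invariance), and per-condition results are normalized to in-experiment
controls exactly like the screening module.

# Numerical choices and degenerate inputs

* Canonical concentration unit: nanomolar; all screen-relevant values
  (40 nM – 100 µM) are integers, and unit conversion happens once at
  manifest load.
* Pixel calibration comes from configuration (default 0.32 µm/px, a
  20x-class objective), never from image metadata; all cross-sample
  comparisons are in normalized units, so absolute calibration only scales
  reported areas.
* Constant-intensity fields, empty masks, empty crystal tables and empty
  rule sets all return empty results rather than errors; a missing or
  zero-area control, an unlabeled segment, conflicting rules and
  sub-fivefold class counts are hard errors naming the offending entity.
* Strict inequality at the 5 % threshold: a series sitting exactly at 5 %
  is "not reached".
* The watershed tolerance (1 px) trades under- against over-segmentation:
  raising it merges close crystals, lowering it fragments textured ones.

# Problem sizes used in the test-suite

The packaged validation runs at desk scale, chosen once: the classifier
benchmark uses the full default fixture (13 images at 896 px, ~1770
labeled crystals); segmentation recovery uses 20 noise-free 384-px scenes;
end-to-end MIC recovery uses 448-px fields in a reduced layout
(2 experiments x 2 wells x 2 fields, control + 4 concentrations, 5 master
seeds) with a classifier trained on a 4-image fixture. The generator's
*defaults* remain the full study layout (3 experiments x 2 wells x
5 fields, 512-px fields).

# Known limitations

* Brightfield rendering is phenomenological, not optical: no interference
  fringes, no refraction, no depth-of-field stack.
* Crystal aggregates (many crystals fused into one segment) are only
  lightly represented (small overlap probability); real screens see more,
  and the standard remedy — routing them to the not-defined class — is
  only as good as that class's training examples.
* The SVM hyperparameters are fixed at the conventional "cubic" values;
  no model selection across families is performed.
* Timepoint kinetics are emulated through effect functions only; there is
  no crystallization-kinetics model.
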