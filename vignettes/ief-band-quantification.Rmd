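---
title: "Box densitometry for hemoglobin IEF gels: models, parameters and design choices"
author: "IEFquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Box densitometry for hemoglobin IEF gels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(IEFquant)
```

## The measurement problem

Isoelectric focusing (IEF) separates hemoglobin species along a pH gradient
until each protein reaches its isoelectric point (pI). On a microarray IEF
chip, twelve vertical micro separation columns are imaged at 405 nm as an
8-bit grayscale frame: dark bands on a light background, with the migration
(pI) axis running vertically. The clinically relevant readout is the
*relative content* of each species — above all the Hb A2 share of total Hb,
whose 3.5% cutoff screens for β-thalassemia trait.

IEFquant quantifies band contents from an image plus a set of classed
bounding boxes. The boxes may come from an external object detector (read
from YOLO-txt or JSON) or from the classical profile-analysis baseline the
package also implements. Around that core sit detection-quality metrics
(IoU, CIoU, AP/mAP50, confusion matrix), method-agreement statistics
(regression and Bland–Altman), and a synthetic gel simulator that makes the
whole chain testable without clinical material.

## Box densitometry

Let $I(x, y)$ be the 8-bit image. Quantification proceeds as:

1. **Inversion.** $I'(x,y) = 255 - I(x,y)$, so band signal is positive.
2. **Background threshold.** $T$ = mean of $I'$ over the gel region between
   the detection boxes (the gel box minus all band, marker and bubble
   boxes). When no gel box is available the whole image minus boxes is used
   and the result is flagged *whole-image*.
3. **Subtraction.** $S(x,y) = \max(I'(x,y) - T,\ 0)$. Clamping at zero keeps
   integrals non-negative and monotone; the alternative (keeping negative
   residuals) would let background noise cancel band signal in low-amplitude
   boxes.
4. **Integration.** Band intensity $B_c = \sum_{(x,y) \in \text{boxes}(c)}
   S(x,y)$, excluding pixels inside bubble boxes. A pixel covered by two
   band boxes is counted exactly once, for the box whose vertical centre is
   nearest (ties to the upper box). This generalises the reason Hb A1c and
   Hb A0 are merged into one class in the first place: their boxes overlap,
   and double-counting the shared pixels would bias both contents.
5. **Contents.** $f_c = B_c / \sum_{c'} B_{c'}$ over the Hb classes
   (pI-marker boxes never enter the denominator). The Hb A2 call is
   *abnormal* iff $f_{\text{HbA2}} \ge 0.035$, boundary inclusive.

Two invariances follow from the construction and are enforced by tests: a
uniform illumination offset cancels exactly through the threshold (on a
uniform background, pre-quantization), and any positive scaling of the
subtracted signal leaves every fraction unchanged.

```{r quant-example}
sim <- generateGel(gelSimConfig(noise_sigma = 2, seed = 7))
quantifyBands(sim$image, gtBoxes(sim$truth))
```

## The profile-analysis baseline

The traditional chain is implemented as a deterministic reference method:

* **Projection**: mean inverted intensity per row (per lane), so dark bands
  become peaks. Means rather than sums are used so lane width does not bias
  comparisons between lanes.
* **Baseline correction**: a 1-D morphological opening (rolling minimum then
  rolling maximum, default window 51 px). The window must exceed the band
  support (about $7\sigma_y$ for Gaussian bands) so bands survive; anything
  slower — illumination drift, lane-wide pedestals — is removed. Opening is
  idempotent, so repeated correction is a no-op.
* **Lane segmentation**: supra-threshold runs of the baseline-corrected
  x-projection (threshold 0.25 of the maximum). The opening window here is
  scaled from the expected lane pitch when a lane-count hint is given. If
  the corrected projection carries less than one intensity unit of
  contrast, the image cannot be split into lanes and a single full-width
  region is returned with a *whole-image* flag — quantification still
  proceeds, at the cost of counting inter-lane background into boxes.
* **Peak detection**: local maxima with prominence at least 5% of the
  profile maximum (default) and at least 3 px apart. Bounds walk outward to
  the nearest local minimum; because quantized profiles flatten to zero
  between bands, the walk also stops where the profile falls below 1% of
  the peak height, which on a Gaussian band lands near $\pm 3\sigma$ — the
  same convention as the simulator's ground-truth boxes.
* **Classification**: with two or more located pI markers, peak positions
  are mapped to pI by piecewise-linear calibration (linear extrapolation
  beyond the anchors) and assigned to the nearest nominal class pI; without
  markers, a fixed migration-order template (Hb A1c/A0, Hb F, MetHb, Hb A2,
  top to bottom) is applied. The template is the deterministic stand-in for
  marker-free classification, which in the detector-based workflow is
  learned.

Peak heights, normalised by the tallest peak in the image, serve as
confidences so baseline output can be ranked on PR curves like any detector.

## Detection metrics

IoU uses half-open pixel boxes, so areas are exact integer counts. CIoU
subtracts a normalised centre-distance term and an aspect term:
$\mathrm{CIoU} = \mathrm{IoU} - \rho^2/c^2 - \alpha v$ with
$v = \tfrac{4}{\pi^2}(\arctan\tfrac{w_1}{h_1} - \arctan\tfrac{w_2}{h_2})^2$
and $\alpha = v/((1-\mathrm{IoU})+v)$. The total detection loss is combined
as $\mathrm{BCE} + 7.5\,\mathrm{CIoU_{loss}} + 1.5\,\mathrm{DFL}$; the
component losses themselves belong to detector training and are taken as
given scalars.

Matching is greedy and one-to-one per class: predictions in descending
confidence take the unmatched ground-truth box with the highest IoU at or
above the threshold, IoU ties breaking to the lower GT index. AP uses
all-point interpolation (the area under the precision envelope of the
confidence-ranked PR curve), the convention of the modern YOLO tooling
ecosystem, rather than 11-point interpolation; mAP50 averages AP at IoU 0.5
over the classes that have ground-truth instances (classes without GT would
have undefined AP and are excluded). The confusion matrix matches
class-agnostically after dropping predictions below the confidence cutoff
(default 0.25): matched pairs increment (GT class, predicted class),
unmatched boxes count against *background*. The tests verify the ranked AP
against an independent threshold-enumeration oracle; exact equality holds
because greedy matching of a confidence-ranked prefix is a prefix of the
full matching (ties in confidence are avoided by construction in the random
instances — with ties, rank-wise and threshold-wise PR point sets differ).

## Agreement statistics

`linearAgreement(x, y)` fits OLS of y on x and reports slope, intercept,
Pearson r and r². Because "linearity" is quoted sometimes as a slope and
sometimes as a squared correlation in clinical method-comparison reports,
both are always returned rather than guessing. `blandAltman(x, y)` uses
differences d = x − y (candidate method minus reference), the sample SD
(n − 1), and limits of agreement at mean ± 1.96 SD; at least three pairs
are required for a meaningful SD.

## The simulator: what it emulates, and what it does not

`generateGel()` renders each band as a separable profile — Gaussian along
the migration axis (the focusing equilibrium shape), a soft-edged top-hat
across the lane — into every lane, then applies, in order: a linear
illumination ramp across x, bubbles (bright ellipses with dark rims, the
artifact produced by agitated cooling liquid), a global exposure scale,
Gaussian sensor noise, clipping to [0, 255] (with a warning when the
noiseless render clips) and round-half-to-even quantization. The pI→y map
is affine over the central 90% of the frame, pH 5.2 at the top; drift can
be emulated by perturbing that map, and lane curvature by a sinusoidal
horizontal displacement.

Key defaults and why:

* **Geometry**: 640 × 640 px, 12 lanes of 30 px — the chip's lane count at
  the typical detector frame size.
* **Contents 0.80/0.05/0.10/0.05** (Hb A1c/A0, Hb F, MetHb, Hb A2): a
  plausible composition whose Hb A2 share (5%) lies above the 3.5% cutoff,
  so the abnormal branch of the decision rule is exercised by default.
* **Band pIs 6.80/7.10/7.35/7.60** inside the 5.2–7.8 gradient, preserving
  the known migration order; spacing keeps neighbouring bands separated by
  clearly more than their supports so the baseline corrector's window
  assumption holds.
* **Amplitudes**: when fractions are requested, amplitudes are rescaled so
  the *discrete* clean signal masses match the fractions exactly (the
  tallest band keeps its requested depth, 150 of 200 background units).
  This makes the generator's ground truth sharp rather than approximate.
* **Noise σ = 2** on an amplitude-150 band is a conservative SNR for a
  modern scanner; recovery tests run at this level.

Ground-truth boxes are centred on each band with half-height $3\sigma_y$
(99.7% of Gaussian mass) and carry the lane's width, widened by the
curvature excursion; a conservation test checks that at least 99% of each
band's clean mass falls inside its box, and that per-band masses add to the
total rendered signal to within 1e−6 relative.

What the simulator does **not** model: focusing dynamics and pH-gradient
chemistry, band co-migration and overlap (bands of one lane are disjoint by
construction), spatially correlated noise, lane-edge shading, or
photorealistic texture. Passing recovery tests therefore demonstrates the
correctness and stability of the *quantification chain*, not detector-grade
performance on clinical images — marker-free classification of distorted,
low-contrast clinical gels is exactly the part that needs a learned
detector, whose output this toolkit consumes as files.

## Numerical choices and degenerate inputs

* Pixel coordinates are 0-based half-open intervals; y grows downward.
  YOLO round-trips are exact to ±1 px (round half away from zero, the
  common tooling convention).
* Quantization rounds half to even (R's `round`), stated so byte-identical
  reproduction is testable.
* An all-zero intensity vector yields an *undetermined* result with no
  division; an empty background region is an error that names the
  whole-image fallback; fewer than two pI markers raises the marker-free
  error rather than silently extrapolating.
* All randomness flows through the config seed; `generateDataset()` derives
  per-image seeds as `seed + i − 1`, so batches are reproducible
  byte-for-byte and images are mutually distinct.

## Problem sizes used in the checks

The packaged checks simulate twenty 640 × 640 twelve-lane gels for content
recovery (maximum per-class error ≤ 0.01 with ground-truth boxes, ≤ 0.03
with profile-analysis boxes), two hundred random small detection instances
(≤ 6 boxes per class) for oracle agreement, and five single-lane noiseless
gels for the baseline's exact mAP50 — sizes at which every quantity is
recomputed from scratch in seconds.

## Known limitations

* The migration-order template assumes all four Hb classes are present; on
  lanes with missing bands the template mislabels peaks below the gap
  (marker-based calibration does not have this failure mode).
* The baseline corrector truncates band tails when the window is chosen
  smaller than the band support; the default window assumes bands no wider
  than about 7 px σ.
* Whole-image (lane-free) quantification counts inter-lane background into
  boxes, biasing contents — the degraded mode is flagged for this reason.
* mAP across multiple images is computed by pooling boxes with disjoint
  per-image offsets; per-image AP is not reported separately.
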