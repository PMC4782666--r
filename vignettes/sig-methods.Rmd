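---
title: "Signal intensity gradient analysis of DW-MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal intensity gradient analysis of DW-MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwisig)
```

## The model

Diffusion-weighted MR contrast reflects the microscopic mobility of water.
Densely cellular tumor tissue restricts diffusion and appears bright, and —
crucially for this package — *unevenly* bright: cellularity varies within a
tumor, so the DW signal fluctuates spatially inside the lesion while normal
tissue stays nearly uniform. `dwisig` measures that fluctuation with local
intensity gradients and condenses it into one number per subject.

For a subregion $f(x,y)$ of $M \times N$ pixels, the eight Robinson compass
kernels $G_S, G_{SE}, G_E, G_{NE}, G_N, G_{NW}, G_W, G_{SW}$ — Sobel-type
$3\times3$ masks with weights $1/2/1$, each the next one rotated by
$45^\circ$ — are convolved with $f$ over *valid* positions only. The
response per direction is the maximum absolute convolution value in the
subregion, and

$$\mathrm{SIG}_{\max} = \max\{G_S, \dots, G_{SW}\}, \qquad
  \mathrm{SIG}_{\min} = \min\{G_S, \dots, G_{SW}\}.$$

Eight directions are used, rather than a single gradient magnitude, because
water diffusion is anisotropic: a fluctuation oriented along any compass
direction is picked up by the kernel tuned to it.

Per axial slice, the tumor-side **resultant SIG** is the largest
$\mathrm{SIG}_{\max}$ over the ROI's tiles — the subregion with the
strongest heterogeneity, taken to mark the densest cellularity. On the
contralateral side the *minimum* response rule is used instead
($\min$ over tiles of $\mathrm{SIG}_{\min}$): taking maxima there proved
unstable in the presence of sulci and gyri, whose anatomy produces large
gradients unrelated to pathology, while the minimum response captures the
uniform-tissue baseline. Averaging the per-slice resultants over all
analysed slices gives the per-subject **decisive SIG** per side, and

$$\mathrm{RSIG} =
  \frac{\mathrm{SIG}_{\text{tumor}} - \mathrm{SIG}_{\text{contralateral}}}
       {\mathrm{SIG}_{\text{contralateral}}}$$

is the within-subject relative excess. Because every SIG value is
positively homogeneous in intensity (the kernels are linear and zero-sum),
RSIG is invariant under any global intensity gain and under additive
offsets, which makes it comparable across subjects and scanners.

### Assumptions

* Tumor heterogeneity is expressible as *in-plane* 2-D gradients; no
  through-plane gradient is computed (the slice gap makes 3-D gradients
  ill-defined at this resolution).
* The head is roughly symmetric about a vertical midline, so the
  mirror-image ROI samples homologous normal tissue. An off-centre head is
  handled by an explicit `midline_col` override, not by registration.
* The contralateral hemisphere is tumor-free; the decisive contralateral
  SIG is strictly positive (guaranteed by tissue noise; a zero value is a
  degenerate input and raises an error rather than an infinite RSIG).

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| tile size (`tile_rows`, `tile_cols`) | 16 | px | centre of the admissible 13–18 px range; large enough for a stable maximum response, small enough to localize heterogeneity |
| `margin_px` | 2 | px | erodes the ROI before tiling so no tile touches the tumor periphery, where the bright/dark rim would masquerade as heterogeneity |
| `glioma_min` / `meningioma_max` | 10.08 / 9.86 | — | the empirical RSIG range boundaries of the two tumor types; values in the open gap are reported as indeterminate rather than forced |
| midline | image centre column | px | overridable per subject for off-centre heads |

The tile range 13–18 px is enforced (`dwisig_config_error` outside it), and
partial tiles at the ROI edge are discarded, never padded: padding would
manufacture gradients at exactly the border the margin is meant to avoid.

## What the phantom emulates — and what it does not

`phantom_config()` / `generate_subject()` synthesise an axial DW-like
stack: a brain ellipse at intensity 60 with Gaussian pixel noise (sd 1.5),
dark curvilinear cortical strokes (depth 25) stamped near the brain rim and
mirrored, with jitter, across the midline, and on the affected levels a
hyperintense tumor (plateau 180) whose interior carries band-limited
speckle. The speckle amplitude is the *cellularity-heterogeneity knob*: the
glioma-like preset uses amplitude 24, the meningioma-like preset 8. These
two constants were calibrated once so that default cohorts land inside the
empirical RSIG ranges of the two tumor types (≈ 10–28 vs ≈ 5.6–9.9); they
live in the preset configuration, are recorded in every output sidecar, and
are not adjusted anywhere else.

Deliberate simplifications:

* **No MR physics.** No b-value, T2, or diffusion-tensor modelling; the
  phantom imitates the *appearance* of DW slices, not their acquisition.
  T2 shine-through, which real studies exclude via ADC maps, therefore
  cannot occur.
* **Soft tumor margin.** The tumor edge is blurred (Gaussian sd 5 px) so
  the rim gradient does not drown the internal texture; this mirrors the
  care taken on real images to keep subregions away from the tumor
  periphery, implemented here as smoothness rather than manual avoidance.
* **Sulci keep clear of both ROIs.** Stamped strokes are confined to a
  cortical band (0.80–0.95 of the brain ellipse radius) and excluded from
  the tumor ellipse and its mirror, so the control ROI reflects the
  uniform-tissue noise floor. Stray strokes can still clip ROI corners,
  which is exactly the situation the SIG$_{\min}$ rule is designed to
  absorb.
* **Geometry.** Elliptical tumors with ellipsoidal through-slice taper and
  bounded jitter; real lesions are irregular, infiltrative, and can abut
  the midline, which the generator refuses (config error) rather than
  approximates.

Consequently, passing phantom tests show that the *pipeline* recovers a
known heterogeneity contrast under realistic noise, sulcal clutter and
geometric jitter; they do not show that the published clinical ranges
transfer to any particular scanner or patient population.

## Numerical choices

* **8-bit rescaling** uses one global min–max map per stack (global min
  → 0, global max → 255), not per-slice maps: per-slice normalization
  would rescale each slice's gradients differently and corrupt the
  across-slice average in the decisive SIG. A constant stack maps to all
  zeros by convention. Quantization is round-half-up, stated once
  (`round_half_up()`) and used for every intensity quantization in the
  package.
* **Valid-only convolution.** No padding, output $(M-2)\times(N-2)$;
  padded borders would introduce spurious edge responses.
* **Per-kernel response reading.** The response of a subregion in one
  direction is the maximum absolute convolution value over positions, one
  number per kernel per subregion. For $\mathrm{SIG}_{\max}$ the order of
  maxima (over kernels vs over positions) is immaterial; for
  $\mathrm{SIG}_{\min}$ it is not, and the per-kernel-over-subregion
  reading is the one implemented. The alternative (min over kernels at
  each pixel, then some spatial aggregate) would require an aggregation
  rule with no principled choice, and is not offered.
* **Tie-breaking.** Argmax/argmin tiles are resolved to the first tile in
  row-major order, making results deterministic.
* **Degenerate inputs.** Zero-variance difference vectors (paired t),
  two zero-variance groups (Welch), an all-constant contralateral region
  (RSIG), and sub-3×3 subregions all raise typed conditions
  (`dwisig_*_error`) rather than returning NaN.
* **Determinism.** Phantom generation runs under an isolated RNG seed
  (`with_seed()`), restores the caller's RNG state, and derives cohort
  member seeds from one master seed.

## Design decisions that were genuinely open

* **Six-area partition.** The conventional six-area division of an axial
  slice is realized as a 3 × 2 grid: rows split as evenly as possible,
  columns at the vertical midline. The areas are reporting labels only; no
  SIG quantity depends on them, so any reasonable partition would do.
* **t-test variants.** Within-subject comparison (tumor vs contralateral)
  is a paired t — the sides are matched by subject. Between groups, sizes
  and spreads differ visibly, so Welch's unequal-variance t is the
  default; the pooled-variance Student variant is computed alongside in
  every report for readers who prefer it.
* **Two-sided p-values** throughout, with significance flagged at the
  0.01 level (99% confidence).
* **Slice weighting.** The decisive SIG is an unweighted mean over
  analysed slices; weighting by per-slice tumor area was considered and
  rejected as it would entangle the heterogeneity statistic with lesion
  size, which RSIG deliberately ignores.
* **Slice selection** stays operator-driven (the ROI config lists the
  affected levels); `suggest_slices()` flags hyperintense candidates but
  decides nothing.

## Problem sizes used by the test suite

Unit and property tests run on 16 × 16 subregions (200 random tiles for
the convolution oracle), 64 × 64 synthetic slices, and reduced phantoms
(9 levels, tumor on 3) for the parameter sweeps. The end-to-end
experiments use the full default conditions: 128 × 128 px, 19 levels,
tumor on 5, a 20 + 12 cohort, 50 paired seeds for the separation and
localization experiments, and 2 000 simulated cohorts for the null
calibration of the 0.01-level test. In the localization experiment a tile
counts as inside the tumor when its centre pixel lies in the ground-truth
mask: the ROI is the mask's padded bounding box, so tiles legitimately
clip the elliptical mask's corners and a strict subset criterion would
measure ROI padding rather than localization.

## Known limitations

* ROIs are axis-aligned rectangles placed by the user (or the phantom's
  ground truth); there is no tumor segmentation.
* The DICOM reader handles uncompressed single-frame little-endian series
  only — the common export format for this kind of analysis; compressed
  or multi-frame series must be converted first.
* The RSIG thresholds are empirical range boundaries, not a fitted
  classifier; subjects in the 9.86–10.08 gap are reported indeterminate.
* Findings on phantoms bound what can be claimed clinically; see the
  phantom section above.
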