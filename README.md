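# dwisig

Quantifying brain-tumor heterogeneity on diffusion-weighted MR slices with
the **signal intensity gradient (SIG)** technique, and separating
glioma-like from meningioma-like tumors with the **relative SIG (RSIG)**
statistic.

## The problem and the method

On diffusion-weighted (DW) images, tumors with high cellularity restrict
water diffusion and appear hyperintense, with *heterogeneous* internal
signal; normal brain tissue shows a nearly uniform signal. `dwisig` turns
that qualitative contrast into a number:

1. **ROI and mirror ROI.** A rectangular region of interest is placed over
   the bright tumor area of each affected axial slice; a same-size control
   ROI is placed at the mirror-image location in the contralateral
   hemisphere.
2. **Subregion tiling.** Both ROIs are tiled automatically into small
   M × N subregions (13 ≤ M, N ≤ 18 px, default 16 × 16), after eroding a
   configurable margin (default 2 px) to avoid edge effects at the tumor
   periphery.
3. **Compass gradients.** Each subregion *f(x, y)* is convolved with the
   eight Robinson compass kernels (Sobel-type masks G_S, G_SE, …, G_SW,
   each a 45° rotation of the next). Per direction, the response is the
   maximum absolute convolution value over valid positions, and

   SIG_max = max{G_S, G_SE, G_E, G_NE, G_N, G_NW, G_W, G_SW},
   SIG_min = min{…}.

4. **Resultant and decisive SIG.** Per slice, the tumor-side resultant is
   the largest SIG_max over tiles (the most heterogeneous subregion); the
   contralateral resultant is the smallest SIG_min (the most uniform
   patch, which sidesteps sulci/gyri gradients on the normal side). The
   per-subject *decisive SIG* on each side is the mean of the per-slice
   resultants over all analysed slices.
5. **RSIG.** The discriminating statistic is

   RSIG = (decisive SIG_tumor − decisive SIG_contralateral) / decisive SIG_contralateral,

   the within-subject relative heterogeneity excess. It is invariant under
   any global intensity gain, so subjects and scanners can be compared.
   Empirically glioma falls in the RSIG range ≈ 10.1–28.4 and meningioma
   in ≈ 5.6–9.9, and `classify_by_rsig()` applies those range boundaries.

Since patient DW-MRI data cannot ship with a package, `dwisig` includes a
synthetic **phantom generator** (uniform noisy brain ellipse, mirrored dark
sulcal strokes, soft-edged hyperintense tumor with band-limited internal
speckle) whose texture amplitude plays the role of tumor cellularity, plus
cohort-level statistics (paired t within subject, Welch/Student t between
groups, at the 99% confidence level).

## Worked example

```r
library(dwisig)

ph  <- generate_subject(phantom_config("glioma", seed = 7))
res <- analyze_phantom(ph)   # = analyze_subject(ph$stack, ph$true_roi)
res
#> <subject_sig> 'phantom_glioma_7': 5 slice(s); decisive SIG tumor 240.20 vs
#>   contralateral 12.00; RSIG 19.02 -> glioma-like
```

The per-slice resultants behind those numbers (`tidy(res)`): the tumor-side
resultant SIG is 195–301 across the five affected levels while the mirrored
control stays at 11–13, so the decisive SIGs are 240.2 vs 12.0 and
RSIG = (240.2 − 12.0) / 12.0 ≈ 19.0 — inside the glioma-like range.

A small cohort, end to end:

```r
coh  <- generate_cohort(n_glioma = 6, n_meningioma = 4, master_seed = 7)
rows <- dplyr::bind_rows(lapply(coh, function(s) {
  g <- glance(analyze_phantom(s)); g$group <- s$group_label; g
}))
cohort_report(rows)
#> Cohort summary (mean +/- sd)
#>   glioma-like      n= 6  decisive SIG tumor  220.23 +/-  18.36  contralateral  13.23 +/-  0.96  RSIG  15.71 +/-  1.67
#>   meningioma-like  n= 4  decisive SIG tumor  111.75 +/-   9.34  contralateral  13.10 +/-  0.26  RSIG   7.54 +/-  0.78
#> ...
#>   Welch:  t = 10.390, df = 7.48, p = 1.04e-05 (significant at 0.01)
```

Real data enter through `load_slice_stack()` (DICOM series, PNG or BMP
slices), `rescale_to_8bit()` and a per-subject ROI config
(`read_roi_config()`); see `vignette` sources under `vignettes/` and the
command-line interface:

```sh
dwisig phantom --preset glioma --n 1 --seed 7 --out subj/
dwisig analyze --input subj/ --out results/
dwisig report  --cohort results/cohort.csv
```

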