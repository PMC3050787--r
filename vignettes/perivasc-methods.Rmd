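---
title: "Quantifying perivascular mobile-cell density: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying perivascular mobile-cell density: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perivasc)
```

## The question and the measurement

In many tissues one wants to know whether a mobile cell population (for
example CD56-bright uterine NK cells, or CXCR3-positive lymphocytes in
first-trimester decidua) is *enriched* near a fixed structure (vascular
endothelium, the smooth-muscle ring of a spiral artery, a tumor margin)
relative to the rest of the tissue.  `perivasc` implements a fully
automated, area-based morphometric answer for two-color
immunohistochemistry micrographs:

1. **Specimen mask** `A_T`: the analyzable tissue, obtained by rasterizing
   a region-of-interest file (include polygons minus exclude polygons for
   vessel lumina, glands, off-section background).  `A_T` masks every
   later step.
2. **Stain segmentation**: a pixel is "red" (mobile cell) when its red
   grey value is at least 1.6 times *each* of the green and blue values —
   i.e. at least 60% higher — and analogously "blue" for the fixed
   structure with the roles of R and B swapped.  Because the rule is a
   ratio of channels it is largely insensitive to overall staining
   intensity and illumination.  The red mask is cleaned by a morphological
   closing-then-opening (3 x 3 square by default); the blue mask by
   scrapping connected objects smaller than 0.01% of `A_T` followed by a
   closing with an 11 x 11 square element, yielding `A_R` and `A_B`.
3. **Graded neighborhoods**: `A_B` is dilated with square kernels of side
   `2*round(w*s) + 1` pixels for neighborhood widths `w` = 10, 20, ..., 50 µm
   at scale `s` px/µm.  At the reference calibration `s = 1.5` (a 100 µm =
   150 px scale bar) this is the series 31, 61, 91, 121, 151.  The
   neighborhood area is `A_N = (dilated ∩ A_T) \ A_B` and the residual
   area `A_D = A_T \ dilated`; `A_N`, `A_D`, `A_B` partition `A_T`
   exactly, an integer identity asserted by the tests.
4. **Density fractions**: `F_N = |A_R ∩ A_N| / |A_N|` and
   `F_D = |A_R ∩ A_D| / |A_D|`.  Both are dimensionless, so no µm
   conversion is ever needed; `F_N / F_D` is the enrichment measure.  Red
   pixels lying on the structure itself (`A_R ∩ A_B`) belong to neither
   fraction and are reported separately (`area_BR`) for audit.
5. **Statistics**: per patient the median of each fraction over that
   patient's samples (one robust observation per patient), then a
   two-tailed paired Wilcoxon signed-rank test of `F_N` versus `F_D`
   across patients at α = 0.01, per neighborhood width.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `scale_px_per_um` | 1.5 | physical calibration; 100 µm = 150 px |
| `ratio_threshold` | 1.6 | relative-RGB rule, "at least 60% higher", inclusive |
| `red_cleanup_kernel_px` | 3 | square closing/opening element for `A_R` |
| `blue_min_object_fraction` | 1e-4 | object scrapping threshold, fraction of `A_T` |
| `blue_closing_kernel_px` | 11 | closing element for `A_B` |
| `widths_um` | 10-50 by 10 | neighborhood widths |
| `alpha` | 0.01 | significance level |

Three of these required interpretation, documented here as package
decisions:

* The element size of the red closing/opening is not specified by the
  method's description beyond "closing and opening"; 3 x 3 is the smallest
  element that removes single-pixel noise, and it is exposed as a
  parameter.
* "Objects less than 0.01%" is read as a fraction of the specimen area
  `A_T` (the specimen mask is stated to mask all subsequent steps), not of
  the full frame; also a parameter, so either reading can be tested.
* Whether dilated neighborhoods may extend into excluded lumina is not
  stated; `perivasc` clips the dilated area to `A_T` before the
  subtraction (`clip_to_specimen = TRUE`), since neighborhood pixels
  inside an excluded lumen could not contain cells by construction and
  would deflate `F_N`.

Two numerical conventions: pixel-in-polygon tests use pixel centers with
the even-odd rule, boundary inclusive, so ROI rasterization is exactly
reproducible; and morphological erosion pads the border with `TRUE`
(dilation with `FALSE`), the common toolbox convention, so that the
closing inside `clean_red_mask`/`clean_blue_mask` cannot eat tissue
touching the frame edge.  Kernel sides are odd so structuring elements are
center-symmetric; `kernel_px_for_width` rounds half-up when
`width * scale` is not an integer (the reference calibration is exact).

## The random-distribution null

Comparing `F_N` and `F_D` across samples with very different overall cell
densities motivates a simulation reference: artificial images in which
"cells" are scattered at random over the *same* specimen geometry.
Following the original procedure, seed points are placed uniformly at
random over the whole frame, each grown into a blob by repeatedly adding a
uniformly chosen unoccupied pixel adjacent to the blob until it reaches
the target cell area, and the overlay is then clipped to the specimen:
cell parts inside the vessel or outside `A_T` are eliminated.  The default
study is 100, 200, ..., 500 seeds x 100 replicate images each — 500 images —
and reports the mean and SD of `F_N`, `F_D` and their ratio per seed count
and width.

The clipping order matters.  By translation invariance, free growth with
whole-frame seeds gives a spatially uniform expected cell-pixel density,
so `E[F_N] = E[F_D]` and the mean ratio is 1 up to sampling noise — which
is what makes the null usable as a reference line in the
quantile-quantile display (`qq_plot_data()`).  The alternative reading —
confining the growth itself to the specimen minus structure — folds cell
mass back against the structure boundary and measurably inflates `F_N`
(on a 512 x 512 ring geometry with 110 px cells the bias is about +2% of
the density, growing with cell size).  Both modes are implemented
(`simulation_config(placement =)`); `"overlay"` is the default and the
validated null, `"constrained"` guarantees exact planted pixel counts and
is used where tests need them.

The target cell area is the one free parameter with no stated value; it
should match the size of the real cells, e.g. the median connected
component area of a segmented red mask (`estimate_cell_area()`).  The
default 110 px corresponds to a ~10 µm diameter cell at 1.5 px/µm, the
size class of uterine NK cells.

## What the synthetic data emulates — and what it does not

`make_fixture()` renders a light background (235, 225, 225), a blue
structure (60, 60, 200) — a vessel ring with a lumen exclusion polygon
drawn flush against the wall, a set of vessel cross-sections, or a
branching curve — and red cells (200, 60, 60) grown by the same stochastic
process as the simulation null.  The colors sit far from the 1.6 decision
boundary, so in the noise-free default the segmentation recovers the
planted masks pixel-exactly, and mild Gaussian channel noise cannot flip
pixels.  Enrichment is planted by rejection sampling of seed positions:
acceptance probability proportional to `enrichment_factor` within
`enrichment_band_um` of the structure and 1 outside, so factor 1 is
exactly uniform placement and the planted in-band/out-of-band density
ratio equals the factor.

A green test on these fixtures establishes that the *measurement chain*
(ROI, segmentation, cleanup, dilation, counting, testing) is correct and
calibrated.  It does not establish robustness to the things real
micrographs add: chromogen co-localization and mixed stains, uneven
illumination, out-of-focus tissue, section folds, or stain-intensity
gradients.  The relative-RGB rule is known to tolerate moderate intensity
variation, but no claim beyond that is tested here.

Cohorts (`make_cohort()`) draw a per-patient enrichment factor around the
central `effect` on the log scale (`effect_sdlog`, default 0.25) and
generate independent fixtures per sample.  One modeling point deserves
emphasis: a *null* patient has no enrichment, i.e. factor exactly 1.  A
lognormal spread around 1 would give every patient a random true
enrichment, whose paired differences are skewed (exp-asymmetric), and the
signed-rank test would rightly reject such a world — it is a
heterogeneous-effect world, not a null.  The type-I calibration therefore
uses `effect = 1, effect_sdlog = 0`, while the power analyses keep the
between-patient spread.

## Validation summary (computed by the test suite)

The acceptance suite (`tests/testthat/test-acceptance.R`) recomputes, at
fixed seeds:

* the kernel series 31/61/91/121/151 px for 10-50 µm at 1.5 px/µm,
  exactly;
* the default 500-image simulation study (512 x 512 ring geometry) with
  mean `F_N/F_D` within 3 SE of 1 in every seed-count x width cell;
* pixel-exact equivalence of square dilation with Chebyshev-distance
  thresholding on 200 random masks, and of the relative-RGB segmentation
  with a per-pixel brute-force oracle;
* the exact integer partition `|A_N| + |A_D| + |A_B| = |A_T|` on all
  fixture geometries at all widths;
* exact agreement of the paired Wilcoxon p-value with full sign-flip
  enumeration for all tested cohorts of n ≤ 10 (zeros dropped, mid-ranks,
  two-tailed doubling — the classical convention; the exact distribution
  is used up to n = 25, beyond that the tie-corrected normal approximation
  with continuity correction);
* detection of a planted enrichment factor 3 at the band width in ≥ 95%
  of 100 scaled-down cohorts (15 patients), with a rejection rate ≤ 0.03
  at α = 0.01 over 200 null cohorts.

Runtimes are kept inside a CI budget by scaling frames down (cohorts at
160 x 160) while keeping the stated design constants (seed counts,
replicate counts, widths, thresholds) fixed.

## Known limitations

* Area fractions, not cell counts: touching cells merge, so no per-cell
  statistics are produced (by design, as in the original method).
* The TIFF codec is deliberately minimal: 8-bit uncompressed baseline
  RGB.  PNG covers everything else; whole-slide formats are out of scope.
* The Wilcoxon p-value at n < 6 informative pairs cannot reach p < 0.05
  (flagged `low_power` in the result).
* The simulation null conditions on the observed specimen geometry; it
  does not model between-sample geometry variation.
* The exact small-sample Wilcoxon and the zero/tie conventions are one
  defensible choice; the original analysis software may have differed in
  details not stated in its description.
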