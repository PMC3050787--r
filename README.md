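# perivasc

Automated morphometric analysis of the relative density of mobile
(stained) cells within graded distance neighborhoods of fixed tissue
structures in two-color immunohistochemistry micrographs — for
histologists and image analysts who want an objective, area-based
replacement for visual enumeration of, e.g., perivascular leukocyte
accumulation.

## The method

Given an RGB micrograph (red = mobile cells such as CD56⁺ uterine NK
cells; blue = fixed structure such as CD34⁺ endothelium), a
region-of-interest polygon file, and a physical scale *s* (px/µm):

* the specimen mask **A_T** is the rasterized ROI (includes minus
  excludes such as vessel lumina);
* **A_R** (cells): pixels with `R ≥ 1.6·G` and `R ≥ 1.6·B` ("at least 60%
  higher"), cleaned by a 3×3 closing + opening;
* **A_B** (structure): the same rule with R and B swapped, then objects
  < 0.01% of A_T scrapped and an 11×11 closing applied;
* for each neighborhood width *w* (10–50 µm), A_B is dilated with a
  square kernel of side `2·round(w·s)+1` px (31, 61, 91, … at
  s = 1.5 px/µm), giving the neighborhood **A_N** = (dilated ∩ A_T) \ A_B
  and residual tissue **A_D** = A_T \ dilated;
* the density fractions **F_N = |A_R ∩ A_N| / |A_N|** and
  **F_D = |A_R ∩ A_D| / |A_D|** quantify cell density near and away from
  the structure; their ratio is the enrichment measure;
* per patient, sample fractions are summarized by their **median**, and
  F_N vs F_D is tested with a two-tailed **paired Wilcoxon signed-rank
  test** (exact for ≤ 25 patients) at α = 0.01, per width;
* a **simulation null** scatters artificial cells uniformly over the same
  specimen geometry (100–500 seeds × 100 replicate images, grown to the
  real-cell size, clipped to the specimen) and provides the random
  distribution reference (mean ratio 1) with SD bars for a QQ display.

A synthetic micrograph generator with exact ground truth
(`make_fixture()`, `make_cohort()`) makes the entire chain testable
without any real data.

## Worked example

```r
library(perivasc)

# one synthetic micrograph with 4-fold perivascular enrichment
spec <- fixture_spec(enrichment_factor = 4, rng_seed = 42)
fx <- make_fixture(spec)
fx$image
#> <color_image 256 x 256 px, 1.5 px/um (170.7 x 170.7 um)>

res <- analyze_image(fx$image, fx$roi, image_id = "demo", patient_id = "P01")
res[, c("width_um", "kernel_px", "area_N", "area_D", "F_N", "F_D", "ratio")]
#>  width_um kernel_px area_N area_D    F_N    F_D ratio
#>        10        31   7920  46875 0.1879 0.0422  4.45
#>        20        61  17640  37155 0.1091 0.0416  2.62
#>        30        91  29160  25635 0.0865 0.0369  2.34
#>        40       121  42480  12315 0.0735 0.0279  2.63
#>        50       151  53566   1229 0.0647 0.0000    NA
```

Reading this: at the 10 µm band the cell density next to the vessel
(`F_N` = 18.8% of the area red) is 4.45× the residual density — the
planted factor 4 is recovered; the enrichment dilutes as the band widens.
At 50 µm the residual area has shrunk to 1229 px and happens to contain
no cells, so the ratio is undefined (`NA`) — on this small frame that
width saturates the specimen.

```r
# random-distribution null on the same geometry (reduced for the example)
study <- run_simulation_study(fx$truth$a_t, fx$truth$a_b, widths_um = 10,
  config = simulation_config(seed_counts = c(100L, 300L),
                             replicates_per_count = 25L, rng_seed = 1L))
study$summary
#>  seed_count width_um mean_F_N sd_F_N mean_F_D  sd_F_D mean_ratio sd_ratio
#>         100       10    0.157 0.0211    0.156 0.00961      1.016    0.176
#>         300       10    0.396 0.0377    0.398 0.01338      0.996    0.116
```

Randomly scattered cells give `F_N ≈ F_D` (mean ratio ≈ 1) at any overall
density — the reference line for judging real samples.

```r
# a small enriched cohort, summarized per patient and tested
set.seed(7)
co <- make_cohort(8, 2, spec, effect = 3)
results <- do.call(rbind, lapply(names(co$fixtures), function(id)
  analyze_image(co$fixtures[[id]]$image, co$fixtures[[id]]$roi,
                widths_um = 10, image_id = id)))
summaries <- summarize_patients(results, co$mapping)
paired_wilcoxon(summaries, width = 10)
#> Paired Wilcoxon signed-rank, width 10 um: W+ = 36, n = 8 (8 used),
#>   p = 0.007812 (exact) *significant at 0.01*
```

All eight patients show F_N > F_D, giving the smallest two-tailed exact
p-value possible at n = 8 (2/2⁸).

A file-based pipeline (`run_full_analysis()`) and a subcommand CLI
(`perivasc_cli()`: `fixtures`, `analyze`, `simulate`, `stats`, `run-all`)
chain the same stages with CSV/JSON artifacts and a reproducibility
manifest; see `?run_full_analysis`.

## More

The methods vignette (`vignettes/perivasc-methods.Rmd`) documents the
model and its assumptions, all tunable parameters with units and
defaults, the simulation-null design (and why the overlay-then-clip
order matters), what the synthetic data does and does not emulate, and
known limitations.
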