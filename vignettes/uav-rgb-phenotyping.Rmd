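---
title: "Plot-level phenotyping from UAV RGB orthomosaics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plot-level phenotyping from UAV RGB orthomosaics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uavpheno)
```

## The problem

Breeding trials of tall fibre crops such as kenaf (*Hibiscus cannabinus* L.)
need per-plot measurements of growth — canopy surface area, plant height,
stem diameter, node count — across many entries and replicates. Manual
measurement is the bottleneck; a consumer RGB camera on a small UAV can
replace a large part of it. `uavpheno` implements the image-analysis chain
that turns a georeferenced RGB orthomosaic plus surface/terrain models into
a per-plot trait table, and the nonparametric statistics used to compare
entries and relate image traits to manual ones.

The chain is: radiometric calibration → chromatic vegetation indices →
canopy segmentation → per-plot trait extraction → rank-based statistics.
Because the imagery of any given trial is rarely shareable, the package
also ships a seeded synthetic field generator that renders a full trial
with known ground truth, so every stage is testable end to end.

## Radiometric calibration (empirical line method)

Raw digital numbers (DN) depend on illumination and camera settings. Ground
panels of known reflectance (3, 12, 36 and 56 %) are imaged in every
flight, and a per-band exponential empirical-line model maps DN to surface
reflectance:

$$ r_k = A_k \, e^{B_k \cdot \mathrm{DN}}, \qquad k \in \{R, G, B\}. $$

`fit_elm()` fits the log-linear form $\ln r = \ln A_k + B_k\,\mathrm{DN}$
by ordinary least squares. This choice (over nonlinear least squares on the
natural scale) is deliberate: it is closed-form, deterministic, and exact
on noise-free panels, and the published per-flight coefficients we use as
generator defaults are recovered to machine precision by a round trip
through the four panels. The reported $R^2$ is that of the log-linear
regression; users comparing against coefficients fitted on the natural
scale should expect small differences in $R^2$ but not in $(A, B)$ for
well-behaved panels. Pixels at the extremes of the sensor range are
excluded from panel means (they violate the exponential model);
`apply_elm()` clips output reflectance to $[0, 1]$ and reports the count of
clipped pixels.

## Vegetation indices

All indices are computed on chromatic coordinates
$r = R/(R+G+B)$, $g = G/(R+G+B)$, $b = B/(R+G+B)$, which removes overall
brightness. The six indices are

| index | formula | range on valid pixels |
|-------|--------------------|----------------------|
| EXG   | $2g - r - b = 3g - 1$ | $[-1, 2]$ |
| EXR   | $1.4r - g$            | $[-1, 1.4]$ |
| EXGR  | $3g - 2.4r - b = \mathrm{EXG} - \mathrm{EXR}$ | — |
| NDI   | $(g - r)/(g + r)$     | $[-1, 1]$ |
| GLI   | $(2g - b - r)/(2g + b + r) = (3g-1)/(1+g)$ | $[-1, 1]$ |
| VARI  | $(g - r)/(g + r - b)$ | unbounded |

Pixels with $R+G+B = 0$ are flagged invalid and excluded from all
downstream means and histograms — never zero-filled, which would bias plot
means toward the background. VARI (and NDI) pixels with a vanishing
denominator are invalidated for that index only. Two identities are worth
noting because the test suite leans on them: EXGR is *identically*
EXG − EXR, and both EXG and GLI are strictly increasing functions of $g$
alone, so their per-pixel Spearman correlation is exactly 1.

Indices are computed on calibrated reflectance, not raw DN, matching the
processing order of calibrate-then-extract; chromatic normalization makes
the indices fairly robust to the difference, but the calibrated route is
the default.

## Canopy segmentation and trait extraction

Canopy is separated from the (dark plastic mulch) background by Otsu's
threshold on EXG: a 256-bin histogram over the observed range, threshold at
the interior bin edge maximizing the between-class variance
$\omega_0 \omega_1 (\mu_0 - \mu_1)^2$, ties broken toward the lowest edge
for determinism. The default scope is one *global* threshold over the
union of plot ROIs per scene: plot-wise thresholds fail on plots that are
nearly all canopy or all background, while the union histogram is reliably
bimodal. A per-plot mode exists for robustness studies.

Per-plot traits follow the conventions of the field:

* **Sur (cm² per plant)** — canopy pixels inside the plot ROI × gsd² ÷
  stand count. The divisor is the *established* stand count of that plot
  (germination is rarely 100 %), not the nominal seed count. Plots with a
  stand count of 0 (non-germinated entries) yield NA and are dropped from
  trait tables with a log message.
* **Eph (mm)** — the canopy height model is DSM − DTM; negative
  differences (reconstruction noise) are floored at 0, and the plot height
  is the ROI maximum, in mm.
* **VI means** — arithmetic mean over either all valid ROI pixels
  (default) or canopy pixels only. The all-ROI default makes the VI mean
  sensitive to both canopy greenness and canopy cover, which is what makes
  it an effective whole-plot vigor proxy; the canopy-only mode isolates
  tissue color. Both are first-class options.

A single geometry convention is used everywhere: a pixel belongs to a
polygon iff its *center* is inside (boundary inclusive). This makes canopy
counts exactly additive over ROI partitions and keeps areas and means
consistent with each other.

## Statistical layer

Trait tables from small trials (3 replicates) frequently fail normality,
so the pipeline is nonparametric throughout; the Shapiro-Wilk screen is
computed per trait × set and *reported*, never used to switch methods.

* **Kruskal-Wallis** with tie correction, p from the chi-square tail on
  $g - 1$ df (via `kruskal.test`). Entry effects and replicate effects are
  tested separately per trait. All-identical data gives H = 0, p = 1
  rather than an error.
* **Dunn post hoc** z tests on mean ranks with the tie-corrected variance
  $N(N+1)/12 - \sum(t^3 - t)/(12(N-1))$, two-sided p, Bonferroni over all
  $g(g-1)/2$ pairs capped at 1. Two-sided is the conventional reading of a
  "Dunn-Bonferroni" post hoc.
* **Compact letter display** by insert-and-absorb: groups sharing a letter
  are not significantly different, and the implementation satisfies that
  contract *exactly* (the test suite verifies it exhaustively for every
  significance pattern up to 5 groups).
* **Spearman correlations** are Pearson correlations of mid-ranks
  (tie-aware), pairwise-complete, p from the t approximation on $n-2$ df.
* **PCA** on the correlation matrix (variables standardized), which is the
  right scale for variables as heterogeneous as cm², mm, counts and
  dimensionless indices; covariance PCA is available behind `scale.`.
  Because EXR carries the opposite sign of the green-emphasizing indices,
  it is replaced by |EXR| before standardization by default. Observations
  are listwise-complete; constant variables are dropped with a warning;
  component signs are fixed so each component's largest-magnitude loading
  is positive.

A caveat the package's own null simulations expose: with 20 groups of 3
observations, the chi-square approximation to the Kruskal-Wallis null is
conservative — the empirical size at nominal α = 0.05 is around 1–2 %, not
5 %. The test suite asserts the honest property (size never exceeds
nominal). Users should read non-significant entry effects at this design
size as weak evidence, not strong absence.

## The synthetic field generator

The generator emulates the design of a two-acquisition kenaf trial: 24
entries × 3 replicates = 72 rectangular plots, 15 plants per plot,
plants 25 cm apart, on black mulch with four calibration panels
(3/12/36/56 %) along one edge, imaged at two growth stages ("set 1" early,
"set 2" late). Where the emulated design leaves details open, the
generator fixes them once:

* **Planting grid**: "fifteen seeds 25 cm apart" is laid out as a 5 × 3
  grid (a single 3.5 m row would make plots needlessly elongated); one
  entry (default `E02`) is flagged non-germinating, so 72 plot ROIs exist
  but 69 plots carry plants.
* **Camera**: 72.3° horizontal field of view, 4000 px sensor width, 40 m
  altitude → 1.46 cm/px nominal ground sampling distance.
* **Radiometry**: mulch reflectance 4 % in all bands (dark, spectrally
  flat); canopy pixels have total reflectance 0.30 split green-dominantly
  (fraction $g$ per plot, defaults 0.42 early / 0.48 late); DN are
  obtained by inverting the per-flight exponential model, adding Gaussian
  DN noise (sd 1), and quantizing to 8 bits (16-bit option). Top-of-range
  clipping warns: with the early-flight blue coefficients the 56 % panel
  sits near DN 254, so mild saturation under noise is expected and those
  pixels are excluded from panel means.
* **Geometry**: plants are soft-edged disks (2 cm edge ramp centered on
  the disk boundary) so the hard-disk truth mask is an exact area oracle;
  plant centers are snapped to pixel centers, and the tallest plant's dome
  apex equals the plot's true height exactly, making height extraction
  exact in the noise-free case. The DTM is a smooth 0–30 cm gradient so
  height extraction is tested against non-flat terrain; DSM noise
  defaults to sd 0.5 cm.
* **Trait structure**: all plot traits (height, canopy radius, stem
  diameter, node count, greenness) are linear in a latent growth factor
  shared within a plot (entry effect + replicate noise, sd 0.3), plus
  independent noise. Set-1 loadings are near zero (early-stage traits
  are essentially uncorrelated); set-2 loading-to-noise ratios are ≈ 1.4,
  giving population correlations of roughly 0.55–0.75 among traits — the
  magnitude range reported for late-stage kenaf trials — with greenness
  loading positively so green indices rise, and EXR falls, with growth.

What the generator deliberately does **not** emulate: canopy texture,
self-shadowing and specularity, SfM reconstruction artifacts, mosaic seam
lines, lens distortion, georeferencing error, weeds, and within-canopy
reflectance gradients. Green tests therefore demonstrate that the
*algorithms* are correct and the pipeline recovers known truth under
realistic noise — not that segmentation or calibration would survive every
field condition.

```{r example, eval = FALSE}
study <- simulate_study(seed = 1)
sc <- study$scenes[["2"]]
elm <- fit_elm(extract_panel_samples(sc$dn, sc$panel_rois, dn_max = 255))
refl <- apply_elm(elm, sc$dn)
traits2 <- extract_plot_traits(refl, sc$dsm, sc$dtm, sc$plot_rois)
head(traits2)
```

## Numerical choices and degenerate inputs

* Otsu requires ≥ 2 distinct values; constant input is an error, and
  thresholds are exactly reproducible (fixed binning, lowest-edge ties).
* `fit_elm()` refuses under-determined bands (< 2 distinct DN) and
  non-positive reflectance; `invert_elm()` refuses non-positive targets,
  naming the band.
* Empty ROIs (no pixel centers) are errors naming the feature; plots with
  no plants are signals (NA), not errors.
* Rasters are stored as plain TIFF with a JSON sidecar carrying the
  affine transform, band names and value scaling: integer DN round-trips
  bit-exactly, continuous rasters to ~1 part in 4 × 10⁹ of their span
  (power-of-two scale/offset, 32-bit samples).
* All randomness is seeded; a study, a scene or the whole pipeline
  rerun with the same seed reproduces outputs byte for byte.

## Problem sizes used by the test suite

Unit tests run on a reduced trial (4 entries × 3 replicates, 6 plants per
plot, a coarser 80 m-altitude camera) that renders in under a second; the
acceptance checks render the full 24 × 3 design once at the native
1.46 cm/px ground sampling distance (two ~1550 × 710 px scenes) and reuse
it, run a 2000-replicate null simulation for the rank-test size, 200
generator replicates against a 10⁶-draw Monte-Carlo correlation oracle,
and an exhaustive compact-letter check over all patterns up to 5 groups.
These sizes were chosen to exercise every code path at full design scale
while keeping a complete run in the low tens of seconds.

## Known limitations

* The chi-square Kruskal-Wallis size issue at 3 replicates, above.
* Plot VI means in the default all-ROI mode conflate cover and color;
  use canopy-only mode when tissue color itself is the question.
* The empirical-line model is per-flight; no cross-flight BRDF or
  illumination transfer is attempted.
* Heights come from the ROI maximum of DSM − DTM, so a single tall weed
  or reconstruction spike inside the ROI sets the plot height; the
  generator's DSM noise tests cover Gaussian error, not spikes.
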