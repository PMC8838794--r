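---
title: "Detecting lodged maize with the spectral sum index: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting lodged maize with the spectral sum index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lodgedetect)
```

## The detection model

When maize lodges, the canopy collapses from a rough, vertically structured
surface into a flat mat of stacked stems and leaves. Three physical effects
follow: the effective reflecting surface grows and its roughness drops; the
low-reflectance contributions of shadowed leaves and soil shrink as the mat
closes over them; and the disruption of photosynthesis slowly degrades
chlorophyll and water content. All three push surface reflectance *upward,
in every band* from blue through near-infrared.

That same-direction change is why this package sums bands instead of
differencing them. The spectral sum index at a pixel,

$$\mathrm{SSI} = R_1 + R_2 + R_3 + R_4,$$

accumulates the per-band increases, while NDVI,
$(R_4 - R_3)/(R_4 + R_3)$, subtracts two quantities that moved together and
so barely responds (it drifts slightly downward as growth is inhibited).
`class_band_statistics()` quantifies this contrast on any scene: on
default-parameter synthetic scenes the SSI class means differ by roughly
27 % of the upright-class mean, against an NDVI change an order of
magnitude smaller and of opposite sign. Detection is then one comparison
per pixel: a maize pixel whose SSI is *strictly greater* than the threshold
is lodged, all others upright. Strictness at the boundary follows the
method's definition of the lodged region as the pixels *above* the cut; a
pixel exactly at the threshold is upright. The maize mask is applied last
and dominates everything: no pixel outside it can be lodged, whatever its
SSI, which protects the map from bright non-crop surfaces (bare soil,
buildings) that share high sums.

The model's assumptions are worth stating plainly. It is a binary,
per-pixel model: lodging severity (inclination angle) is not graded, mixed
pixels are forced to one side, and the threshold is global per scene —
appropriate when one storm event hit one crop stage across the scene, which
is the situation the method was designed for.

## Threshold choice

The default threshold is **0.62** (unitless SSI), the packaged operating
point for post-typhoon maize at the milking–maturation stage; it sits in
the gap between class means of about 0.57 (upright) and 0.73 (lodged).
When labelled regions of interest are available and a manual value is not
trusted, `select_threshold()` offers two data-driven selectors:

* `boxplot_midpoint` — the midpoint between `max(upright)` and
  `min(lodged)` when the training values do not overlap; with overlap it
  falls back to the midpoint of the two class medians, a robust centre that
  ignores tail excursions.
* `variance_maximization` — Otsu's criterion on the pooled values: the cut
  maximizing the between-class variance $w_1 w_2 (m_1 - m_2)^2$. Candidate
  cuts are the midpoints of consecutive sorted unique values (no search
  grid to tune); ties break toward the lower cut, which errs on the side
  of flagging more lodging. A pooled sample with a single unique value has
  no cut and raises a degenerate-separation error rather than guessing.

The test suite pins `variance_maximization` to an independent oracle that
minimizes pooled within-class variance over an exhaustive enumeration of
candidate cuts, on lists up to 1 000 values.

## The synthetic landscape generator

No imagery ships with the package, so `generate_scene()` builds landscapes
with exactly the statistical structure the detector relies on, and nothing
more:

* **Patch structure.** The grid is tiled into square field patches
  (`patch_scale`, default 16 px = 256 m at the default 16 m cell — a
  realistic field edge for mechanized maize in north-east China). Whole
  patches are drawn as maize vs background (`maize_fraction`, default 0.6,
  matching a maize-dominated county) and maize patches as lodged vs upright
  (`lodged_fraction`, default 0.5456, a severe post-typhoon event). Drawing
  without replacement at patch level pins realized fractions to the targets
  within patch-count granularity.
* **Spectra.** Each pixel draws independent per-band Gaussian reflectance
  around its class mean, clipped to [0, 1]. The default class means are the
  measured post-storm values for upright maize (0.0188, 0.0496, 0.0327,
  0.4703) and lodged maize (0.0400, 0.0829, 0.0639, 0.5389); background
  defaults to a bright bare-soil-like spectrum (0.10, 0.12, 0.15, 0.28)
  whose SSI of 0.65 deliberately straddles the threshold, so the maize
  mask — not luck — keeps it out of the map.
* **Noise level.** Per-band class standard deviation defaults to 0.01
  reflectance, giving an SSI class sd of 0.02 (four independent bands).
  Two constraints fix this once: the SSI distributions must separate
  cleanly around 0.62 as the field data's box plots do (the gap is
  ±~3.9 sd, so overlap is confined to field edges), and clipping at zero in
  the darkest band (blue, upright mean 0.0188) must leave class means
  essentially unbiased — the analytic clipped-normal shift is under
  2×10⁻⁴ at sd 0.01, within the generator's moment-recovery contract,
  whereas at sd 0.015 it would not be.
* **Paired acquisitions.** `generate_paired_scenes()` lays the truth on the
  coarse grid, replicates it to a fine grid at an integer block ratio
  (default 4, e.g. 16 m → 4 m), adds pixel noise on the fine grid, and
  produces the coarse bands as exact block means. An integer ratio was
  chosen over the real sensors' non-integer 16 m/3 m ratio because it makes
  aggregation exact and the zero-noise cross-comparison identity testable
  to machine precision; the comparison statistic is area-based, so the
  ratio itself carries no scientific content. Partial fine coverage is one
  contiguous block-aligned band of rows (default 0.83 of the extent),
  mimicking swath coverage while keeping the shared-footprint area
  accounting exact.
* **Ground data.** `generate_sample_points()` places points without
  replacement on maize-truth pixels, balanced over the two labels, and
  splits train/validate by largest-remainder rounding so realized
  proportions sit within one point of the target; an `n_train` override
  reproduces historical campaigns whose splits were not exact fractions.
  `generate_survey()` models respondents who report the true grade with
  probability `1 − misreport_prob` and an adjacent grade otherwise —
  adjacent-only confusion keeps modal-grade recovery analyzable while still
  letting the mode fail at small n.

Everything is deterministic under the seed (`withr::with_seed`), and
identical parameters give bit-identical scenes.

What the generator does **not** emulate matters for interpreting green
tests: there is no radiative-transfer or canopy-geometry physics, no
within-field spectral gradients, no mixed pixels beyond hard patch edges,
no clouds, haze, topography or co-registration error, and class
reflectances are uncorrelated across bands where real canopies correlate
strongly. Passing tests therefore demonstrate that the algorithms are
implemented correctly and behave as designed under the assumed statistical
structure — not that the 0.62 threshold or the accuracy levels transfer to
any particular real sensor scene.

## Validation statistics

The error matrix is oriented rows = reference (field label), columns =
mapped class; producer's accuracy is row-wise, user's accuracy column-wise,
and overall accuracy the diagonal share. The identity
$\mathrm{OA} = \sum_c w_c \,\mathrm{PA}_c$ with $w_c$ the reference row
shares is asserted to 10⁻⁹ before rounding. Validation points that land on
non-maize or nodata pixels are excluded from the matrix, counted, and
reported — silently dropping them would bias accuracy upward.

The cross-resolution difference is
$D = (S_{\text{coarse}} - S_{\text{fine}})/S_{\text{fine}} \times 100$,
computed strictly over the footprint the fine sensor covered: fine-scene
areas over its valid pixels, coarse-scene areas over coarse pixels whose
entire block of fine pixels is valid. $D$ is signed; swapping the roles
rescales it by the area ratio rather than flipping its sign, and the tests
assert that formula consistency rather than a naive antisymmetry.

Survey grades are the five quintile bins treated as contiguous real
intervals, half-open upward with 0 in the lowest bin, so every proportion
in [0, 100] has exactly one grade. The modal grade breaks ties toward the
higher grade (flagged in the output): under-calling a severe event is the
worse operational error.

## Numerical conventions

* Published-style percentages and reflectances are rounded **half away
  from zero** (2 and 4 decimals respectively) via `round_half_up()`;
  base R's round-half-to-even would turn 88.235 into 88.23. A 10⁻⁹ guard
  absorbs binary-representation error on decimal ties. Unrounded values are
  retained alongside (`accuracy_raw`, `d_raw`, raw tibble columns).
* NDVI pixels with $R_3 + R_4 = 0$ become nodata — an undefined ratio, not
  zero vegetation.
* Areas: 1 pixel = `cell_size`² m², 1 ha = 10⁴ m²; reports carry ha and
  thousand ha.
* Raster storage uses multi-page 32-bit TIFF with a JSON sidecar for the
  georeference (top-left origin, north-up, pixel-is-area; points are
  located by containing pixel). The codec quantizes samples onto a
  [0, 1]/2³² grid, so index maps are stored with a linear scale/offset
  recorded in the sidecar and round trips are exact to ~2×10⁻¹⁰ —
  comfortably inside float32 precision, though a rewrite is not guaranteed
  byte-identical. Class maps (8-bit codes), point sets, surveys, configs
  and reports round-trip exactly.

## Problem sizes

The shipped tests run the full pipeline on 40–128 px scenes, the
moment-recovery checks on a 512×512 scene, and the parameter-recovery
property on twenty seeded 256×256 scenes across lodged fractions 0.2,
0.5456 and 0.8179 — sizes chosen so the whole suite completes in seconds
while every estimate they assert (fractions to ±2 points, means to 4
standard errors) is statistically meaningful at those n.

## Known limitations

Severity grading by inclination angle, optical–microwave fusion for cloudy
scenes, SVM-based maize mapping (the mask is an input here), atmospheric
and geometric preprocessing, and reprojection between coordinate systems
are all out of scope. The threshold default is an operating point for one
crop, one phenological stage and one sensor family; new settings should
re-derive it from training ROIs with either selector.
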