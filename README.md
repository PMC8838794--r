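# lodgedetect

Storm lodging — maize stems bent or snapped flat by wind — is one of the
most destructive late-season events in a maize landscape, and surveying it
on foot over whole counties is not realistic. `lodgedetect` maps lodged
maize from four-band (blue, green, red, near-infrared) surface-reflectance
imagery. It is written for remote-sensing analysts and agronomists who have
corrected reflectance scenes, a maize-extent mask from before the storm, and
some ground truth, and who need a lodged/non-lodged map with an honest
accuracy assessment.

## The method

A flattened maize canopy presents a denser, smoother reflecting surface and
hides the dark soil background, so reflectance *rises in every band* after
lodging. Instead of a normalized-difference index, whose subtraction cancels
a same-direction change, the package uses the **spectral sum index**:

    SSI = R1 + R2 + R3 + R4

where R1–R4 are the blue, green, red and NIR surface reflectances. Lodged
maize separates from upright maize by a wide SSI gap (class means around
0.73 vs 0.57 in the landscapes this package emulates), so a single cut —
0.62 by default, or one selected from labelled training values by box-plot
midpoint or between-class variance maximization (Otsu's criterion on the
pooled values) — classifies each maize pixel. Pixels with SSI strictly above
the threshold are lodged; the maize mask confines the classification; cell
area converts pixel tallies to hectares.

Results are validated three ways, mirroring operational practice:

1. **Error matrix** — reference labels (rows) vs mapped classes (columns)
   over held-out ground points, with producer's, user's and overall
   accuracy;
2. **Cross-resolution comparison** — the signed percent difference
   `D = (S_coarse − S_fine) / S_fine × 100` between lodged areas mapped from
   a coarse (e.g. 16 m) and a fine (e.g. 3–4 m) sensor over the footprint
   the fine sensor actually covered;
3. **Survey consistency** — whether the mapped lodged proportion falls in
   the modal lodging-proportion grade (0–20 % … 81–100 %) reported by
   farmer questionnaires.

Because no satellite scenes ship with the package, a seeded synthetic-scene
generator reproduces the statistical structure the method relies on:
contiguous field patches of background, upright and lodged maize, per-class
Gaussian band reflectance, paired coarse/fine acquisitions with partial fine
coverage, labelled ground points and survey responses. Every stage of the
pipeline is exercised end to end on these scenes.

## Worked example

```r
library(lodgedetect)

p    <- scene_params(extent = c(256L, 256L), seed = 2026L)      # 16 m cells
pair <- generate_paired_scenes(p, block_ratio = 4, coverage_fraction = 0.83)
pts  <- generate_sample_points(pair$coarse, n = 140, train_fraction = 0.7,
                               seed = 2026L)

res <- run_detection_pipeline(pair$coarse, config = detection_config(threshold = 0.62))
res
#> <lodging_result> threshold 0.6200
#> <lodging_map> 256 x 256 px @ 16 m; lodged 21504, non-lodged 17920, non-maize 26112 (threshold 0.62)
#>   lodged 0.55 kha of 1.01 kha maize (54.55%)
```

With the paired fine scene classified at the same threshold, a simulated
survey, and the held-out points, the three validation checks consolidate
into one report:

```r
fine   <- run_detection_pipeline(pair$fine, maize_mask = pair$fine$truth > 0L,
                                 config = detection_config(threshold = 0.62))
survey <- generate_survey(0.5456, n_respondents = 18, misreport_prob = 0.1,
                          seed = 2026L)
run_validation(res, points = pts, fine_result = fine,
               fine_valid = !pair$fine$nodata_mask, survey = survey)
#> <validation_report>
#> <error_matrix> reference rows x mapped columns
#>             mapped
#> reference    lodged non-lodged
#>   lodged         21          0
#>   non-lodged      0         21
#>   OA 100.00%; PA lodged 100.00%, non-lodged 100.00%; UA lodged 100.00%, non-lodged 100.00%
#>   cross-comparison: coarse 0.48 vs fine 0.48 kha, D = -0.54%
#> <survey_summary> modal grade 41-60%, mapped grade 41-60% -> agreement
```

Reading the output: the 42 held-out points are all mapped correctly (at this
noise level the SSI class gap is ~7 standard deviations wide, so
misclassification is confined to mixed pixels near field edges); the coarse
map's lodged area agrees with the fine map's within half a percent over the
83 % footprint the fine sensor covers; and the mapped lodged share (54.55 %)
lands in the 41–60 % grade that most simulated respondents chose. The
spectral-change table behind the index is available as a tibble via
`class_band_statistics(pair$coarse, points = pts)`, and `tidy()`, `glance()`
and `autoplot()` methods expose every result for dplyr/ggplot2 workflows.

A shell entry point wrapping the same functions ships in
`inst/cli/lodgedetect.R` with subcommands `simulate`, `ssi`, `detect`,
`validate` and `run-all`.

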