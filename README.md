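# dermoborder

Automated measurement of skin lesion **border irregularity** — the *B* of
the clinical ABCD melanoma screening rule. Inter-observer agreement on
whether a naevus border is irregular is notoriously poor; this package turns
the judgment into a reproducible computation for image-analysis researchers
and method developers working with dermoscopy-style images.

The pipeline:

1. **Segmentation** — fuzzy c-means (c = 2, lesion vs. skin) refined by a
   type-II fuzzy *ambiguity threshold*: an S-function membership profile is
   slid along the gray range, its footprint of uncertainty
   (μ^1/α − μ^α, α = 2) averaged over the histogram gives the
   *ultrafuzziness* γ̃(g), and the maximizing position τ separates confident
   from ambiguous pixels. Ambiguous pixels are resolved by *gradual
   focusing*: a raster sweep assigning each to the majority cluster of its
   already-assigned neighbors (ties keep the highest-membership cluster).
2. **Border detection** — the four-step Canny detector (separable Gaussian,
   2×2-stencil gradient, sector-quantized non-maximum suppression,
   hysteresis linking), returning the longest closed contour as an ordered
   trace.
3. **Irregularity descriptor** — 27 values per lesion:
   the box-counting **fractal dimension** D (slope of log N(ε) vs.
   log(1/ε), dyadic ε), the **convexity** C (hull perimeter / lesion
   perimeter, both as 8-connected arc lengths), and 25 **Zernike moment
   magnitudes** (orders n ≤ 8, unit-disc mapping at the centroid, unit
   mass — so |Z₀₀| ≡ 1/π ≈ 0.3183).
4. **Classification** — a Gaussian naive Bayes on the descriptor and a
   compact 5-conv/5-pool/2-dense CNN on the segmented image + border map,
   fused as P = (CNN₁·GnB₁ + CNN₂·GnB₂)/2, thresholded per test batch at
   (max P + mean P)/2; above = irregular.

A seeded synthetic-lesion generator (smooth ellipses = regular, harmonic
rough blobs = irregular, with ground-truth masks) makes the whole pipeline
testable without clinical data.

## Worked example

```r
library(dermoborder)

les  <- make_regular_lesion(size = 256, axes = c(60, 40), contrast = 120,
                            noise_sd = 8, seed = 1)
mask <- extract_lesion_mask(les$image)
jaccard_index(mask, les$mask)
#> [1] 99.31108

tr <- canny_border(mask)
tr
#> <border_trace> 292 points, closed, perimeter = 335.1 px

round(irregularity_vector(mask, tr)[1:5], 4)
#>     FD      C    ZM1    ZM2    ZM3
#> 0.9657 1.0000 0.3183 0.0000 0.2434
```

The segmentation recovers the ground-truth mask at Jaccard 99.3%; the
recovered border of the 60×40 ellipse has arc length 335 px (the ellipse
perimeter is ~317 px; 8-connected traces run a few percent long). The
descriptor reads as: fractal dimension ≈ 1 (smooth border), convexity 1
(convex), ZM1 = 1/π as it must be. A rough lesion
(`make_irregular_lesion(..., roughness = 0.45)`) gives `FD 1.134, C 0.733`
instead — the high-FD/low-C quadrant that marks irregular borders.

Metric arithmetic, from a confusion description (40 irregular of which 3
were called regular; 7 regular, all correct):

```r
evaluate(c(rep("irregular", 37), rep("regular", 3), rep("regular", 7)),
         c(rep(0, 40), rep(1, 7)))
#> <lesion_metrics> n = 47
#>            predicted
#> truth       irregular regular
#>   irregular        37       3
#>   regular           0       7
#> accuracy 93.6% | sensitivity 100.0% | specificity 92.5% | F-score 96.1%
```

End to end: `train_pipeline(samples, pipeline_config())` fits both
classifiers on segmented training lesions; `run_pipeline(test, models)`
returns a tibble of per-image decisions. A thin CLI (`exec/dermoborder`)
exposes `synth`, `segment`, `border`, `features`, `train`, `predict` and
`evaluate` subcommands over the same functions. See the vignette
(`vignettes/border-irregularity.Rmd`) for the method details, parameter
choices and limitations.

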