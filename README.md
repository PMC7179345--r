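# dotshape

Shape encoding from sparse boundary markers, and a simulated
match-recognition experiment to test it.

Human observers can identify a shape from a handful of dots placed on its
outer contour, and can judge a moment later whether a sparse, shifted,
resized comparison display shows the *same* shape. Whatever summary the
visual system computes from boundary markers must therefore be compact,
deletion-tolerant, and largely invariant to translation and size.
`dotshape` is a laboratory for two candidate summaries of a dot-boundary
display:

* **Scan encoding.** Count the lit dots in each row and each column of
  the display board (a single 128-bin histogram on the default 64 x 64
  board), delete every empty bin, re-bin the remainder to 20 bins by
  fractional interval overlap, and normalize the heights to sum to 1.
  Two shapes are compared by the sum of squared differences (SSD)
  of their histograms, ∑ᵢ (aᵢ − bᵢ)². Translation invariant exactly
  (trimming removes positional zeros), size invariant approximately, and
  deliberately not rotation invariant.
* **Centroid-distance signature.** The normalized histogram of Euclidean
  distances from each lit dot to the dot-set centroid, scale-normalized
  by the mean distance; the angle at which a marker lies is discarded by
  construction. Translation and rotation invariant, size invariant when
  scale-normalized.

Around these sit a dot-boundary stimulus generator emulating an LED
display board (4.9 arcmin dots at 9.2 arcmin pitch), density sampling,
rigid/scale transforms, half-perimeter and opposite-quarters partial
displays, an all-pairs ranked similarity scale, and a same/different
match-recognition simulator analyzed with signal-detection theory
(d′ = z(H) − z(F), p(c)max = Φ(d′/2)) and per-respondent linear
regression of match probability on similarity.

The package is aimed at vision scientists who want the encoding claims —
invariances, pair-similarity scaling, centroid-displacement predictions —
testable end to end without human subjects.

## Worked example

```r
library(dotshape)

shp <- generate_inventory(3, seed = 11)[[2]]
shp
#> <dot_shape> 'shape_002': 119 boundary dots on a 64x64 grid

scan_encode(full_display(shp))
#> <scan_histogram> 'shape_002': 20 bins (joint re-binning), trimmed length 74

sparse <- sample_density(shp, 0.12, seed = 4)
sparse
#> <sampled_display> 'shape_002': 14 dots (density 12%, even sampling, full)

scan_similarity(scan_encode(full_display(shp)), scan_encode(sparse))
#> [1] 0.01971753
```

The full-density shape has 119 boundary dots; at 12% density only 14 are
lit, and the degraded display's scan histogram differs from the
full-density one by an SSD of about 0.02 — small relative to typical
between-shape values, which is why sparse comparisons remain matchable.

The end-to-end simulated experiment (480 shapes, 114,960 ranked pairs,
300 pairs selected at equal rank intervals, 90 same-trials, targets at
100% and comparisons at 12% density, 8 simulated respondents):

```r
report <- run_pipeline(pipeline_config(seed = 1))
report
#> <pipeline_report>
#>   inventory: 480 shapes on a 64x64 grid
#>   scale: 114960 ranked pairs, 300 selected; max similarity 0.04978
#>   design: 390 trials (90 same / 300 different) x 8 respondents
#>   SDT (pooled): d' = 0.261, p(c)max = 0.552
#>   group regression: intercept 0.707, slope -9.93

report$regression
#> <group_regression> mean model over 8 respondent(s)
#>   intercept 0.707  [0.646, 0.769]
#>   slope     -9.928  [-14.189, -5.666]
```

The group regression says: simulated respondents call the most similar
pairs "same" with probability about 0.71, declining linearly to about
0.21 at the top of the similarity scale (intercept + slope x scale
maximum), with a 95% interval on the slope that excludes zero — the
near-linear decline of match judgment with scan similarity. The pooled
p(c)max of 0.55 reflects that three quarters of the trials present
genuinely different shapes that the linear observer still often calls
"same" when their encodings are close.

See the vignette (`vignettes/shape-encoding.Rmd`) for the models,
parameter choices, and limitations, and `inst/scripts/dotshape` for a
command-line front end (`generate`, `sample`, `partial`, `encode`,
`pairs`, `simulate`, `render`).

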