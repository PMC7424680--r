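# dapdr

Developmental normalization of plant phenotyping time-series — with the
top-view rosette image pipeline that feeds it.

## The problem

High-throughput phenotyping platforms image hundreds of *Arabidopsis*
plants daily and extract the projected rosette area and leaf number.
Sowing time is the usual temporal reference, but seeds germinate on
different days even under uniform conditions, so at any fixed
day-after-sowing the population mixes developmental stages. Trait
dispersion inflates over the time-series and genuine outliers hide inside
it. `dapdr` aligns each plant's timeline to the population by
developmental stage instead.

## The method

Each plant's daily leaf number is fitted with an early-development
exponential trend, `leaf(t) = a·exp(b·t)`, by least squares over the
window where the count lies between 2 and 12 leaves. The population
reference is the mean of the fitted curves. A plant's whole-day shift `s`
minimizes the mean squared deviation

```
MSD(k) = (1/n) Σ_t ( leaf(t − k) − mean_trend(t) )²
```

over candidate delays `k ∈ −7..7` with at least 5 overlapping days; ties
break toward zero. Because equal leaf numbers can coexist with different
rosette expansion, the area series receives an extra whole-day adjustment
`Δt ∈ ±2` minimizing the log-area MSD against the mean area trend.
Normalized day `t` then carries the leaf value measured at `t − s` and
the area measured at `t − s + Δt` — values are re-indexed, never
interpolated or rescaled, so within-day (diurnal) area oscillations
survive unchanged.

Leaf numbers come from images: rosettes are segmented by a decision tree
choosing among K-means clustering, hue-histogram clustering
(Savitzky–Golay-smoothed, spatial-correlation-tested) and a
shape-assisted hue pipeline, run under several random gamma values with a
pixel-wise consensus and interpolation-based repair; leaves are counted
by marker-controlled watershed of the distance transform, with markers
derived from contour analysis (leaf tips as prominence-gated radius
maxima along the traced contour). Accuracy is scored with precision,
recall, Jaccard and Dice on pixel-exact synthetic ground truth; all
raster primitives are implemented in-package on plain matrices.

## Worked example

```r
library(dapdr)

pop <- generate_population(population_spec(n_plants = 50, seed = 1))
res <- normalize_population(pop$series)
res
#> DAPD normalization of 50 plants over days 12..32
#>   shifts s: -4×1, -3×5, -2×7, -1×8, 0×4, 1×8, 2×7, 3×10
glance(res)
#> # A tibble: 1 × 5
#>   n_plants n_flagged mean_abs_shift final_day sd_ratio_final_day
#>      <int>     <int>          <dbl>     <int>              <dbl>
#> 1       50         0           1.86        32               18.0
```

Fifty simulated plants with germination offsets of up to ±3 days were
re-aligned; no plant failed fitting, and the standard deviation of the
projected area at the final common day is 18 times smaller after
normalization (the offsets, not biology, dominated the raw spread).
Comparing `tidy(res)$s` with the generator's stored offsets shows 96%
exact recovery at 5% measurement noise.

```r
fx <- generate_rosette_image(rosette_spec(n_leaves = 8), seed = 2)
mask <- segment_rosette(fx$image, seed = 3)
mask_metrics(mask, fx$truth$mask)
#> # A tibble: 1 × 5
#>   precision recall jaccard  dice degenerate
#>       <dbl>  <dbl>   <dbl> <dbl> <lgl>
#> 1      92.4   99.8    92.2  96.0 FALSE
count_leaves(mask)
#> Leaf labelling: 7 leaves over 1833 foreground pixels
```

A synthetic 8-leaf rosette is segmented at Dice 96; the watershed counts
7 leaves on the segmented mask (the youngest leaf hides under the apex at
this seed — exactly the occlusion undercount the normalization model
anticipates).

A command-line front end mirrors the pipeline stage by stage:

```sh
Rscript inst/cli/dapd.R all --seed 4 --out runs/demo
# simulate | segment | count-leaves | normalize | evaluate | outliers
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computations from
scratch — generating the default synthetic population, normalizing it and
scoring shift recovery and dispersion; segmenting and counting the
20-image fixture suite; and running the outlier detection on a population
with a planted defect — and writes the results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
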