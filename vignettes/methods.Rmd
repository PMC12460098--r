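---
title: "Methods: sonar-based avoidance analysis in net pens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sonar-based avoidance analysis in net pens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`pensonar` measures how far a fish school keeps from a structure at the
centre of a sea pen, and whether that distance changes when a sound or
light stimulus switches on. This vignette documents the models and the
numerical decisions behind each stage, and what the synthetic experiments
do and do not establish about real farm data.

## 1. The measurement model

A 360° mechanical-scanning sonar suspended at the structure returns, per
revolution, an intensity array over bearing × range bins. The analysis
assumes the school responds to a centred intrusive object with an
*annular* distribution around it, so all information of interest is
radial. Each revolution is rendered onto a centred square raster
(`render_frame()`): the sample at bearing θ and range r lands on the
pixel nearest `centre + (r cos θ, r sin θ)/mpp`, overlaps combine by
maximum, bearing 0 points along +x, angles increase counter-clockwise and
the y axis points up. The raster side is odd so the sonar axis is a
single pixel; nothing beyond the maximum range is ever painted. The
coordinate convention is stated because only radial distances matter
downstream — any fixed convention gives identical distances.

Default geometry (all configurable via `sonar_config()`): 400 bearings ×
200 range bins at 0.05 m/bin (10 m range), 8 s per revolution, 0.5 m
central exclusion zone for the structure and its self-echo, raster
401 × 401 px at 0.05 m/px.

## 2. Phase windows and CFP images

A stimulus event lasts 60 s with a 10-min break before the next. The
first and last 5 s of each phase are transition periods and are
discarded, leaving 50-s *before*, *during* and *after* windows
(`phase_windows()`); a revolution contributes to a window only when its
full 8-s span lies inside it, so no image mixes bearings from both sides
of a stimulus transition.

The Cumulative Fish Presence (CFP) image of a window is the pixelwise
**maximum** over its revolutions. Maximum — rather than sum or mean —
encodes "was a fish ever detected here", which is exactly the semantics
the fish-free region needs: a pixel is only fish-free if no revolution
ever saw an echo there. Sum and mean remain available
(`accumulate_cfp(reduce =)`) for densitometric uses, but all analysis
paths use the maximum.

## 3. Synthetic trials and their ground truth

`simulate_frames()` generates trials with known behaviour:

* **Dynamics.** The ground-truth inner radius is `r0` before onset,
  relaxes exponentially toward `r0(1 + δ)` with time constant τ during
  exposure, and decays back with the same τ afterwards; five time
  constants past the offset the residual transient (< 1%) is truncated
  to exactly `r0`, so the after-window genuinely represents full
  recovery ("During > Before = After"). Published accounts of such
  trials report that the school returns to its original distance but not
  how fast; τ is therefore a free parameter of the generator (default
  1 s, i.e. recovery is complete well before the trimmed after-window
  starts), not an estimate of fish behaviour.
* **Radial spread.** Each agent sits at `r(t) + |N(0, σ)|`, σ = 0.5 m by
  default. The half-normal keeps the *inner* edge of the annulus crisp —
  the segmentation's key assumption — while still giving the annulus a
  realistic outward tail.
* **Echoes.** Each agent paints an isotropic Gaussian blob (sd 2 range
  bins × 1 bearing bin) scaled by lognormal speckle with CV 0.3;
  exponential background noise (mean 0.02 of the unit echo amplitude)
  covers every bin; a bright ring just inside the exclusion radius
  emulates the structure's self-echo. None of these values is measured
  from real sonar; they are chosen so that classical segmentation is
  non-trivial (noise exists, speckle varies echo strength several-fold)
  but solvable, which is the regime the pipeline is designed for.
* **Study conditions.** Effect-recovery experiments use `r0` = 2.0 m and
  150 visible agents per revolution; pen-to-pen differences (and
  attraction versus avoidance) are emulated purely through the sign and
  size of δ per treatment level. Flight beyond sonar range is modelled
  by letting `r0(1 + δ)` exceed the maximum range under an explicit
  `out_of_range_flag`.

What the generator does **not** emulate: schooling interaction forces,
hydrodynamics, acoustic/optic propagation, multipath and shadowing
artifacts, depth structure, or obstructions (cables, cameras) in the
sonar volume. Passing tests therefore demonstrate that the *pipeline*
recovers known annular behaviour from realistic-noise sonar streams —
not that real farm recordings are this clean.

## 4. Segmentation

Every CFP image maps to exactly one of three categories: `pattern`
(coherent annulus, star-shaped fish-free region containing the centre),
`out_of_range` (no fish within range; full-disc mask, distance censored
at max range — the category exists precisely to keep flight responses in
the data), and `invalid` (no coherent pattern; empty mask, excluded from
analysis).

The default, fully deterministic **classical backend**
(`segment_classical()`):

1. Binarise at the echo threshold, ignoring the exclusion zone. By
   default the threshold is Otsu's, with a bimodality guard: Otsu's
   split is accepted only when the above/below mean contrast exceeds
   15× (echo blobs are an order of magnitude brighter than background;
   splitting a unimodal exponential yields a contrast near 8×). For a
   unimodal image the structure self-echo provides the intensity
   reference: an annulus far darker than the structure has no echoes at
   all (→ `out_of_range` via the coverage rule), while an annulus as
   bright as the structure is saturated noise (→ `invalid` via the
   collapsed region below).
2. Per bearing, take the nearest above-threshold radius ρ(θ) beyond the
   exclusion zone (max range where the bearing is empty). If fewer than
   `coverage_min` = 5% of bearings show an echo, the school is out of
   range.
3. Smooth ρ circularly with a running median over 9 bearing bins — wide
   enough to reject single-bearing dropouts, narrow enough (≈ 8° at the
   default geometry) to follow genuine asymmetry. The fish-free region
   is the star-shaped set of pixels inside the smoothed profile.
4. Noise test: the fraction of above-threshold pixels inside the region
   *eroded radially by 3 px* must not exceed `noise_max` = 2%. The
   erosion margin exists because a median-smoothed boundary legitimately
   leaves roughly half the bearings' first echoes just inside the fitted
   contour; without the margin a perfectly clean annulus would fail its
   own noise test. A region that collapses onto the exclusion zone
   (fewer than 50 px) also yields `invalid`: echoes everywhere means no
   fish-free zone exists.

The **trainable backend** (`train_segmenter()`) is a single-hidden-layer
neural network classifying each (bearing, range) bin as fish-free from
scale-free features: radius fraction, normalised intensity, a local mean,
the prefix maximum at smaller radii on the same bearing, and the image's
global above-threshold fraction. The predicted per-bin mask is mapped to
a category by the same rules as the mask invariants — an (almost) full
disc of free bins is `out_of_range`, a collapsed region `invalid`,
anything else `pattern` with the region rebuilt from the predicted
per-bearing boundary. It is a deliberately small, trainable-in-kind
stand-in for large encoder–decoder segmentation networks used on real
sonar imagery: the category logic and mask contract are identical, the
capacity is desk-scale. Training requires all three categories in the
dataset and is seeded; it is deterministic up to the optimiser's
floating-point reduction order.

A manual-correction pathway for individual images is supported by
constructing masks directly (or editing PNG masks re-read with
`read_mask()`); no interactive tool is shipped.

## 5. Avoidance distance

The avoidance distance is the mean Euclidean distance from the fish-free
region's boundary pixels to the centre, times the pixel scale, plus a
constant half-pixel coverage offset. Two numerical conventions matter:

* **Boundary convention.** The contour is the standard 8-connected
  region / 4-connected background boundary: fish-free pixels with at
  least one axis neighbour outside the region. Using 8-neighbour
  "outside" tests instead admits diagonal-corner pixels down to
  `R − √2` on a disc of radius R and biases the mean radius by ≈ 0.7 px;
  the 4-neighbour test keeps every contour pixel within one pixel of the
  geometric boundary.
* **Half-pixel offset.** The centres of the last fish-free pixels lie
  half a pixel inside the boundary they represent, so 0.5 px is added to
  the mean contour radius. With both conventions, a centred disc of
  radius 60 px at 0.05 m/px measures 2.999 m. Sub-pixel contour
  refinement beyond this constant is out of scope.

`out_of_range` masks yield exactly the maximum range, flagged
`censored = TRUE`. Censored values are *included* in the statistics by
default (conservative: it underestimates flight magnitude); the flag is
carried so a sensitivity analysis can exclude them. `invalid` images
raise a typed not-measurable condition and appear in run logs, never in
analysis tables.

On clean synthetic trials the estimated distance tracks the ground-truth
phase means within 10%: the half-normal spread shifts the first-echo
radius slightly outward while the echo blob's inward tail shifts it
slightly inward, leaving a small net offset that is common to all phases
and largely cancels in during-versus-before ratios.

## 6. Permutational ANOVA

The response (avoidance distance, m) is univariate and compared by
Euclidean distance, so the distance-based SS partition — Gower-centred
inner-product matrix projected onto sequentially orthogonalised term
subspaces — coincides with classical ANOVA sums of squares; the test
suite asserts that equivalence to a relative error of 1e-8, and cross-
checks the one-factor case against an independent distance-based
implementation. The engine is nevertheless written in the distance
formulation throughout, because that is the estimator family the design
(crossed fixed/random factors, permutation inference) belongs to.

Decisions a reader should know:

* **Denominators.** Expected-mean-squares rules for crossed mixed
  models, with at most one random factor: a purely fixed term crossed
  with the random factor is tested over that interaction's MS (e.g.
  Timing over Timing × Pen); every term containing the random factor is
  tested over the residual. The lookup is printed in each result table's
  `denom` column.
* **Permutation scheme.** Freedman–Lane: for the term under test, the
  reduced model contains every term *not containing* the tested term's
  factors; permuted responses are reduced-model fitted values plus
  permuted reduced-model residuals. Excluding higher-order relatives of
  the tested term from the reduced model is essential — with treatment
  coding their columns would otherwise absorb the tested effect and the
  permutation null would collapse onto the observed statistic.
* **p-value convention.** The observed statistic counts in numerator and
  denominator: `p = (#{F* ≥ F} + 1)/(n_perm + 1)`, so p ∈
  [1/(n_perm+1), 1]. With `exhaustive = TRUE` (n ≤ 9) all n!
  permutations are enumerated and p is the exact fraction, observed
  included by construction.
* **Monte-Carlo p.** The F(df1, df2) upper tail, reported for every term
  and intended for use when fewer than ~100 unique assignments exist
  (`n_unique`, the multinomial coefficient over the tested term's
  cells). For the univariate Euclidean case this reference distribution
  is the asymptotically exact one; the moment-matched sampling some
  software uses for general dissimilarities is out of scope.
* **Pooling.** Terms with permutation p ≥ 25% are merged into the
  residual, iterating from the highest interaction order downward and
  respecting marginality (a term is never pooled while a retained
  higher-order term contains it); a `keep` argument protects terms of
  primary interest. SS additivity is re-checked after pooling. Pooling
  the last remaining term is refused as a degenerate design.
* **Degenerate inputs.** Rank-deficient designs (empty cells in a fitted
  interaction), zero denominator mean squares, and levels with fewer
  than two observations raise typed errors rather than silent results.
  Ties in permuted statistics are counted as exceedances (a relative
  1e-12 tolerance guards floating-point equality).

## 7. Problem sizes and calibration

The package's own experiments are sized for a single CPU: effect
recovery uses 3 replicate events per condition at the full default
geometry (≈ 250 revolutions per trial, ≈ 2 s to simulate and measure);
the type-I calibration uses 1000 null datasets of 3 × 10 observations
with 999 permutations each (≈ 15 s); the bundled miniature fixture
(`make_fixtures()`) is a 120 × 50-bin sonar with 101 × 101 px rasters
that runs a complete pipeline in well under a second. The calibration
places the empirical rejection rate at the 5% level within its binomial
95% confidence band, and power is monotone in effect size on the same
grid (`analysis/04_calibration.R` prints both).

## 8. Known limitations

* The segmentation assumes a star-shaped (annular) fish-free zone
  centred on the structure; schools wrapping non-radially (e.g. split
  schools, off-centre voids) violate the per-bearing first-echo model.
* The trainable backend shares its category-decision thresholds with the
  mask invariants but its feature set is hand-designed; it is not a
  substitute for a full encoder–decoder on real imagery.
* Censoring at max range compresses genuine flight responses; with many
  `out_of_range` images the Timing effect is underestimated.
* One sonar stream is processed per trial; fusing top and bottom sonars
  is out of scope.
* The PERMANOVA engine is univariate-Euclidean by design; multivariate
  responses and non-Euclidean dissimilarities are not supported.
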