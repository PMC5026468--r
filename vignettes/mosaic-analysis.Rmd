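---
title: "Quantifying retinal mosaics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinal mosaics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retmosaic)
```

This vignette documents the science behind each measurement in
`retmosaic`, the tunable parameters and their defaults, the numerical
choices made where conventions diverge, and what the synthetic-data tests
do and do not establish about real data.

## The measurement problem

Neurons of one retinal cell type are arranged in a mosaic: somata keep an
exclusion zone around themselves, and their neurites tile the field
without bundling. Degraded mosaics show up in three complementary spatial
statistics computed from per-image cell coordinates (ImageJ XY exports,
converted to µm at read time), and degraded neurite self-avoidance shows
up as fasciculation, which is graded by blinded pairwise comparison. All
group comparisons use the *retina* as the experimental unit: per-image
values are averaged to retinal means before any test.

## Density recovery profile

For every ordered pair of distinct cells the pair distance is tallied into
half-open annuli `[r, r + Δr)` around the reference cell. The count in
annulus *i* is divided by the summed annulus area to give a density
`ρ_i`, and by the overall density `D = n / |W|` to give the normalized
profile, whose far field is 1 for any stationary pattern.

**Edge correction.** Annuli near the window boundary are partly outside
the field; uncorrected, the profile decays artificially at large radii
(a bias the test suite demonstrates). Each annulus∩window area is computed
analytically for the rectangular window by a corner decomposition of the
circle–rectangle intersection integral, so the correction is exact and
deterministic.

**Effective radius.** The exclusion zone is summarized by the dead-space
volume accumulated over the *initial contiguous run* of bins with
`ρ_i < D`, stopping at the first bin that recovers to the overall
density:

```
V = Σ (D − ρ_i) · a_i / n_ref        (over the initial deficit run)
r_eff = sqrt(V / (π D))
```

Restricting the sum to the initial run is deliberate. Beyond the
recovery point every bin fluctuates around `D` with binomial noise, and
each below-average fluctuation contributes a strictly positive term; a
sum over *all* below-average bins therefore grows with the number of bins
and assigns a random pattern a substantial spurious effective radius
(packing factor ≈ 0.2 in the acceptance geometry rather than ≈ 0). The
initial-run rule keeps the defining anchors exact: a pattern with no
exclusion zone scores ≈ 0, and a perfect triangular lattice — empty out
to its lattice spacing, then a sharp recovery spike — scores ≈ 1.

**Packing factor.** `PF = (r_eff / r_max)²` where
`r_max = sqrt(2/(√3·D))` is the spacing of the triangular lattice at the
same density, i.e. the largest exclusion zone the density permits. PF is
clipped to [0, 1] and is invariant under uniform rescaling of the
coordinates and window.

**Parameters.** `bin_width` defaults to a quarter of the mean NN distance
(fine enough to resolve the exclusion zone, coarse enough that bins hold
many pairs); `max_radius` defaults to ten mean NN spacings, capped at half
the shorter window side so edge correction never dominates. Distances are
nudged by `+1e-9·Δr` before tallying so a lattice spacing computed as
49.999999999… lands in its true bin; without this, a perfect lattice
loses a full bin of dead space to floating-point rounding.

## Voronoi domain regularity

Each cell's domain is the window intersected with the half-planes closer
to it than to every other cell, computed by perpendicular-bisector
clipping with a distance cutoff (a site whose half-distance exceeds the
cell's current reach cannot cut it). The clipped domains exactly
partition the window — asserted to 1e-6 relative in tests. Cells whose
polygon touches the window boundary are excluded from the statistics:
their domains are truncated by the field of view, not by neighbors. The
exclusion count is always reported.

The regularity statistic is the variance-to-mean ratio of the retained
areas, using the sample (n−1) variance since retinal fields have modest
n. The VMR has units of area and is therefore not fully
density-controlling; the dimensionless `CV² = var/mean²` is reported
alongside, and the tests pin down both behaviors (CV² scale-free, VMR
scaling with the square of the magnification).

## Nearest-neighbor regularity

`NNRI = mean(d_NN) / sd(d_NN)` with the sample SD. A homogeneous Poisson
pattern has Rayleigh-distributed NN distances, giving the closed-form
limit `0.5·sqrt(4π/(4−π)) ≈ 1.913` that the suite recovers by
simulation. A perfect lattice has zero SD and is reported as a degenerate
condition, not a number.

The comparable quantity across images is the ratio of the measured NNRI
to the mean NNRI of random arrays with the same point count in the same
window. Because measured and random arrays share the window, edge bias
cancels in the ratio (no NN edge correction is applied, by design).
`n_reps` defaults to 99: a single random array (the literal historical
procedure, available as `n_reps = 1`) leaves ~5% noise in the
denominator; 99 replicates shrink it an order of magnitude at negligible
cost.

## Elo fasciculation scoring

Observers blind to genotype pick the less-fasciculated of two images;
the log of forced choices drives a zero-sum rating. Every image starts at
0. After a matchup the winner gains `Δ = k·(1 − E_win)` and the loser
loses the same, with the chess-standard expected score
`E = 1/(1 + 10^(−(r_win − r_lose)/s))`. Upsets exchange more points than
expected wins by construction. Defaults `k = 32`, `s = 400` are the
standard tournament constants; only rating *differences* matter, so the
0 start replaces the chess 1500 with no effect on the dynamics.

`run_tournament()` presents uniformly random distinct pairs in sweeps of
one matchup per image on average and stops when the rank order of
genotype mean ratings has been unchanged for `stability_window = 5`
consecutive sweeps (the endpoint: further matchups do not change the
relative genotype ranking), or at `max_rounds = 200`. Multiple raters'
choices are pooled into one rating pool in arrival order, matching a
shared scoring instance; per-rater tournaments on the same latent truth
correlate at Spearman ≥ 0.8 in the consistency tests.

Final ratings are averaged per retina and compared across genotypes by
Wilcoxon rank-sum (exact when combined n ≤ 20 and untied), with BH
adjustment over the genotype pairs.

## Image metrics

- `percent_area_above()` counts pixels *strictly* above each threshold —
  one fixed convention, since thresholding tools differ by version. The
  three threshold levels are required configuration, not defaults.
- `overlap_ratio()` is `|A∧B| / |B|` on thresholded masks: mask
  intersection is mathematically the thresholded-multiply colocalization
  workflow, made deterministic. The denominator is the marker channel, so
  the measure is intentionally asymmetric.
- `line_profile_mean()` samples bilinearly at pixel-pitch steps along a
  segment (default length 10 µm) and averages; pixel centres sit at
  `(j−0.5, i−0.5)·scale` with the image-convention origin at top-left.

Inputs are already-projected 2D images; 3D reconstruction and cropping
are upstream of this package.

## Synthetic data: what it emulates, what it does not

The generators reproduce the spatial *regimes* the measurements must
distinguish — exclusion-zone mosaics (sequential inhibition with hard
`dmin`), randomness (binomial points), clustering (Neyman–Scott with
Gaussian dispersal), near-crystalline order (jittered triangular
lattice) — plus Bradley–Terry raters over latent image qualities and
binary images with exact area/overlap fractions. Sequential inhibition
was chosen over dependent thinning because it is the simplest process
with an exact hard-core signature; Bradley–Terry matches the latent-
strength assumption underlying Elo itself.

Passing tests on these patterns shows the estimators recover known
ground truth in their operating regimes. It does not show robustness to
what real images add: segmentation errors, soma-size effects (soft rather
than hard exclusion), density gradients across the retina, or rater
idiosyncrasies beyond a logistic choice model.

Default simulated study conditions mirror typical experiments of this
kind: 1000×1000 µm fields, 120–300 cells per image, dmin ≈ 40–50 µm,
2–3 images per retina, 4–8 retinas per genotype, 6 raters and ~50
matchups per image for the Elo suites.

## Numerical choices and degenerate inputs

- Bins half-open; a pair distance exactly at `max_radius` is excluded.
- Duplicate coordinates are an error everywhere (a digitization fault),
  never silently merged.
- Fewer than 3 points, or an all-collinear pattern, is an error for the
  tessellation; fewer than 2 for NN/DRP.
- The NNRI degeneracy check uses a relative SD threshold (`1e-9` of the
  mean) so a floating-point-perfect lattice is still reported degenerate.
- Windows default to the tight bounding box of the points when not
  declared, with a warning, because the edge correction and the random-
  array normalization both depend on the window.
- Test problem sizes (n ≤ 3000 points, ≤ 500 calibration replicates, 10–20
  seeds per stochastic claim) keep the full suite under half a minute
  while leaving Monte-Carlo error well inside each asserted tolerance.

## Known limitations

Single-population statistics only (no cross-type DRP); rectangular
windows only for the analytic edge correction; no automatic threshold
selection; no tie handling in comparisons (forced choice); VMR/NNRI
and PF are summary statistics — two differently organized patterns can
share a value, which is why the three metrics are reported together.
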