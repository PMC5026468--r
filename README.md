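# retmosaic

Quantification of retinal mosaic phenotypes in R.

Many retinal cell types tile the retina as a *mosaic*: cell bodies of one
type keep a minimum distance from each other, and their neurites spread to
cover the field evenly (self-avoidance). Mutations in cell-adhesion genes
degrade this organization in two separable ways — cell bodies cluster, and
neurites bundle into fascicles. `retmosaic` implements the measurements a
lab uses to grade both phenotypes from microscopy exports, plus the
statistics used to compare genotypes:

- **Density recovery profile (DRP)** — the density of cells in concentric
  annuli of width Δr around each cell, averaged over cells. For a pattern
  of overall density *D*, a random arrangement is flat at *D*; a mosaic
  shows a near-origin deficit (the *exclusion zone*); clustering shows an
  excess. Profiles are normalized by *D* so the far field sits at 1. The
  deficit is summarized by the **effective radius**
  `r_eff = sqrt(V / (pi D))`, where *V* is the dead-space volume of the
  initial below-average run of bins, and by the **packing factor**
  `PF = (r_eff / r_max)^2` with `r_max = sqrt(2 / (sqrt(3) D))` the spacing
  of a triangular lattice at density *D*. PF is 1 for a perfect triangular
  array and 0 for a pattern with no exclusion zone.
- **Voronoi domain analysis** — variance-to-mean ratio (VMR) of Voronoi
  domain areas (boundary-touching domains excluded), with the
  dimensionless `CV² = var/mean²` alongside.
- **Nearest-neighbor regularity index (NNRI)** — mean NN distance / SD,
  normalized by the NNRI of random arrays of equal count in the same
  window (`nnri_ratio`), the quantity compared across genotypes.
- **Elo fasciculation score** — a zero-sum rating over blinded pairwise
  image comparisons ("which of these two images is less fasciculated?"),
  with per-retina averaging and pairwise Wilcoxon rank-sum tests under
  Benjamini–Hochberg correction.
- **Image metrics** — percent area above thresholds, two-channel overlap
  ratio (thresholded colocalization), and mean intensity along a 10 µm
  line profile.
- **Group statistics** — retinal means as the experimental unit; one-way
  ANOVA with Tukey HSD, two-way ANOVA (genotype × threshold level),
  Student's t, exact Wilcoxon, BH adjustment.

A synthetic-data module (`gen_random`, `gen_hex_lattice`, `gen_dmin`,
`gen_clustered`, `gen_comparisons`, `gen_test_image`) generates point
patterns, rater logs and images with known ground truth, so the entire
pipeline is testable without microscopy data.

## Worked example

Score a simulated mosaic (300 cells with a 40 µm exclusion zone in a
1 mm² field):

```r
library(retmosaic)
w <- c(0, 0, 1000, 1000)                       # window, um
mosaic <- gen_dmin(300, w, dmin = 40, seed = 42)

compute_drp(mosaic, bin_width = 5, max_radius = 200)
#> DRP: 40 bins of 5 um (to 200 um), 300 reference points
#>   overall density 0.0003 cells/um^2
#>   effective radius 38.9 um, packing factor 0.394

compute_domains(mosaic)
#> Voronoi domains: 236 retained, 64 boundary-excluded
#>   mean area 3457 um^2, VMR 138.5 um^2, CV^2 0.04007

nnri_ratio(mosaic, n_reps = 99, seed = 1)
#> NNRI 7.390 / random 1.859 (+/- 0.102, 99 reps) -> ratio 3.974
```

Read as: the DRP recovers the simulated exclusion zone (effective radius
38.9 µm ≈ the 40 µm dmin) and the pattern realizes ~39% of the maximal
packing at its density; domain areas are far more even than random
(CV² 0.04); and the mosaic is ~4× more regular than random arrays of the
same count (NNRI ratio 3.97, where random ≈ 1).

`run_pipeline(run_config(seed = 1))` runs the full demo — two synthetic
cohorts (exclusion-zone "wildtype" vs clustered "mutant"), per-image
metrics, retinal means, and genotype statistics — writing CSV/JSON results
and a manifest to an output directory.

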