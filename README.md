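# plumadrum

Do species that evolve more conspicuous head plumage also evolve more
elaborate acoustic displays? **plumadrum** is an R package for asking that
question the way comparative colour studies do: it quantifies head-plumage
colour patterns from transparency-masked images, and relates those colour
metrics to display traits (drum speed and length, in woodpecker-style
non-vocal drumming) across species with phylogenetic regression. It is
aimed at evolutionary biologists running family-level analyses of
correlated signal evolution, and ships synthetic-data generators so the
entire pipeline is testable without any external data.

## What it computes

**Colour quantification.** Each species image (RGBA PNG, non-plumage
masked by transparency) is downsampled to the cohort's common pixel width,
binned into a 3×3×3 sRGB histogram, and the bin centroids are
agglomeratively merged in CIE Lab space below a ΔE cutoff (default 45),
yielding a discrete colour map. From it:

- *chromatic contrast* — boundary strength over the opponent axes:
  Σ w_ij‖(a,b)_i − (a,b)_j‖ with w_ij the off-diagonal adjacency
  transition frequencies;
- *achromatic contrast* — the analogue with |ΔL| (black/white patterning);
- *scaled Simpson colour diversity* — (D − 1)/(k − 1), D = 1/Σp_i², 1 when
  all k patches are equal in area, → 0 under single-patch dominance;
- *red patch proportion* — fraction of plumage pixels with L > 55, a > 30,
  b > 5 (carotenoid-red criterion).

Pairwise image distances (exact earth-mover transport over the colour
signatures, ΔE ground cost) feed a neighbour-joining colour-similarity
tree.

**Comparative analysis.** Phylogenetic generalized least squares
y = Xβ + ε, ε ~ N(0, σ²C(λ)), with Pagel's λ estimated by maximum
likelihood on [0, 1]; all variables log10-transformed; drum speed
residualized on body mass by OLS; an open/closed habitat covariate; a
|r| ≥ 0.7 collinearity screen; and both model directions (colour → drum
and drum → colour) for robustness.

## Worked example

Segment a synthetic head image (black base, 30% carotenoid-red crown, 20%
white stripe, mild pixel noise) and compare the measured metrics with the
generator's analytic ground truth:

```r
library(plumadrum)
sp <- plumage_spec(width = 200, height = 240,
  patches = list(
    list(frac = 1,   lab = c(15, 0, 0)),    # black base
    list(frac = 0.3, lab = c(60, 65, 55)),  # carotenoid red crown
    list(frac = 0.2, lab = c(92, 0, 3))),   # white stripe
  noise_sd = 4, seed = 11)
out <- make_plumage_image(sp)
round(pattern_metrics(out$image), 4)
#>  chromatic_contrast achromatic_contrast      simpson_scaled      red_proportion
#>             41.1971             55.4698              0.8158              0.3000
round(out$metrics, 4)   # analytic ground truth from the noiseless layout
#>  chromatic_contrast achromatic_contrast      simpson_scaled      red_proportion
#>             41.5000             55.3288              0.8158              0.3000
```

The red patch reads back at exactly 0.30 of the plumage area; boundary
strengths differ from truth only through the pixel noise.

Now a full comparative run on a simulated 132-species cohort whose true
generating model has a chromatic-contrast effect of 0.1535 on
mass-corrected log drum speed with residual phylogenetic signal λ = 0.877:

```r
tree   <- simulate_tree(132, seed = 1)
traits <- simulate_traits(tree, simulation_spec(seed = 2))
report <- run_analysis(run_config(), traits = traits, tree = tree)
report$fits$drum_speed
#> PGLS fit (n = 132)
#> Lambda: 0.916, F-statistic: 5.638, 5 and 126 d.f., p-value: 0.0001003
#>                 term estimate     se       t      p
#>          (intercept)  -0.2850 0.0887 -3.2121 0.0017
#>     colour diversity   0.0101 0.0352  0.2861 0.7753
#>   chromatic contrast   0.1861 0.0402  4.6291 0.0000
#>  achromatic contrast   0.0245 0.0395  0.6194 0.5368
#>       red patch size  -0.0267 0.0394 -0.6786 0.4987
#>             habitat   -0.0383 0.0223 -1.7152 0.0888
```

The fit recovers the generating structure: λ̂ = 0.916 near the true 0.877,
a significant positive chromatic-contrast coefficient (0.186 ± 0.040)
bracketing the true 0.1535, and no spurious signal on the null predictors.
`report$reversed_fits` holds the drum-as-predictor direction and
`report$collinearity` the predictor correlation screen.

A command-line front end covers the same workflow
(`inst/cli/plumadrum`): subcommands `segment`, `metrics`, `colortree`,
`pgls`, `simulate`, `robustness`, `run`.

## Layout

- `R/colorspace.R` — sRGB↔Lab, ΔE and its chromatic/achromatic split
- `R/segmentation.R` — masked PNGs, common-width resampling, 27-bin
  histogram, Lab reclustering, colour maps
- `R/pattern-metrics.R`, `R/transport.R` — the four pattern statistics,
  exact transport image distance, NJ colour tree
- `R/phylo-gls.R` — covariance from trees, λ transform, GLS/PGLS-ML,
  mass correction, collinearity screen, log10 transforms
- `R/synthetic-data.R` — plumage images with ground truth, pure-birth
  trees, λ-BM trait tables
- `R/pipeline.R`, `R/cli.R` — orchestration, report bundle, CLI
- `vignettes/plumadrum-methods.Rmd` — model details, parameter rationale,
  generator scope, limitations
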