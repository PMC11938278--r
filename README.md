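# hydrasite

Water molecules at protein surfaces and in binding pockets are not spread
uniformly: they concentrate in *hydration sites* — localized regions of high
time-averaged water density, each characterized by an occupancy and by the
thermodynamics (ΔH, −TΔS, ΔG = ΔH − TΔS at T = 300 K) of moving one water
molecule there from bulk solvent. Knowing where these sites are and how
"happy" their waters are matters for structure-based drug design: displacing
an unfavorable (ΔG > 0) water with a ligand atom contributes favorably to
binding. The reference way to get this information — explicit-water
molecular dynamics followed by grid-based density clustering and
inhomogeneous-solvation-theory analysis — costs hours per structure.

`hydrasite` implements a one-shot alternative for R users in structural
bioinformatics and molecular modelling, plus the surrounding analysis
toolkit:

* **Location model** — candidate water nodes are seeded on every solvent
  exposed heavy atom (fractional SASA > 0.1) and refined by five
  E(3)-equivariant attention layers on a 6 Å distance-cutoff graph whose
  topology is rebuilt before each layer. Each layer moves a water node by an
  attention-weighted sum of relative-position vectors scaled by invariant
  radial messages, so predictions rotate and translate exactly with the
  input and the protein atoms never move. Raw weighted predictions
  (x_j, w_j) are condensed into sites by filtering at w_c = 0.035, Ward
  clustering at a 2 Å linkage threshold, certainty-weighted centroids, and
  a 0.1 cluster-weight gate.
* **Training loss** — both the predictions and the reference sites are read
  as isotropic Gaussian mixtures (σ = 0.5 Å; mixture weights are normalized
  certainty weights w̃_j = w_j / Σw, resp. normalized occupancies), and the
  fit term is a component-centered surrogate of the symmetrized
  Kullback–Leibler divergence, L₁ = −(Σ_j w̃_j log q(x_j) + Σ_i õ_i log p(y_i)),
  plus a concentration penalty L₂ = Σ_j w̃_j² weighted by α. All gradients
  are analytic (hand-derived reverse mode, finite-difference verified).
* **Thermodynamic model** — a protein + site graph with an 8 Å cutoff and no
  intra-protein edges, three graph-attention layers (attention coefficients
  are learned functions of the RBF-expanded edge length, plus a radial
  degree channel) and a feed-forward head predicting (ΔH, −TΔS) per site in
  kcal/mol, trained on the shared mean squared error of both terms over
  sites with occupancy ≥ 0.5.
* **Trajectory reference analysis** — 0.25 Å water density grids, greedy
  density-peak site extraction at 1 Å radius, occupancy counting,
  ΔH = ⟨E_site⟩ − E_bulk, and ΔS from discretized integration of the
  external-mode probability density of translations and rotations with the
  C° = 1 molecule / 29.9 Å³ bulk reference.
* **Evaluation** — ground-truth recovery rate (GTRR), prediction hit rate
  (PHR), first/second hydration-layer split at 3.5 Å, occupancy-binned
  tables and R²/MSE/RMSE regression metrics.
* **Desolvation scoring** — sites displaced by a ligand pose (2.4 Å
  tolerance), the desolvation free energy −Σ ΔG over displaced sites,
  slope-one calibration, and a packaged 12-ligand MUP benchmark.
* **Synthetic data** — seeded generators for toy protein-like structures,
  planted hydration sites with occupancy/thermodynamic labels, and
  pseudo-trajectories, so the entire pipeline is testable offline.

Everything is tidyverse-shaped: structures, predictions and sites are
tibbles, functions compose with the pipe, fitted models have `tidy()` /
`glance()` methods and results have `autoplot()` methods.

## Worked example

Generate toy structures with planted reference sites, train the location
model on them, and predict hydration sites:

```r
library(hydrasite)
library(dplyr)

# five training fixtures from the synthetic generator
fixtures <- lapply(1:5, function(s) {
  spec <- synthetic_spec(n_residues = 8, seed = s)
  st <- make_structure(spec) |> compute_sasa()
  list(structure = st, refs = plant_sites(st, spec))
})

model <- new_site_model(seed = 11) |>
  train_site_model(fixtures)

fx <- fixtures[[1]]
sites <- predict_sites(fx$structure, model)
refs  <- filter(fx$refs, occupancy >= 0.5)
gtrr(refs, sites, r = 1.0)
#> [1] 1
```

The first fixture has 9 qualifying reference sites; after training, every
one of them lies within 1 Å of a predicted site (pooled over all five
fixtures this run recovers 97.8%). Trajectory analysis localizes planted
sites to within a few hundredths of an Ångström:

```r
spec <- synthetic_spec(n_residues = 8, seed = 4, n_frames = 1000)
st <- make_structure(spec) |> compute_sasa()
planted <- plant_sites(st, spec)
traj <- make_trajectory(planted, spec, st)
analyze_trajectory(traj) |> head(3)
#> # A tibble: 3 × 7
#>       x     y     z occupancy    dH  mTdS    dG
#>   <dbl> <dbl> <dbl>     <dbl> <dbl> <dbl> <dbl>
#> 1  7.26  2.00 25.9      0.949 1.62   2.29  3.91
#> 2 -5.89  4.48  7.99     0.927 0.477  2.94  3.42
#> 3  5.76  4.80  4.98     0.801 1.55   2.61  4.15
```

Each row is a recovered site: occupancy is the fraction of the 1000 frames
with a water oxygen within 1 Å of the center; dH/mTdS/dG (kcal/mol) come
from the toy interaction energies and the external-mode entropy estimator.
The packaged MUP ligand benchmark reproduces the published fit quality of
displacement-based desolvation free energies against experimental binding
affinities:

```r
run_mup_benchmark()
#> # A tibble: 3 × 4
#>   method         r2    mse  rmse
#>   <chr>       <dbl>  <dbl> <dbl>
#> 1 watsite_nn  0.867   3.13  1.77
#> 2 watsite     0.318  16.1   4.01
#> 3 mm_gbsa    -0.947  45.9   6.78
```

A command-line wrapper (`inst/cli/hydrasite.R`) exposes the same pipelines
as subcommands (`predict-sites`, `profile-thermo`, `analyze-trajectory`,
`evaluate`, `desolvation`, `bench-mup`, `train-sites`, `train-thermo`,
`make-fixtures`); see `hydrasite_run()`.

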