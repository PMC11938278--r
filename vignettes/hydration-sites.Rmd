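---
title: "Hydration-site prediction and thermodynamic profiling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydration-site prediction and thermodynamic profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hydrasite)
```

This vignette is the package's own account of its science: the two learned
models, the losses, the trajectory-based reference analysis, the tunable
parameters, the synthetic study conditions, and the numerical choices that
were genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem

A hydration site (HS) is a localized region of persistently high water
density on or near a protein, summarized by a point center, an occupancy
(the fraction of simulation frames in which a water oxygen occupies the
site), and the thermodynamics of transferring one water molecule from bulk
solvent into the site: enthalpy change ΔH, entropy term −TΔS, and
ΔG = ΔH − TΔS at T = 300 K. The reference route to these quantities is
explicit-water molecular dynamics plus grid-density analysis; `hydrasite`
implements a one-shot surrogate (two small graph networks) together with
the reference analysis itself, evaluation metrics, and a
displacement-based ligand desolvation score.

## Location model

**Input representation.** A structure is a tibble of heavy atoms (hydrogens
are dropped at parse time; HETATM waters/ions excluded; highest-occupancy
altloc kept). Each node carries a 92-dimensional feature vector: a 38-slot
one-hot over a frozen vocabulary of 37 protein heavy-atom PDB names plus an
"other" slot; a 21-slot one-hot over the 20 standard residues plus "other";
a 32-center Gaussian RBF expansion of fractional SASA on [0, 1]; and a
node-type flag (0 = atom, 1 = water). Fractional SASA is computed by
Shrake–Rupley with Bondi radii, a 1.4 Å probe and a deterministic 960-point
Fibonacci sphere; the exposed fraction is relative to the atom's full
accessible-sphere area, which is why the 0.1 seeding gate is read as a
fraction (an absolute area of 0.1 Å² would seed waters on almost every
atom, an implausible reading). The sphere-point set is fixed, so SASA is
deterministic; rotating the point set together with a rigidly moved
structure reproduces the values to 1e-6.

**Seeding and refinement.** One candidate water node is placed on every
atom with SASA strictly above 0.1, at that atom's coordinate. Five
equivariant attention layers then refine the water coordinates on a 6 Å
distance-cutoff graph (strict `<`), with the topology rebuilt from the
moved waters before each layer. A layer updates water j by

  x_j ← x_j + Σ_k α_jk m_jk (x_j − x_k),

where the sum runs over all nodes within 6 Å of j, α is a softmax over j's
neighbors of logits a_c(d_jk), and m is a radial message b_c(d_jk); both a
and b are linear in a 16-center Gaussian RBF basis on [0, 6] Å with one
coefficient column per neighbor class (backbone polar N/O, sidechain polar
N/O/S, apolar, water). Because the update is a linear combination of
relative-position vectors with rotation-invariant coefficients, the whole
stack is exactly E(3)-equivariant and permutation-invariant, and protein
coordinates are never touched. The per-class radial profiles matter: with a
single shared profile the model could not distinguish backbone-carbonyl
environments from sidechain-donor environments and systematically missed
sites anchored on backbone oxygens.

**Certainty head.** After the last layer, w_j = sigmoid(c₀ + Σ_c c_c ρ_jc)
with ρ pooling the RBF expansion of distances to protein atoms within 6 Å.
The sigmoid enforces w ∈ [0, 1].

**Loss.** Predictions and reference sites are both read as isotropic
Gaussian mixtures with σ = 0.5 Å: mixture weights are the normalized
certainty weights w̃ = w / Σw and the normalized occupancies õ (references
are restricted to occupancy ≥ 0.5 before the loss). The fit term is the
component-centered symmetrized cross-likelihood surrogate of the
symmetrized Kullback–Leibler divergence,

  L₁ = −( Σ_j w̃_j log q(x_j) + Σ_i õ_i log p(y_i) ),

evaluated in log space (log-sum-exp) so that far-apart configurations keep
usable gradients — a property the closed-form L2-type divergences lack,
since their Gaussian overlap kernels vanish beyond a few σ. For reference
sites separated by more than ~2 Å (the generator guarantees this, and real
sites rarely sit closer), placing the predictions exactly on the references
with matched weights minimizes L₁ against random perturbations, which the
suite verifies over 100 draws. The concentration penalty L₂ = Σ_j w̃_j² is
minimal for uniform weights and discourages collapsing all certainty onto
one prediction; the total is L = L₁ + αL₂ with α = 0.1 by default (the
weight is exposed in the configuration).

**Weight-scale gauge.** L depends on the raw certainties only through w̃,
so the overall scale of w is a gauge freedom of the loss: training
determines the *shape* of the certainty profile but not its magnitude,
while the downstream filter w_c = 0.035 acts on raw values. After
optimization the head intercept c₀ is therefore calibrated so that the
mean total raw certainty per training structure equals the mean number of
qualifying reference sites. This gives Σ_j w_j the interpretation of an
expected water count and makes the w_c filter meaningful; it changes
nothing the loss can see.

**Optimization.** Full-batch Adam (β₁ = 0.9, β₂ = 0.999) for 2000 steps
with the learning rate decayed exponentially from 0.015 to 2% of that
value. The objective is non-convex and occasionally traps a poor
initialization, so training first runs three 200-step pilots from
different seeded initializations and continues only the best; pilot seeds
derive from the incoming parameter vector so independent training runs
explore different pilots. All gradients are hand-derived reverse mode
(there is no autodiff in this stack) and are validated against central
finite differences in the tests, both for the loss alone (rel. 1e-4) and
through the full five-layer network.

**Post-processing.** Predictions with w < 0.035 are removed; the rest are
clustered with Ward linkage (`stats::hclust(method = "ward.D2")`), undoing
every merge whose linkage distance is ≥ 2 Å (strict `<` merging,
implemented by cutting the tree at k = 1 + #{heights ≥ 2}); each cluster
becomes a site at the certainty-weighted mean of its members with weight
equal to the *sum* of member certainties (the sum, not the mean, so that
the 0.1 gate reads as aggregate evidence — a cluster of several moderately
certain predictions should pass where a single faint one should not; the
mean variant is available via `cluster_weight_mode = "mean"`). Clusters at
or below weight 0.1 are dropped. Tie-breaks are lexicographic in the
coordinates, so the pipeline is deterministic and order-independent.

## Thermodynamic model

Nodes are the protein heavy atoms plus the hydration sites (at training
time only sites with occupancy > 0.3); edges connect atom–site and
site–site pairs strictly within 8 Å — intra-protein edges are ignored, so
protein atoms communicate only through sites. Three graph-attention layers
update node features: attention coefficients are softmaxed learned
functions of the RBF-expanded edge length, aggregation is the
attention-weighted mean of neighbor features through a learned linear map,
and each layer adds a radial-degree channel — the per-node sum of RBF
expansions of its edge lengths. The degree channel exists because softmax
attention normalizes away neighbor *counts*, while burial and coordination
(how many atoms surround a site, and at what distances) carry most of the
thermodynamic signal. A two-layer feed-forward head maps each site node to
(ΔH, −TΔS) in kcal/mol; ΔG = ΔH + (−TΔS) holds exactly by construction.
The loss is the shared-mean squared error over sites with occupancy ≥ 0.5:
mean over qualifying sites of (ΔĤ − ΔH)² + (TΔŜ − TΔS)², with dS inputs
scaled by T = 300 K. Training is full-batch Adam; gradients again are
hand-derived and finite-difference checked. Internally everything is
kcal/mol; kJ/mol (× 4.184) appears only at reporting boundaries.

## Trajectory reference analysis

Water-oxygen observations are binned on a 0.25 Å grid (counts conserve
in-bounds observations exactly). Sites are extracted greedily: take the
highest-count voxel, absorb all density within 1 Å into a
density-weighted centroid, repeat; a candidate peak closer than 2 Å to an
existing site is merged into it, and sites below 10% of the frame count in
total density are dropped. Occupancy is the fraction of frames with at
least one water oxygen within 1 Å (inclusive) of the center.

ΔH is the mean per-observation interaction energy of the site's waters
minus a bulk reference energy. Interaction energies are *inputs*: in
production they come from MD post-processing; the synthetic generator
attaches self-consistent values from a toy Lennard-Jones + Coulomb
evaluator so the pipeline is exercisable end to end. ΔS is estimated by
discretized integration of the external-mode probability density of the
water's translational and rotational motions:

  ΔS = −R Σ_v p_v ln(p_v / C°) ΔV − R Σ_b f_b ln(f_b / u_b) − S_bulk,

with C° = 1 molecule / 29.9 Å³, translational bins of 0.25 Å, and
orientations histogrammed in 30° z-y-z Euler bins against the uniform
SO(3) measure u_b (so uniform orientations contribute zero). Two
refinements control the discretization bias, both validated on the
analytic uniform-ball case (S_trans = R ln(V·C°) for volume V):

* **Support clipping.** Site observations are by construction confined to
  the 1 Å site sphere, so boundary voxels are mostly empty volume; using
  the full voxel volume dilutes the density and biases |S| low by ~10% at
  0.25 Å bins. Clipping each voxel's volume to the sphere (deterministic
  8³ subgrid) removes this bias.
* **Miller–Madow correction.** The plug-in histogram entropy is biased by
  sparsely occupied bins; adding R(K−1)/(2N) (K occupied bins, N
  observations) compensates. This matters most for the rotational
  histogram, whose 864 bins are undersampled at realistic per-site counts.

With both, the default-bin estimate lands within ~0.1% of the analytic
uniform-ball value and halving the bin width moves it by well under 2%.
Orientation quaternions are the internal representation; the z-y-z Euler
binning uses the exact per-bin uniform measure (cos θ differences), not
equal angular volumes. The bulk reference entropy and energy are
configuration inputs (they depend on the water model used upstream) and
default to 0 and −9.5 kcal/mol respectively.

## Evaluation metrics and desolvation

GTRR is the fraction of reference sites with at least one prediction
within r; PHR the fraction of predictions within r of at least one
reference. Matching is any-within-r (many-to-one allowed) — the natural
reading of set-recovery rates; a greedy one-to-one variant is available
behind `matching = "one_to_one"` for sensitivity checks and can only be
lower. Both rates are monotone in r, bounded in [0, 1] and rigid-motion
invariant. A site is first-layer if its distance to the nearest protein
heavy atom is ≤ 3.5 Å (inclusive boundary, per the standard "no further
than" convention); occupancy-stratified GTRR uses bins [0.5, 0.6) …
[0.9, 1.0], reporting empty bins as NA rather than zero.

For ligand scoring, a site is displaced when its center lies within the
2.4 Å tolerance (inclusive) of any ligand heavy atom, and the desolvation
free energy is −Σ ΔG over displaced sites: displacing water that is
unfavorable in the site (ΔG > 0 for bulk→site transfer) releases it to
bulk and contributes favorably (negatively). Slope-one calibration shifts
predictions by mean(experimental) − mean(predicted) — the intercept of a
fixed-slope regression — leaving residuals that sum to zero, and R² is
computed as 1 − SSres/SStot on the calibrated values (squared Pearson
correlation would not reproduce the packaged benchmark's published fit).

## Synthetic study conditions

The generator builds coarse-grained helical structures (rise 3 Å, 100° per
residue, four backbone pseudo-atoms plus a sidechain dummy and a polar or
apolar tip atom per residue, ≥ 2 Å between any two heavy atoms — the
structures are geometric, not physically folded, because every contract
under test is geometric or statistical). Sites are planted 2.8–3.0 Å from
exposed polar sidechain or backbone oxygens/nitrogens in the least crowded
direction, pairwise > 2 Å apart; occupancies are uniform on [0.35, 0.95]
(straddling both the 0.3 node gate and the 0.5 loss gate); the positional
spread σ is a deterministic function of burial (0.1–0.35 Å, more exposed →
more mobile), and the thermodynamic labels follow smooth deterministic
rules of the 7 Å environment — ΔH decreases with polar and heavy-atom
coordination, and −TΔS = 1.8 − 4σ so that more mobile sites get strictly
higher entropy. The 7 Å radius was chosen because neighbor counts at
tighter radii are nearly constant across planted sites on these toy
structures, which would leave the labels without learnable variance.
Trajectories emit, per frame and site, a water with probability equal to
the occupancy at a Gaussian displacement of the site's σ, with uniform (or
optionally concentrated) orientation quaternions and toy interaction
energies. All randomness flows through one seeded generator; fixture runs
are bit-reproducible.

What passing tests on these fixtures does and does not show: the suite
pins down the exact geometric and statistical contracts (equivariance,
filtering and clustering thresholds, loss minima and gradients, density
conservation, estimator convergence, recovery of planted structure). It
does not demonstrate accuracy on real proteins — toy structures have no
rotamers, no condensed packing, no second-shell water networks, and their
label rules are far smoother than real solvation thermodynamics. The
corpus-scale accuracy of the approach is outside what can be established
at this scale; the package's claims on real data are limited to the
packaged 12-ligand desolvation benchmark, which is exactly recomputable.

## Problem sizes and defaults

The suite and the acceptance script run at deliberately small, fixed
problem sizes chosen as the package's own desk-scale study conditions:
8-residue structures (≈ 48 heavy atoms, 8–12 planted sites), five
training fixtures for the location model with three seeded training runs,
ten labelled fixtures (7 train / 3 held out) for the thermodynamic model,
1000-frame trajectories, and 20 000 observations for the uniform-ball
entropy oracle. Key defaults: SASA gate 0.1, cutoffs 6 Å / 8 Å, σ = 0.5 Å,
α = 0.1, w_c = 0.035, Ward threshold 2 Å, cluster-weight gate 0.1,
occupancy gates 0.3 / 0.5, layer boundary 3.5 Å, displacement tolerance
2.4 Å, T = 300 K, grid 0.25 Å, site radius 1 Å.

## Known limitations

* The certainty-weight scale is fixed by the expected-count gauge
  calibration, not learned; other calibrations (e.g. matching a quantile)
  are equally consistent with the loss.
* The location model's radial-profile parameterization is deliberately
  compact (so its reverse-mode gradients stay tractable by hand); it
  under-resolves sites in strongly anisotropic environments, visible as a
  GTRR at 0.5 Å well below the GTRR at 1 Å on the fixtures.
* `site_entropy()` requires ≥ 50 observations and degrades for sites with
  very low occupancy; the rotational term assumes the orientation
  histogram's bins are meaningfully populated.
* The toy energy evaluator exists only to make fixtures self-consistent;
  its absolute energies are not physical.
* Training is full-batch and CPU-bound; the intended scale is tens of
  structures, not thousands.
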