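---
title: "Deconvoluting spatial transcriptomics spots with spotdeconv: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvoluting spatial transcriptomics spots with spotdeconv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotdeconv)
```

## The problem and the model

A spot in spot-based spatial transcriptomics captures transcripts from a
handful of cells, so the observed count vector is (approximately) a sum of
single-cell count vectors with unknown type composition. `spotdeconv` treats
composition estimation as supervised regression onto the probability
simplex: because sums of annotated single cells with *chosen* composition
can be simulated in any quantity from an scRNA-seq reference, a flexible
regressor can be trained on simulated mixtures and applied to real spots.
The estimator never needs a curated marker panel; it learns whatever
transcriptome-wide features separate the types in the reference.

The pipeline has four stages — simulate, train, deconvolute, regularize —
each exposed as ordinary functions so any stage can be run, inspected or
replaced on its own.

## Simulating mixtures with known composition

`split_cells()` partitions reference cells into train/test subsets,
stratified so every type appears in both; mixtures for training and for
evaluation are built from disjoint cells, so held-out evaluation cannot leak
cell-level information.

`sample_proportions()` draws target compositions in three strata: pure
one-hot profiles (default 10%) covering the simplex vertices, sparse
profiles (default 30%) in which a uniformly chosen non-empty strict subset
of types is zeroed before a Dirichlet draw on the survivors (faces), and
full Dirichlet(α = 1) draws (interior). Real tissue spots are often
dominated by one or two types; without the pure and sparse strata a
Dirichlet-only sampler almost never shows the network extreme compositions,
and predictions near the simplex boundary calibrate poorly.

`synthesize_mixtures()` converts a proportion row into integer cell counts
by largest-remainder rounding (ties broken by lexicographic type order, so
realized compositions are deterministic), samples cells uniformly *with
replacement* within type, and sums raw counts. Replacement sampling lets a
small reference support arbitrarily many profiles at the cost of correlated
profiles; this is stated here because it bounds how much new information
extra simulated profiles can add. The stored targets are the *realized*
(post-rounding) fractions, which differ from the requested ones by less
than `1/n_cells` per type. The default of 50 cells per mixture matches the
cell content of typical multi-cellular capture spots.

## Normalization

The paper trail for this class of method leaves the transformation
unstated, so the package fixes a simple scheme and applies it *identically*
to simulated mixtures and real spots — the property that actually matters
is that training and inference distributions match. Each profile is scaled
to 10,000 counts (all-zero profiles stay zero) and `log1p`-transformed;
the gene space is the lexicographically sorted intersection of reference
and ST genes, with optional low-count and low-prevalence filters and an
optional regex exclusion (e.g. `^mt-`) that is off by default since no
mitochondrial-filter convention is universal. Scaling is idempotent on the
pre-log scale, and genes missing at prediction time are zero-filled with a
warning below 90% overlap (error at zero overlap).

## The network and its training

The regressor is a fully connected network: default two hidden layers of
200 ReLU units with inverted dropout 0.25 and a softmax head, so outputs
are non-negative and sum to one *by construction* for any input, including
all-zero profiles. The default loss is the Kullback–Leibler divergence of
the predicted from the true composition (mean-squared and mean-absolute
error are available); KL treats the target as a distribution, which is what
a composition is. Optimization is mini-batch Adam (learning rate 1e-3,
batch 64, up to 60 epochs) with a 10% validation slice carved from the
training profiles for early stopping (patience 10, best weights restored).

Two training details deserve explanation:

* **Decoupled weight decay (default `weight_decay = 2`, i.e. a per-step
  shrink of `learning_rate * weight_decay = 0.002`).** In a dense network,
  first-layer weights on genes that carry no composition signal receive
  essentially zero loss gradient, so without decay they retain their random
  initialization forever and training can additionally park spurious
  directions there. Predictions are barely affected — those directions are
  near-orthogonal to the data manifold — but input *gradients* are polluted,
  and gradient-based interpretation then ranks uninformative genes among
  the top. Decay removes exactly the weights the loss does not defend. In
  our synthetic benchmarks it slightly *improves* held-out accuracy while
  making attributions concentrate on the planted markers.
* **Determinism.** Weight initialization, shuffling, dropout and data
  simulation all draw from R's RNG, and the linear algebra is ordinary
  single-threaded BLAS, so a fixed seed reproduces training bit-for-bit.
  There is no nondeterministic backend to switch off.

A non-finite training loss aborts with a hint to check the input scale
(unnormalized counts are the usual culprit) or lower the learning rate.

`evaluate_deconv()` scores a held-out mixture set per cell type — Pearson
correlation (PCC), Lin's concordance correlation (CCC), RMSE across
profiles — plus the mean per-profile Jensen–Shannon divergence. CCC is the
most informative single number here: unlike PCC it penalizes slope and
location departures from the identity, so a model that is correlated but
systematically over- or under-calls a type scores visibly worse.

## Deconvolution and spatial regularization

`deconvolute()` predicts every spot's composition from its measured
(*intrinsic*) profile. When `spatial = TRUE` it also builds each spot's
*extrinsic* profile — the summed raw counts of its k nearest neighbours by
Euclidean distance, the spot itself excluded — and predicts its composition
with the *same* model (not by averaging neighbours' intrinsic predictions:
the extrinsic profile is a bona fide simulated sample, so it goes through
the network like any other). The final estimate blends the two:

* dissimilarity `d_i = 1 − cosine(intrinsic_i, extrinsic_i)` on normalized
  profiles (Pearson similarity available), min-max rescaled to [0, 1]
  across spots;
* blend weight `λ_i = λ_max (1 − d_i)`, default `λ_max = 0.5`;
* `regularized_i = (1 − λ_i) intrinsic_i + λ_i extrinsic_i`.

The blend is convex, so the result is automatically on the simplex;
`λ_max = 0` is a bit-exact identity. Two limits anchor intuition: in a
perfectly homogeneous region every `d_i` ties, min-max maps them all to 0
and smoothing is maximal, while the spot most unlike its surroundings gets
`λ = 0` and keeps its own prediction. Regularization assumes
transcriptional continuity between neighbouring spots; it is **off by
default** because tissues with fine interdigitated structure violate the
assumption, and the per-spot `d_i` map
(`intrinsic_extrinsic_distance_map()`) should be inspected first — region
boundaries light up as high-distance bands. Default `k = 6` matches
hexagonal lattices; use 4 on square grids. Neighbours are summed
unweighted; distance weighting was considered and rejected for the default
because platform coordinate units vary and the blend already adapts to
profile similarity.

## Gradient-based interpretation

`gene_scores()` attributes a type's predicted proportion to input genes:
either gradient × input (default), the mean over profiles of
`(∂ output_t / ∂ x_g) · x_g`, or integrated gradients from the all-zero
baseline (trapezoidal rule, default 50 steps). Integrated gradients are
included because they satisfy a checkable axiom — attributions sum to
`output(x) − output(0)`, with error vanishing as steps grow — which the
test suite verifies against an analytic single-layer model. By default
scores are averaged over simulated pure profiles of the target type, so the
ranking answers "which genes drive this type's detection"; any profile
matrix (e.g. real spots) can be supplied instead. The zero baseline is
natural here because a zero count vector is a genuine "no signal" input
that the softmax head maps to a proper (uninformative) composition.

## Metrics and clustering conventions

* CCC uses population (1/n) moments: `ccc(x, x)` is exactly 1, and two
  equal constant vectors return 1 by convention (unequal constants return
  the formula's 0). `|CCC| ≤ |PCC|` always.
* JSD uses base-2 logarithms so its range is [0, 1]; `0·log 0 = 0`; inputs
  are renormalized. Reported JSD is the mean over spots/profiles (per-spot
  averaging, not pooled).
* Agreement summaries are computed per cell type (across profiles) by
  default — the convention used when comparing deconvolution methods — with
  a per-profile reducer available.
* `cluster_spots()` is k-means on proportion rows, 10 restarts keeping the
  lowest inertia, deterministic given the seed.

## The synthetic-data generator

`simulate_reference()` draws a negative-binomial marker-block reference:
gene baseline rates are Gamma-distributed (mean `base_expression = 2`),
each of the `n_types = 5` types owns a disjoint block of
`marker_genes_per_type = 25` genes whose rate is multiplied by
`marker_fold_change = 8` in that type, cells carry log-normal library
factors (CV 0.2), and counts are NB with size `dispersion = 2` — strongly
overdispersed, as real UMI data per cell type is. Every type's marker block
shares one baseline-rate template, so expected per-cell totals are equal
across types; after depth normalization the marker blocks are then the
*only* composition signal, which is what makes the generator's ground truth
(markers, compositions) exact for attribution and recovery testing. With
`marker_fold_change = 1` the generator degenerates to a null dataset with
no separability.

`simulate_spatial()` places spots on a lattice, assigns regions (default: a
two-region left/right split with mirrored archetype compositions), draws
per-spot compositions from a Dirichlet concentrated on the region archetype
(concentration 30), and synthesizes spot counts exactly as training
mixtures are synthesized. `simulate_single_cell_st()` +
`bin_single_cell_st()` emulate the standard quantitative evaluation for
imaging-based platforms: single cells with coordinates and labels are
aggregated into square bins whose true composition is the member-type
frequency; counts are conserved exactly and bin centres become spot
coordinates.

What the generator does **not** emulate: batch effects between reference
and ST, platform-specific capture efficiency and lateral transcript
diffusion, spot-size variability, cell types absent from the reference, and
continuous cell states. Passing tests on these fixtures therefore
demonstrate the machinery is correct and the estimator recovers
composition when the reference faithfully describes the tissue — not that
any real reference does.

## Problem sizes, tolerances, degenerate inputs

The test suite trains on a 3-type, 150-gene reference with 1500 mixtures
for fast unit checks and on the default 5-type, 500-gene, 1000-cell
reference with 2000 training / 500 test mixtures for the end-to-end
benchmark; the binned-recovery check uses 2000 cells binned into ~196
spots. These sizes were chosen as the smallest at which the statistical
claims are stable across seeds. Simplex sums are checked to 1e-6;
closed-form metric oracles to 1e-12; normalization idempotence to 1e-9.
Degenerate cases are defined, not rejected: all-zero profiles stay zero
through normalization and still yield simplex outputs; duplicate gene
symbols are summed on input (conservative for counts); duplicate
coordinates are valid and tie-break by spot index; constant vectors give a
warning and `NA` for PCC but a documented convention for CCC.

## Known limitations

* Proportions are per spot; the package does not estimate absolute cell
  numbers or per-cell assignments.
* A cell type missing from the reference is silently redistributed over
  the types the model knows — inspect the intrinsic–extrinsic distance map
  and evaluation report rather than trusting predictions blindly.
* Spatial regularization is single-round and linear by design; it will not
  recover structure finer than the k-neighbourhood scale, and should stay
  off when neighbouring spots are not expected to resemble each other.
* The HDF5 reader is eager; very large matrices should be subset or
  converted upstream.
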