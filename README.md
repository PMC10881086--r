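# spotdeconv

Cell-type deconvolution of spatial transcriptomics (ST) spots with a neural
network trained on simulated mixtures of single cells.

Spot-based ST platforms (Visium and kin) capture transcripts from several
cells per spot, so each measured profile is a mixture over cell types.
`spotdeconv` estimates, for every spot, the proportion vector
`p = (p_1, ..., p_K)` on the simplex (`p_k >= 0`, `sum p_k = 1`) of the `K`
cell types in an annotated scRNA-seq reference. It is aimed at analysts who
have a labelled reference from the same tissue context and want per-spot
composition estimates plus diagnostics, without hand-curating marker panels.

## Method

1. **Mixture simulation.** Reference cells are split into disjoint train/test
   subsets (stratified by type). Proportion vectors are drawn to cover the
   simplex — a Dirichlet(α) interior stratum, a sparse stratum with random
   type subsets zeroed, and pure one-hot profiles — and each mixed profile is
   the sum of raw counts of `n` cells (default 50) sampled with replacement
   according to the largest-remainder rounding of its proportion vector. The
   realized composition is the regression target.
2. **Network training.** Profiles are depth-normalized (counts-per-10k,
   `log1p`) on a harmonized reference/ST gene space and fed to a fully
   connected network (default 200-200 hidden units, ReLU, dropout 0.25,
   softmax head) trained with Kullback–Leibler divergence loss, Adam with
   decoupled weight decay, and validation-based early stopping. The softmax
   head guarantees simplex outputs. Held-out test mixtures give a per-type
   report: Pearson correlation (PCC), Lin's concordance correlation (CCC),
   RMSE, and per-profile Jensen–Shannon divergence (JSD).
3. **Deconvolution and spatial regularization.** The model predicts each
   spot's *intrinsic* profile composition. Optionally, an *extrinsic* profile
   per spot — the summed counts of its k nearest neighbours (default k = 6) —
   is deconvoluted by the same model, and the two predictions are blended:
   `regularized_i = (1 - λ_i) intrinsic_i + λ_i extrinsic_i` with
   `λ_i = λ_max (1 - d_i)`, where `d_i` is the (min-max scaled) cosine
   dissimilarity between the spot's normalized intrinsic and extrinsic
   profiles. Spots that resemble their surroundings are smoothed most;
   transcriptionally isolated spots are left untouched.
4. **Interpretation and downstream.** Gradient × input and integrated
   gradients attribute each type's predicted proportion to genes;
   k-means clusters spots on predicted proportions.

Synthetic data with known ground truth (negative-binomial references with
disjoint marker blocks, spot lattices with regional compositions, and
single-cell-resolution datasets for bin-and-recover evaluation) is built in,
so the whole pipeline is testable offline.

## Worked example

```r
library(spotdeconv)

ref <- simulate_reference(n_genes = 300, n_types = 4, n_cells_per_type = 100, seed = 11)
fix <- simulate_spatial(ref, grid = c(10, 10), seed = 12)    # two-region lattice

split <- split_cells(ref, test_frac = 0.2, seed = 13)
types <- sort(unique(ref$cell_types))
p_tr <- sample_proportions(1000, 4, seed = 14); colnames(p_tr) <- types
p_te <- sample_proportions(250, 4, seed = 15); colnames(p_te) <- types
train <- synthesize_mixtures(ref, split$train, p_tr, seed = 16)
test  <- synthesize_mixtures(ref, split$test,  p_te, seed = 17, partition = "test")

spec  <- harmonize_gene_space(ref, fix$spatial, min_counts = 1)
model <- train_deconv(train, spec, config = deconv_config(seed = 18))
evaluate_deconv(model, test)
#> deconv_eval on 250 held-out profiles
#>   cell_type   pcc   ccc   rmse
#> 1     type1 0.989 0.984 0.0494
#> 2     type2 0.989 0.987 0.0437
#> 3     type3 0.990 0.984 0.0509
#> 4     type4 0.989 0.986 0.0432
#> overall: mean PCC 0.989, mean CCC 0.985, mean RMSE 0.0468, mean JSD 0.0221

res <- deconvolute(model, fix$spatial, spatial = TRUE)
head(as.data.frame(res)[, 1:5], 3)
#>           spot_id     type1     type2      type3      type4
#> spot0001 spot0001 0.3577723 0.4923482 0.08620698 0.06367253
#> spot0002 spot0002 0.4388298 0.3927089 0.11524974 0.05321160
#> spot0003 spot0003 0.3305530 0.5226132 0.09308034 0.05375345
```

The evaluation table says the model recovers each type's proportion across
held-out mixtures almost perfectly (PCC/CCC near 1, RMSE below 0.05); the
result rows are per-spot compositions after spatial regularization. Against
the lattice's known ground truth this run scores mean PCC 0.980 / mean CCC
0.971 across types. Attribution recovers the planted markers: the top genes
for `type2` (`G0050 G0041 G0027 G0028 G0030`) sit in that type's marker
block `G0026–G0050`:

```r
tab <- gene_score_table(model, ref = ref, seed = 19)
top_genes(tab, "type2", n = 5)
```

A command-line wrapper over the same functions lives in
`inst/scripts/spotdeconv-cli.R` (subcommands `fixture`, `deconvolute`,
`interpret`, `metrics`, `cluster`).

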