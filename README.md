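# hamgcn

Physics-informed graph neural classification of single cells from paired
RNA + ATAC (multiome) profiles, for computational biologists who want deep
graph models that neither over-smooth nor fall apart under noisy inputs.

## The idea

A graph convolutional network (GCN) layer propagates cell features over a
cell–cell k-NN graph:

    H^(l+1) = sigma( D^{-1/2} (A + I) D^{-1/2} H^(l) W^(l) )

Stacking such layers homogenizes embeddings (over-smoothing) and amplifies
corruption. `hamgcn` instead encodes each cell once, splits the embedding
into position and momentum coordinates `(q, p)`, and evolves the pair with
symplectic Euler steps of a learnable scalar energy `H_theta(q, p)`:

    p' = p - dt * dH/dq(q, p)
    q' = q + dt * dH/dp(q, p')        (dt = 0.2 over [0, 1], 5 steps)

The energy network is `Linear(2H -> 4H) -> ReLU -> Linear(4H -> 1)` per
node with an l2 aggregation over nodes. Symplectic integration keeps the
learned energy approximately conserved and phase-space volume preserved, so
embeddings retain discriminative structure at depths (or integration
horizons) where a plain GCN collapses toward the random baseline. A linear
head on `(q || p)` classifies cells; the composite task predicts cell type
and disease state jointly (16 classes for 8 types x 2 states), either with
one 16-way head or a two-head loss `0.7 * L_type + 0.3 * L_state`.

Around the model the package provides the full pipeline: RNA
log-normalization (scale factor 10,000), highly variable gene selection,
TF-IDF + LSI for ATAC peaks, ATAC QC filtering, weighted-nearest-neighbor
modality fusion into a consensus k = 15 cell graph, training-set-only
Wilcoxon differential feature selection (leakage-free by construction),
donor-grouped or cell-level stratified splits, over-smoothing diagnostics
(pairwise cosine similarity, Dirichlet energy, intra/inter class
similarity), per-epoch energy-trace monitoring, perturbation-robustness
sweeps, and seeded synthetic multiome generators so everything is testable
offline. All gradients — including backpropagation through the integrator
via analytic Hessian-vector products — are hand-derived and
finite-difference-verified.

## Worked example

```r
library(hamgcn)

data <- make_multiome(synthetic_spec(seed = 1))   # 2,000 cells, 16 classes
cfg  <- model_config(hidden_dim = 16, epochs = 100, seed = 1)
out  <- run_pipeline(data, cfg, mode = "hgcn")

out$metrics$summary
#> # A tibble: 1 x 4
#>   accuracy f1_macro f1_weighted     n
#>      <dbl>    <dbl>       <dbl> <int>
#> 1    0.948    0.947       0.947   400

energy_drift(out$fit$energy_traces)
#> # A tibble: 1 x 3
#>   mean_drift_percent sd_drift_percent n_epochs
#>                <dbl>            <dbl>    <int>
#> 1          0.0000388        0.0000928      100
```

94.8% of held-out cells get the correct joint cell-type + disease-state
label (random guessing: 6.25%), and the learned energy drifts by a few
hundred-thousandths of a percent across the five integrator steps — the
dynamics are effectively conservative. Compare the baseline by rerunning with
`mode = "gcn_baseline"`, inspect over-smoothing with `depth_sweep()` /
`plot_depth_sweep()`, and stress-test with `robustness_sweep()` /
`plot_robustness()`. Fitted models have `tidy()`, `glance()`, `predict()`
and `autoplot()` methods.

A command-line interface wraps the same functions
(`inst/cli/hamgcn.R`): `simulate`, `preprocess`, `build-graph`, `train`,
`evaluate`, `diagnose`, `perturb-sweep`, `depth-sweep`, each writing a
manifest with config, seed and input hashes.

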