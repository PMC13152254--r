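---
title: "Hamiltonian graph convolutional networks for single-cell multiomes: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hamiltonian graph convolutional networks for single-cell multiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Graph convolutional networks (GCNs) classify cells by propagating feature
information over a cell–cell similarity graph. They work well shallow, but
repeated neighborhood averaging makes node embeddings converge toward each
other as depth grows (*over-smoothing*), and small corruptions of features
or edges propagate without any damping. `hamgcn` implements a
physics-informed alternative: each cell's embedding is split into a
position `q` and a momentum `p`, and the pair is evolved by a fixed number
of symplectic Euler steps of a *learnable* scalar energy function
`H(q, p)`. The classifier then reads the evolved phase state. Because the
dynamics approximately conserve the learned energy and exactly preserve
phase-space volume for separable energies, embeddings cannot collapse onto
each other the way iterated averaging forces them to.

## Model

**Encoder.** One graph convolution
`Z = relu(D^{-1/2}(A + I)D^{-1/2} X W)` followed by dropout and a linear
map to `2H` dimensions; the first `H` columns are `q0`, the rest `p0`.

**Learnable energy.** The default (`mlp`) variant applies
`Linear(2H -> 4H) -> ReLU -> Linear(4H -> 1)` to each node's `(q_i || p_i)`
and aggregates the per-node scalars with an l2 norm over nodes, so the
energy is a single non-negative number whose value scales as `sqrt(N)`
under node duplication. A second (`gcn`) variant,
`||g1(tanh(g2(q || p)))||^2` with `g1`, `g2` graph convolutions, is
implemented for completeness and diagnostics; the `tanh` makes it
bounded-input-bounded-output by construction. Two fixed variants —
the separable quadratic `H = (||q||^2 + ||p||^2)/2` and a constructive
kinetic + `||sin q||^2` example with multiple energy wells — serve as
integrator-validation surfaces only.

**Integrator.** The staggered explicit update

```
p' = p - dt * dH/dq(q, p)
q' = q + dt * dH/dp(q, p')
```

with `dt = 0.2` over the horizon `[0, 1]`, i.e. five steps. For separable
energies this map is exactly symplectic (we test that the one-step Jacobian
determinant is 1 to 1e-9 and that energy stays within 1% over 10,000 steps
on the harmonic oscillator). For the learned, non-separable energy it is an
explicit approximation of semi-implicit symplectic Euler; which gradient
point the `q`-update should use is not determined by the architecture, and
we document our staggered choice rather than assert it as canonical.

**Readout and loss.** A linear head on `(q || p)` (a `q`-only head is kept
for ablation). The composite 16-class task (8 cell types x 2 disease
states) is trained with a single 16-way cross-entropy head by default; a
two-head variant with weighted loss `0.7 * L_type + 0.3 * L_state` is
available (`task = "multi"`).

**Gradients.** R has no automatic differentiation, so every derivative is
hand-derived: the energy gradients for all four variants, the
Hessian-vector products of the mlp energy that backpropagation through the
integrator requires (the ReLU second derivative vanishes almost everywhere,
which collapses the Hessian to an analytically cheap rank-structured form),
and the parameter-side vector-Jacobian products. All of them are verified
against central finite differences in the test suite, including the full
model loss through all five integrator steps. Training supports the `mlp`
energy; the `gcn` energy is available for evaluation and gradient
diagnostics but not as a trainable energy; the mlp network is the default
and the one used in every learned forward pass.

One numerical subtlety: the energy network is initialized with small
positive biases (0.01 and 0.1). Zero biases would place every node whose
encoder output is zero *exactly* on the ReLU kink and the l2 norm exactly
at its non-smooth point, where the almost-everywhere gradient and the
finite-difference quotient legitimately disagree.

**Baseline.** The comparison model is a stack of the same graph
convolutions (width, dropout, optimizer, and head all identical) of
configurable depth; depth 2 — the standard GCN — is the default comparator,
and the over-smoothing analyses sweep depth explicitly (1 through 8).

## Preprocessing and graph construction

RNA counts are log-normalized with a scale factor of 10,000, restricted to
the top 2,000 highly variable genes (variance-stabilizing ranking: a
quadratic log-variance vs log-mean trend, standardized residual variance
clipped at `sqrt(N)`; when the feature means barely vary, the quadratic is
ill-conditioned and the trend falls back to a constant), scaled to zero
mean and unit variance, and reduced by PCA. ATAC peak counts pass a QC
filter (cells with nucleosome signal > 2 or TSS enrichment < 2 are
removed; boundary values kept), then TF-IDF with `TF = count / cell total`,
`IDF = log(1 + N/df)` and the `log(1 + TF * IDF)` dialect that maps
structural zeros to exact zeros, then truncated-SVD LSI (50 components at
full scale). Per-modality k-NN graphs (k = 20) feed a simplified
weighted-nearest-neighbor scheme: each modality is scored per cell by how
much better its own neighbors predict the cell's profile than the other
modality's neighbors do, and the softmax of the two affinities gives
per-cell weights. The consensus graph (k = 15) is built on the weighted
fusion of per-cell z-scaled modality distances. All neighbor selection
breaks distance ties by lower node id, so graphs are bit-reproducible.

We deliberately do not reproduce the full Seurat-v4 WNN algorithm (SNN
scores, per-cell kernel bandwidths): typical workflows use WNN as a black
box, and the package needs a self-contained, testable analogue. No SNN
graph is computed, since nothing downstream would consume it.

Classifier features are either the concatenated standardized PCA + LSI
embeddings (default; compact and fast) or Wilcoxon-selected genes plus
peaks (`features = "de"`). Differential selection runs *only* on training
cells (Benjamini–Hochberg, adjusted p < 0.05 by default, exposed in
configuration); tests assert exact invariance of the selection to
arbitrary corruption of non-training cells. Whether ATAC enters the
classifier as selected peaks or as LSI components is a genuinely open
wiring question, so both are supported through configuration.

## Synthetic data: what it emulates and what it does not

`make_multiome()` draws 2,000 cells in 16 balanced composite classes
(8 types x 2 states) with 8 donors nested in disease state. RNA counts are
negative binomial (dispersion 0.3, base log-mean `log 3`) with cell-type
markers (|log-FC| 2.5 on 30% of genes), disease effects (|log-FC| 1.2 on a
disjoint 10%), additive donor shifts (s.d. 0.15), library-size variation,
and 20% multiplicative dropout. ATAC counts are zero-inflated Poisson
(sparsity 0.5) with the same planted structure over 400 peaks. QC metrics
are sampled so roughly 5% of cells fail the standard thresholds.

Effect sizes were fixed during fixture design by checking modality-level
separability (nearest-neighbor and linear-discriminant probes) against the
regime the emulated datasets exhibit — nearly saturating cell-type
distinctiveness, moderately hard disease states — and then frozen. At desk
scale (hundreds of features rather than tens of thousands) per-feature
effects must be stronger than real marker effects for the total information
content to be comparable; that is a deliberate compression, not a claim
about real effect sizes. The generator does not emulate batch effects
beyond donor shifts, peak-count heteroscedasticity, doublets, or ambient
contamination, so passing tests say nothing about robustness to those.
`make_sbm_graph()` provides the over-smoothing testbed: a stochastic block
model with Gaussian class features. The depth-contrast fixture uses
n = 200, 4 blocks, `p_in = 0.2`, `p_out = 0.05`: enough between-block
mixing that deep averaging actually homogenizes classes. (With
near-disconnected blocks, e.g. `p_out = 0.01`, depth-8 averaging stays
within blocks and nothing collapses — a useful negative control, not a
test of over-smoothing.)

## Problem sizes and budgets

Desk-scale analyses use hidden width 16 (full-scale default 256), 100–150
epochs with patience 50, the 2,000-cell fixture, and 5 seeds for every
stochastic contrast. These sizes were chosen so the whole validation suite
runs on a single CPU in minutes while keeping every qualitative contrast
(over-smoothing collapse, robustness ordering, recovery rates) stable
across seeds. The robustness sweep perturbs features (Gaussian shift of
one per-feature s.d. on a fraction of nodes) and edges (removal plus
injection of the same fraction) simultaneously, trains both models on the
corrupted data, and compares test accuracy; intensity 0 rows reproduce the
clean run exactly.

## Numerical choices and degenerate inputs

- Zero-total cells stay as zero rows (with a warning); dropping cells is
  an explicit QC decision, never silent.
- Constant features scale to zero, not NaN; zero vectors have cosine
  similarity 0 by convention.
- Dirichlet energy is the plain unnormalized edge sum, since only relative
  trends across depth are interpreted.
- O(N^2) pair metrics subsample at most 100,000 seeded pairs.
- PCA/LSI/SVD signs are fixed by the largest-|loading|-positive
  convention, so all embeddings are bit-deterministic.
- A single global seed fans out to fixed per-stage streams
  (`derive_seed`), so any stage rerun in isolation sees the stream it saw
  inside the full pipeline.
- Early stopping restores the best-validation-loss parameters; a
  non-finite training loss aborts with a diagnostic rather than continuing.

## Known limitations

- Exact symplecticity holds for separable energies; for the learned
  non-separable energy the integrator is the stated explicit
  approximation, and only boundedness of the recorded energies is claimed.
- The simplified WNN is a functional analogue, not a reimplementation of
  Seurat's; its weights agree qualitatively (informative modality up-
  weighted) but are not numerically comparable to Seurat outputs.
- Training the `gcn` energy variant would require tanh second-derivative
  terms in the integrator backward pass and is not implemented.
- Dense distance matrices cap practical graph construction at a few tens
  of thousands of cells; approximate-NN indices are out of scope.
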