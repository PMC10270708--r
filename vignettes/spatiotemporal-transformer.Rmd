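---
title: "Spatiotemporal transformer representations of dynamic functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal transformer representations of dynamic functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stfc)
```

## The model

`stfc` learns a contextual representation of multivariate BOLD-like time
series together with their dynamic functional connectivity (dFC). The input
to the model is a batch of windowed segments: each entry pairs a
`T_tau x N` slice of the node time series with the `N x N` Pearson
correlation network computed from exactly that slice. Nodes may be the voxels
of one region (with one model per region, combined by majority voting) or
whole-brain ROIs (one model).

One **spatiotemporal (ST) block** consists of a spatial transformer followed
by a temporal transformer:

1. **Positional embedding.** Per node and time step we concatenate the raw
   signal value, a sinusoidal encoding of the *absolute* time index
   (`sin/cos(t / 10000^(2k/N_f))`), and the node's connectomic neighborhood
   (its row of the window's adjacency matrix). A 1x1 convolution maps this to
   `N_f` channels and a depthwise 1-D convolution along time (kernel 3, zero
   padding) refines it, giving the embedded tensor
   `X~` of shape `N_b x T_tau x N x N_f`.
2. **Spatial graph attention.** Per time step, every node attends over all
   nodes: per head `Q = X~ W_Q`, `K = X~ W_K`, `V = X~ W_V`
   (each `W` is `N_f x d_head`, `d_head = N_f / heads`), weights
   `softmax(QK'/sqrt(d_head))`, heads concatenated and merged by a linear
   map, then a three-layer position-wise feed-forward network (ReLU after
   layers 1 and 2) with one residual connection from `X~`:
   `U_S = X~ + FFN(Attn(X~))`.
3. **Chebyshev graph convolution.** In parallel,
   `U_G = ReLU(sum_{k<K} T_k(L~) X~ Theta_k)` applied independently at each
   time step, where `L~` is the scaled normalized Laplacian of the window's
   network (edge weights `|r|` with unit self-loops) and `T_k` the Chebyshev
   recurrence.
4. **Gate fusion.** `alpha = sigmoid(linear(U_S + U_G))` elementwise, and
   `Y_S = alpha * U_S + (1 - alpha) * U_G`, so the fused features always lie
   between the two branches.
5. **Temporal transformer.** The residual `X_T = X~ + Y_S` is concatenated
   with the sinusoidal time encoding, mapped back to `N_f` by a 1x1
   convolution, and every node independently runs bidirectional attention
   over the window's time steps (no causal mask), followed by the shared
   three-layer feed-forward and a residual from the embedding output. The
   value handed to the next block is `Y_T + X_T`.

The final block feeds a prediction head of two 1x1 convolution layers with a
ReLU in between, producing an `N x T_tau` score matrix per class for every
entry; entry logits are the mean over nodes and time, and a softmax yields
class probabilities. Training minimizes entry-level cross-entropy with Adam.

## Design choices where the architecture was genuinely open

Several wiring details are not pinned down by the block diagram conventions
this architecture follows; the package fixes them as follows and exposes the
ones worth varying:

* **Residual source for the temporal block.** The temporal residual
  `X_T = X_S + Y_S` needs `X_S` and `Y_S` to share the feature dimension, so
  `X_S` is taken to be the *embedded* spatial input `X~` (the raw window has
  a single channel and cannot be added to an `N_f`-channel tensor).
* **Attention temperature.** `sqrt(d_head)` by default (standard scaled
  dot-product); `attention_scale = "d"` divides by `d_head` instead for
  fidelity experiments.
* **Head merge.** Concatenation followed by a learned `N_f x N_f` map.
* **Graph for the GCN.** Absolute Pearson weights with unit self-loops; a
  signed normalized Laplacian is not well defined. `lambda_max` is estimated
  with 20 power-iteration steps (deterministic uniform start) with fallback
  2.0; `K` defaults to 3 and is configurable.
* **Positional fusion.** Signal, temporal and connectomic encodings are
  concatenated before the 1x1 convolution. The depthwise convolution runs
  along time only, per node and channel, and its center tap is initialized
  near 1 so the embedding starts close to a pass-through.
* **Entry to subject.** The `N x T_tau` score matrix becomes one label by
  mean pooling; a subject's score is the mean class-1 probability of its
  windows; region-wise models combine by majority vote with ties broken by
  the mean region score against 0.5.
* **Scheduling.** The learning rate is multiplied by `lr_decay` (default
  0.5) whenever validation loss fails to improve for `lr_patience` epochs,
  and training early-stops after `2 * lr_patience` stagnant epochs — a guard
  that bounds runtime without changing the optimum.
* **Final classifier layer** starts at zero so the initial prediction is
  uniform and the first-epoch loss sits at `ln 2` on balanced data.

Windows advance with stride `T_tau - T_phi`: the "overlap" is read as the
number of time points shared by consecutive windows. The trailing remainder
shorter than a window is dropped. Splits are *subject-level* and
class-stratified (train takes `floor(0.7 n)` per class, validation
`floor(0.15 n)`, test the rest), so overlapping windows of one subject can
never straddle folds — a leakage guard that the null-cohort test exercises.
Zero-variance window columns get correlation 0 with a warning rather than an
error, so degenerate synthetic inputs do not abort training.

## Differentiation

No automatic-differentiation framework is available to R here, and the
training loop is central to the method, so the package carries a small
reverse-mode tape (`R/autodiff.R`) over dense arrays with compiled batched
matrix-multiply kernels (`src/ops.cpp`). Every layer is written once against
the tape and shared by training, inference and the exported array-level
functions. Gradients are verified end to end against central finite
differences (relative L2 error below 1e-4 on a one-block model; the observed
agreement is ~1e-10, i.e. machine precision for h = 1e-5). The backward
sweep releases each node's activation as soon as it is consumed, which keeps
peak memory near the size of a single forward pass.

## The synthetic cohort generator

The two-class generator is the package's stand-in for resting-state BOLD
data; cohorts with known ground truth are what make the end-to-end claims
testable. Each node follows

```
x_i(t) = phi x_i(t-1) + beta_c f(t) 1[i in planted, t in window] + eps_i(t)
```

with a shared latent AR(1) factor `f`, class-specific loading `beta_c` on a
planted subnetwork, Gaussian innovations, and z-scored columns. This yields
realistic temporal autocorrelation (`phi` defaults to 0.4, in the range of
parcellated BOLD lag-1 autocorrelations at typical repetition times) and a
controllable between-class difference that lives purely in the *dynamic
connectivity*, which is the structure the model is built to detect. An
optional `coupling_window` confines the coupling to part of the series so the
temporal attention branch has localized signal to find.

What it does **not** emulate: hemodynamic convolution, scanner drift and
motion/physiological confounds, spatial autocorrelation between neighboring
nodes, site effects, or the heavy-tailed marginals of real fMRI. Passing
tests therefore demonstrate that the machinery is correct and can recover
planted dynamic-connectivity structure — not that it attains any particular
accuracy on real cohorts.

## Study conditions used by the shipped experiments

The recovery and ablation experiments (test suite and
`scripts/acceptance.R`) use a cohort of 40 + 40 subjects, 20 nodes with a
6-node planted subnetwork coupled at 0.8 versus 0.0, 200 time points,
windows of 25 with overlap 5, and batches of 50 — nine windows per subject,
720 entries. The model for these experiments uses one ST block, 2 heads,
`N_f = 8`, `K = 3`, learning rate 2e-3, and at most 6 epochs: the planted
effect is strong, and this configuration reaches subject-level test AUC at
or near 1.0 while keeping a full training run under a minute on one CPU.
The architecture defaults (`model_config()`: 3 blocks, `N_f = 64`, learning
rate 1e-4) mirror the reference setup for real-data-scale work. The
null-cohort check uses 60 + 60 subjects with identical coupling in both
classes, where the larger test fold stabilizes the Mann-Whitney AUC
estimate around chance.

```{r, eval = FALSE}
spec <- cohort_spec(n_per_class = 40, n_nodes = 20, series_length = 200,
                    planted_nodes = 0:5, coupling_by_class = c(0.8, 0),
                    seed = 11)
cohort <- generate_cohort(spec)
config <- model_config(n_blocks = 1, n_heads = 2, n_features = 8,
                       cheb_order = 3, window_length = 25, window_overlap = 5,
                       learning_rate = 2e-3, max_epochs = 6, seed = 1)
fit <- fit_st_model(cohort$records, config)
fit$test_auc_subject
```

## Interpretation tools

`extract_attention()` re-runs a trained model and returns per-head maps
(`N x N` per time step for the spatial scope, `T_tau x T_tau` per node for
the temporal scope); `average_attention()` averages the rows of chosen query
nodes over heads, windows and subjects, optionally keeping only the top half
of the averaged scores; `attention_received()` reports the mean column mass
per node — on the planted cohorts, planted nodes receive visibly more
spatial attention in the coupled class. Map pairs are compared with
`mpe_similarity(a, b) = 100 * mean(|a-b| / (|a| + 1e-8))`; the denominator
uses the first (reference) map, so the measure is intentionally ordered and
non-symmetric, and maps from different window lengths are rejected rather
than compared cell-wise. `window_sweep()` re-segments the same cohort for
every valid (window, overlap) pair — overlap must be smaller than the
window — and reports mean test AUC over seeded trials, so data volume varies
with the window settings exactly as it would in practice.

`delong_test()` implements the fast structural-components estimate of the
covariance of two paired AUCs with midrank ties; it is cross-checked in the
test suite against both a model-exchange permutation oracle and the
independent implementation in pROC.

## Known limitations

* Training cost grows linearly in entries and quadratically in `N_f`; the
  pure-R tape is efficient enough for method development and synthetic
  studies, not for voxel-level cohorts of hundreds of subjects.
* Entry-level cross-entropy treats windows of one subject as independent
  samples; subject aggregation happens only at prediction time.
* The Chebyshev filter uses `|r|` edge weights, discarding the sign of
  anticorrelations (the attention branch can still use signed structure
  through the connectomic encoding).
* `lambda_max` from 20 power-iteration steps is an estimate; for the small
  dense graphs used here it is accurate to float precision, but pathological
  spectra would silently fall back to 2.0.
* Reproducibility is bitwise for a fixed seed on a single thread; BLAS
  threading may reorder floating-point reductions on some platforms.
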