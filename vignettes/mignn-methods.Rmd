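---
title: "Multiple-instance temporal graph networks for severity regression: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple-instance temporal graph networks: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mignn)
```

## The problem

Clinical severity of depression is scored on continuous self-report scales
(BDI, 0–63; PHQ-8, 0–24) at the *subject* level, while the observable
evidence — facial expression, prosody, word choice — unfolds *utterance by
utterance* over a long interview.  Two temporal signatures matter and pull
in different directions: severity is a **chronic, persistent state** (a
slowly drifting baseline across the whole session), yet it also surfaces as
**sparse, intermittent symptomatic events** that are far apart in time and
connected by content rather than adjacency.  A purely sequential encoder
captures the first; a dense attention model captures the second but
scrambles chronology.  `mignn` implements a pipeline built around both.

## Model

A session is a bag of `n` utterances with pre-extracted feature matrices
per modality (audio, visual, text; any subset, any dimensions — the
conventional extractor widths are 100/2048/768).

1. **Context encoding.**  Each modality is encoded by its own
   single-layer bidirectional GRU with `H` hidden units per direction
   (default 200); forward and backward outputs are concatenated
   channel-wise, so every row sees the whole sequence.  The per-modality
   contexts are concatenated in the fixed (A, V, T) order and linearly
   projected to the node dimension `d_node` (default 160).  The projection
   reconciles the concatenated width (1200 at the defaults) with the node
   width; it can be disabled (`project = FALSE`) when the two agree.
2. **Temporal graph.**  Nodes are utterances.  Two directed relations are
   built inside a window of `Nw` utterances total (`Nw/2` per side,
   default `Nw = 20`): *FFC* edges carry information forward in time (past
   source to later destination) and *BFC* edges carry it backward.  Each
   node also has a SELF loop, treated as its own singleton relation.
   Sliding a centred window along the sequence with step 1 produces
   exactly one graph per session, so no node duplication is needed.  Edge
   weights are initialised by a bilinear attention score
   `s_ij = c_i' W_r c_j` soft-maxed per (destination, relation); a
   singleton group therefore gets weight exactly 1, which makes the SELF
   weight a constant.
3. **Relational graph convolution.**  Per relation, neighbourhood messages
   are averaged with the softmax weights divided by the neighbourhood size
   and mapped by a relation-specific matrix, plus a self term:
   `h_i = act( sum_r sum_j (a_ij/|N_i^r|) W_r c_j + W_0 c_i )`.  The
   division by `|N_i^r|` on top of the softmax is deliberate (it is how
   the update is specified); `rgcn_degree_norm = FALSE` switches to
   softmax-only normalisation.
4. **Multi-head graph attention.**  `K` heads (default 4) re-score the
   same neighbourhoods from the convolved features with
   `e_ij = a' LeakyReLU(W [h_i , h_j])`, soft-maxed per (destination,
   relation, head), aggregate with the new weights (shared `W` per head
   across relations — the relation distinction is already encoded by the
   previous layer) and concatenate head outputs to width `K * d_head`
   (default 4 × 40 = 160).
5. **Multiple-instance head.**  Each utterance is scored linearly from the
   concatenation of its contextual embedding and its graph-updated
   feature; the subject score is the *exact arithmetic mean* of the
   utterance scores.  No learned pooling: the bag mean is part of the
   contract and tested at 1e-12.
6. **Loss.**  Training minimises `1 − CCC` over the subject scores of a
   batch, where the concordance correlation coefficient is computed with
   population (1/N) moments:
   `CCC = 2 cov(f,y) / (var f + var y + (mean f − mean y)^2)`.
   CCC is undefined for a single pair, so the batch (default 50 sessions)
   is the loss unit.  An MSE option exists (`loss = "mse"`).

## Gradients without a framework

No automatic-differentiation framework is used: every backward pass is
derived by hand and implemented exactly — backpropagation-through-time for
the bidirectional GRUs (batched over sessions, one recurrent matrix
multiply per time step), softmax-group backward for both weight layers,
the bilinear edge-score backward, the attention backward, and the CCC
gradient in closed form.  The test-suite validates the complete chain
against central finite differences at 1e-4 (it agrees to ~1e-10) and each
graph operator against brute-force dense adjacency oracles at 1e-5.
Because the SELF weight is the constant 1 (singleton softmax), no gradient
flows through it; gradients reach `W_r` through the FFC/BFC softmax only.

## Optimisation and reproducibility

The optimiser is Adam (learning rate 1e-4, weight decay 1e-8 added to the
gradient as classic L2, 500 epochs, batch size 50 by default).  The batch
unit is the session; variable lengths are handled by block-diagonal batch
graphs and per-session offsets, never by padding.  All randomness —
initialisation (Glorot-uniform dense maps, orthogonal recurrent matrices,
zero biases) and per-epoch batch order — derives from `config$seed`, so a
seed fixes the loss trajectory bit-for-bit on one platform.  Model
selection keeps the epoch with the best development-set CCC; training
aborts with a diagnostic naming epoch and batch if the loss turns
non-finite.

## Ablation variants

`variant` selects: `no_mil` (each session collapsed to one mean-pooled
instance before encoding — the minimal intervention isolating the
multiple-instance contribution), `no_gnn` (head on the context matrix
alone), `gcn_only` (skip the attention stage), `no_bfc` (drop the
backward relation and its weights), and `mha_fusion` (replace the graph
stage with dense per-session multi-head self-attention, the standard
attention-fusion baseline).  Parameter counts shrink strictly in the order
full > gcn_only > no_gnn and full > no_bfc, which the tests assert.
`mignn_sweep()` runs the window grid (0–40) and head grid (3–6) with
shared seeds and emits a CSV.

## The synthetic cohort generator

Real interview corpora with clinical labels are access-restricted, so the
package ships a generator that emulates their *structure* and plants a
recoverable severity signal with exactly the two temporal shapes the model
targets:

* severity `y ~ Uniform(0, y_max)` per subject;
* a latent state following an AR(1) (persistence 0.8, innovation s.d.
  0.15) drifting toward a severity-proportional mean (`trend_strength`
  at maximal severity) — the chronic trend;
* Bernoulli burst onsets with probability `0.05 + 0.30 · y/y_max` per
  utterance, each burst adding a fixed offset (2.0) for 1–3 consecutive
  utterances — the intermittent events;
* per modality, features are the latent state times a fixed unit
  direction scaled by that modality's signal strength, plus isotropic
  Gaussian noise (s.d. 0.6).  Signal strengths default to text 1.0 >
  audio 0.7 > visual 0.25, reproducing the usual informativeness ordering
  of the three modalities.

The unit directions are population parameters: they are seeded by the
feature dimension alone so that independently-seeded train/dev/test
cohorts share one feature subspace, as corpora drawn from one population
would.  Presets name the study conditions: `strong` (trend 2.0, noise
0.25 — signal recovery), `null` (all signal strengths zero — negative
control), `burst` (trend 0.4, slope 0.5 — severity carried mainly by
sparse events).

`oracle_score()` inverts the generator in closed form: a precision-
weighted combination of the AR(1)-innovation estimate of the trend level
and the binomial estimate of the burst onset rate, clipped to the scale
range.  It consumes the latent states directly, so its cohort CCC is a
ceiling that a model trained on the noisy features should not exceed
(asserted with a +0.05 margin).

What the generator does *not* emulate: realistic marginal distributions of
extractor features, cross-modal redundancy beyond a shared scalar latent,
label noise, or inter-rater variability.  Passing the recovery tests
therefore demonstrates that the implementation can learn the temporal
structures it was built for — not that it attains any particular accuracy
on real corpora.

## Problem sizes and numerical choices

Experiments in the tests and the acceptance script use the desk-scale
configuration (`desk_config()`: hidden size 8, node dimension 16, RGCN
width 16, 4 heads of width 4, learning rate 0.01) with feature dimensions
20/32/24, cohorts of 200 train / 50 dev subjects for signal recovery and
120/40 for the ablation comparison, and 10–30 training epochs.  These
sizes were chosen so the whole pipeline trains in minutes on one CPU
while leaving the architecture untouched; the full-scale defaults remain
on `mignn_config()`.  Other numerical choices: softmax computations are
max-shifted; ties in the attention logits resolve by the softmax itself
(no explicit tie-break is needed); `Nw = 0` degenerates to self-loop-only
graphs and is fully supported; odd windows are rejected rather than
rounded, since the window is defined as `Nw/2` per side.

## Known limitations

* One RGCN layer and one GAT layer, as specified; no stacking option.
* The CCC loss needs at least two sessions per batch; a trailing
  singleton batch is merged into its predecessor.
* `sigmoid_scaled` head activation is available but the identity default
  is used everywhere: the CCC loss is scale-aware, so constraining the
  output range buys little and slows early training.
* Determinism is per-platform (it depends on the BLAS); across platforms
  trajectories may differ in the last bits.
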