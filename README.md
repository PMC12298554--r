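# mignn

Multiple-instance temporal graph networks for continuous severity
regression from utterance-level multimodal features.

## What problem this solves, and for whom

Automatic depression-severity estimation scores a whole interview session
on a clinical scale (BDI 0–63 or PHQ-8 0–24) from pre-extracted
utterance-level features of up to three modalities — audio, visual and
text.  The label lives at the subject level; the evidence lives at the
utterance level and has two temporal shapes at once: a chronic, slowly
drifting baseline and sparse intermittent symptomatic events far apart in
time.  `mignn` is for researchers in computational psychiatry and
affective computing who want a tested, fully inspectable reference
implementation of a graph-based multiple-instance pipeline for this
setting — with no deep-learning framework dependency (all forward passes
and exact analytic gradients are implemented in R and validated against
finite differences and dense oracles).

## The model

For a session of `n` utterances with per-modality feature matrices
`X^m ∈ R^{n×d_m}`:

1. **Context encoding** — per-modality bidirectional GRU (unshared
   weights, `H = 200` per direction by default), channel-wise
   concatenation of directions, fixed-order (A, V, T) fusion and linear
   projection to node features `c_i ∈ R^{d_node}` (default 160).
2. **Dual-relation temporal graph** — inside a window of `Nw = 20`
   utterances (`Nw/2` per side), forward-full-connection (FFC) edges
   carry past → future messages and backward-full-connection (BFC) edges
   future → past; each node keeps a SELF loop.  Initial edge weights are
   `α_ij = softmax_j( c_i^T W_r c_j )`, normalised per (destination,
   relation).
3. **RGCN** — `h_i^{(1)} = σ( Σ_r Σ_{j∈N_i^r} (α_ij/|N_i^r|) W_r c_j +
   W_0 c_i )`.
4. **Multi-head GAT** — `K = 4` heads re-weight the same neighbourhoods
   with `α'_ij = softmax_j( a^T LeakyReLU( W [h_i ⊕ h_j] ) )`, aggregate
   and concatenate to `h_i^{(2)} ∈ R^{K·d_head}`.
5. **MIL head** — `ŷ_i = W_c [c_i ⊕ h_i^{(2)}] + b_c`; the subject score
   is exactly `mean(ŷ_i)`.
6. **Loss** — `1 − CCC` over a batch's subject scores, with
   `CCC = 2·cov(f,y) / (σ_f² + σ_y² + (μ_f − μ_y)²)` (population
   moments).

Ablation variants (`no_mil`, `no_gnn`, `gcn_only`, `no_bfc`,
`mha_fusion`), a window/heads sweep harness, a seeded synthetic-cohort
generator with a planted chronic-trend + burst severity signal, and
cohort readers/writers (JSON manifest + headerless CSV matrices) are
included.  See the vignette `vignettes/mignn-methods.Rmd` for the full
model account and design rationale.

## Worked example

```r
library(mignn)

## 1. simulate a cohort with a planted severity signal
cfg_tr <- synthetic_config(n_subjects = 60, preset = "strong", seed = 1)
cfg_dv <- synthetic_config(n_subjects = 20, preset = "strong", seed = 2)
train <- generate_cohort(cfg_tr)$cohort
dev   <- generate_cohort(cfg_dv)$cohort
train
#> <mignn_cohort> 60 sessions (PHQ8), 20-59 utterances, modalities A+V+T

## 2. train the full model at desk scale
config <- desk_config(epochs = 15L, batch_size = 20L, seed = 1L)
fit <- mignn_train(train, dev, config)
tail(fit$log, 3)
#>    epoch train_loss   dev_ccc dev_rmse  dev_mae
#> 13    13 0.02030948 0.9718794 1.677736 1.331113
#> 14    14 0.01943024 0.9753641 1.584527 1.283081
#> 15    15 0.01788930 0.9686656 1.753500 1.389825

## 3. evaluate subject-level predictions
pred <- mignn_predict(fit$params, dev, config)
head(pred, 3)
#>   session_id    y_true    y_pred
#> 1    syn0001  4.437174  4.439685
#> 2    syn0002  1.859275  4.136158
#> 3    syn0003 16.716454 14.611051
unlist(evaluate(pred$y_pred, pred$y_true))
#>        mae       rmse        ccc n_subjects
#>  1.3040681  1.5677686  0.9764888 20.0000000
```

The PHQ-8-style severities planted by the generator (uniform on 0–24) are
recovered on held-out subjects with CCC 0.98 and a mean absolute error of
1.3 scale points after 15 epochs: the bag-mean scores track both the
chronic trend and the burst rate the generator encodes.

A command-line interface wraps the same functions:

```sh
mignn simulate --n_subjects 60 --preset strong --seed 1 --out cohort/
mignn validate-cohort cohort/manifest.json
mignn train --train cohort/ --dev cohort_dev/ --desk --epochs 15 --out run/
mignn ablate --variant no_bfc --train cohort/ --dev cohort_dev/ --out run_nobfc/ --desk
mignn sweep --train cohort/ --dev cohort_dev/ --nw 0,10,20 --heads 3,4 --out sweep.csv --desk
mignn dump-graph --n 12 --nw 4 --out edges.tsv
```

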