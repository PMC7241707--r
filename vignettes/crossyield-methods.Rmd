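---
title: "Methods: collaborative filtering for cross-yield prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collaborative filtering for cross-yield prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The prediction problem

A hybrid breeding program records the yield of crosses between inbred lines
and tester lines, planted in replicate across many locations. Only a few
percent of the inbred × tester factorial is ever planted; the task is to
rank the unplanted combinations. `crossyield` treats this as explicit-
feedback collaborative filtering: inbreds play the role of "users", testers
of "items", and the normalized plot yield is the response. Two auxiliary
categorical inputs — planting location and a genetic-group label shared by
related parents — absorb environmental and population structure so the
parent embeddings can concentrate on combining ability.

# Model

Each of the four IDs is one-hot encoded and mapped to a dense vector by an
embedding matrix; inbreds and testers get *separate* embeddings for the two
branches so neither branch constrains the other's representation:

* `W1b` (n_b × k1), `W1t` (n_t × k1): GMF parent embeddings;
* `W2b` (n_b × k2), `W2t` (n_t × k2): NN parent embeddings;
* `Wg` (n_g × kg), `Wl` (n_l × kl): group and location embeddings.

**GMF branch.** `q_GMF = (d1b ⊙ d1t) · h`. The element-wise product models
multiplicative (bilinear) combining ability; the learned output weights `h`
let latent dimensions carry different importance. With `h` fixed at ones
this is exactly classical matrix factorization, an identity kept as a unit
test. Location and group do **not** enter this branch.

**NN branch.** The concatenation `[d2b d2t dg dl]` feeds a tower network
(widths 64/32/16 by default) with rectifier activations. Inverted dropout
(keep probability 0.7) follows each hidden activation during training only,
so evaluation needs no rescaling. A linear head reduces the last hidden
layer to the scalar `q_NN`. The branch sees group and location, so it
carries the additive environmental structure as well as any high-order
parent interaction.

**Fusion.** `ŷ = fusion_W · [q_GMF, q_NN] + fusion_b`. The branch scalars
are each well-defined on their own, which is what makes the single-branch
models (`branch = "gmf_only"` / `"nn_only"`) and the pre-training protocol
possible. The output head of the NN branch is a model parameter in every
mode; the fusion layer is always the 2-weight map above. We chose this
layout because a 2-vector fusion and a branch-internal scalar head together
satisfy both selector identities (`fusion_W = [1,0]` returns exactly
`q_GMF`, `[0,1]` exactly `q_NN`) that we use as correctness oracles.

**Coarse model.** Setting `use_parent_ids = FALSE` (only with
`branch = "nn_only"`) removes the parent embeddings entirely: prediction
from `[dg dl]` alone. This is the "no fine details" experiment: how much of
the yield variance is explained by group and environment without knowing
which parents were crossed.

# Training

* **Loss.** Huber with threshold `delta = 0.1` on the normalized yield
  scale: quadratic within ±0.1 (about one standard deviation of typical
  normalized yields), linear beyond, hence robust to plot-level outliers.
  The minibatch objective is the mean elementwise loss.
* **Optimizer.** Adam (0.9 / 0.999 / 1e-8) with learning rate 3e-4 and
  minibatches of 16 by default, up to 70,000 gradient steps; one iteration
  is one minibatch update, the epoch-end remainder is used as a short
  batch, and data are reshuffled every epoch. There is no early stopping.
* **Initialization.** Xavier-uniform everywhere (variance
  `2 / (fan_in + fan_out)`; an `n × k` embedding uses fan-in `n`, fan-out
  `k`), biases zero.
* **Pre-training.** `pretrain_then_train()` trains a GMF-only model, an
  NN-only model, then a fused model initialized from their embedding and
  tower parameters with a fresh Xavier fusion layer. Phase seeds are
  `seed`, `seed+1`, `seed+2` so each phase is independently reproducible.
* **Optional standardization.** Yields arrive pre-normalized (population
  mean ≈ 1), so the default trains on them as given; `standardize = TRUE`
  centers/scales the response during training and maps predictions back,
  which speeds convergence when the response scale is far from the
  Xavier-initialized output scale. Correlation metrics are unaffected.
* **Determinism.** The trainer is single-threaded C++ (RcppArmadillo); all
  shuffling and dropout randomness comes from one generator seeded by
  `config$seed`, so training histories and parameters are bit-reproducible.
  A pure-R forward pass (`gmf_forward()`, `nn_forward()`,
  `fused_forward()`) mirrors the compiled code and the test suite asserts
  the two agree, keeping the fast path honest.

Dropout is applied only inside the NN tower, never to the GMF branch or the
output layers: the GMF branch has no hidden layer for it to act on, and
dropping the two fusion inputs would randomly silence a whole branch.

# Evaluation protocols

* **k-fold cross validation** (`run_cv()`): folds partition *observations*
  (plain random, near-equal sizes), each fold predicted by a model trained
  on the rest with full (b, t, g, l) inputs. Test metrics are pooled over
  all out-of-fold predictions; per-fold values are retained. A fold with a
  single observation (leave-one-out) reports `NA` fold correlation. Note
  that a per-fold-constant predictor is *not* constant in the pooled
  vector, so its pooled correlation can deviate slightly from zero even
  though each fold's correlation is 0 by the zero-variance convention.
* **Hold-out by combination** (`run_holdout()`): whole (inbred, tester)
  pairs are withheld; the model trains on all remaining observations,
  predicts each held pair at every location, and the location-averaged
  prediction is scored against the pair's mean observed yield. Because
  averaging removes plot noise and location variance, hold-out metrics are
  systematically better than CV metrics on the same data — an expected
  artifact of the response definition, not of the model.
* **Group resolution.** An unplanted pair has no recorded group, so
  prediction uses the modal observed group of the inbred, falling back to
  the global modal group (with a message) for inbreds never seen in
  training. The same map is stored in every fitted model, and
  `predict_full_matrix()` and the hold-out harness share one prediction
  code path, so the decision-support matrix and the evaluation numbers
  agree bit-for-bit.
* **Metrics.** RMSE and Pearson correlation × 100; a zero-variance input
  (e.g. a constant predictor) reports correlation 0 by convention, which is
  also why a constant baseline scores RMSE equal to the population standard
  deviation of its targets and correlation 0.

# Baselines

`constant_mean` (training mean), `lasso_linear` (L1-penalized least squares
on the concatenated one-hot blocks, delegated to glmnet; `l1_coef` is
glmnet's `lambda` in the objective `(1/2N)·RSS + lambda·|beta|_1`, default
0.8 — at typical normalized-yield scales such a penalty drives every
coefficient to zero, leaving the intercept, which is informative as a
floor), and `fm` (second-order factorization machines over the same one-hot
features: global bias + linear weights + factorized pairwise interactions,
trained with the same Adam/Huber loop as the main model so losses are
comparable). FM with its interaction factors zeroed reduces exactly to its
linear part, a nested-model identity kept as a test.

# The simulator

`generate_crosses()` draws, from one seed: i.i.d. normal latent factors
`U` (n_b × k_true), `V` (n_t × k_true) with scale `sigma_latent`; additive
location and group effects with scales `sigma_loc`, `sigma_grp`; a uniform
group label per *inbred* (so any unplanted pair still has a well-defined
group); `n_combos` distinct pairs uniformly without replacement;
`max(1, Poisson(mean_obs_per_combo))` plantings per pair at uniform
locations; and per-plot yield

```
y = mu + loc_l + grp_g(b) + U_b·V_t + gamma_nonlinear · tanh(U_b·V_t)² + noise.
```

The `tanh²` term is our choice of a smooth, bounded high-order interaction
that a bilinear model cannot represent, giving the NN branch something real
to learn; nothing is claimed about the functional form of real
genotype-by-genotype epistasis. The defaults emulate the published shape of
a large commercial testcross program: 593 × 496 parents, 10,919 observed
pairs (3.71% of 294,128), ~18.3 plantings per pair over 280 locations, 14
groups, yield mean 1.002 and standard deviation ≈ 0.105. The variance split
behind that total (`sigma_loc = 0.06`, `sigma_grp = 0.04`,
`sigma_latent = 0.16` with `k_true = 4`, `sigma_noise = 0.055`,
`gamma_nonlinear = 0.04`) is our own calibration to those two printed
moments only; the real data's covariance structure (year effects,
location × genotype interaction, unbalanced replication) is *not* emulated,
so passing benchmarks demonstrates correct mechanics and learnability of
this structure, not field performance.

`true_pair_mean()` returns the noise-free location-averaged expectation of
a pair — the oracle against which recovery benchmarks score.

# Benchmark problem sizes and choices

The test suite and `scripts/acceptance.R` run three study designs, sized so
the whole suite completes in minutes on one CPU while keeping each effect
measurable:

* **Memorization**: 4 observations, 4 pairs, `k1 = k2 = 4`, 5,000
  iterations; the fused model must drive training RMSE below 0.01 (pure
  capacity check).
* **Bilinear recovery**: 100 × 80 parents, 2,000 pairs, ~8 plantings each,
  `sigma_noise = 0.02`, no additive or nonlinear signal. A GMF-only model
  (`k1 = 8`, batch 64, learning rate 3e-3, standardized response, 20,000
  iterations) must reach hold-out pair correlation ≥ 90% — below the
  noise ceiling `sqrt(s² / (s² + sigma_noise²/m))` implied by the
  generator, with `s = sqrt(k_true)·sigma_latent²`. The larger batch and
  learning rate than the field defaults compensate for the much smaller
  problem; the iteration budget is the only constrained quantity.
* **Ensemble ordering**: 60 × 40 parents, 900 pairs, with bilinear
  (`sigma_latent = 0.35`), additive (`sigma_loc = sigma_grp = 0.05`) and
  nonlinear (`gamma_nonlinear = 0.5`) signal. Over 5 replicate seeds the
  fused model's median hold-out correlation must be at least each single
  branch's, and pre-training must not worsen the fused median RMSE by more
  than 0.01 (the tolerance is one tenth of the response spread). Medians,
  not per-seed comparisons: at this scale single seeds are noisy and an
  occasional branch win is expected.

# Known limitations

* The hold-out response uses *observed* pair means, so combinations are
  only ever scored where at least one planting exists; truly unobserved
  pairs are ranked (`predict_full_matrix()`) but not scored.
* Fold assignment is plain random; stratification by year or location is
  not implemented (year is carried through I/O but unused by the model).
* The simulator emits no year effects and assumes group membership is a
  property of the inbred; if groups in real data belong to pairs or vary
  over time, the group-resolution rule is an approximation.
* `pheatmap` renders the heatmap export; at very large sub-matrices the
  labeled CSV is the intended interface and the image is illustrative.
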