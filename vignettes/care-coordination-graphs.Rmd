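---
title: "Modelling care coordination with heterogeneous graphs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling care coordination with heterogeneous graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(medhgps)
```

This vignette documents the model, the synthetic data-generating process,
the numerical choices and the known limitations of `medhgps`. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The model

An inpatient surgical cohort is represented as a heterogeneous graph with an
encounter type `ENC`, five featureless provider subgroups and three
featureless care-unit levels. All edges are undirected and run between
encounters and the other types: an encounter–provider edge per assignment
(weight 1) and an encounter–unit edge weighted by the number of stays of
that encounter in that unit level. Provider–provider association is *not* an
explicit edge; it arises through shared encounters, which is exactly the
two-hop meta-path `Provider–Encounter–Provider`.

Each of three stacked convolution layers computes, for every target type
$\Omega$, a self projection $Z_\Omega = H^{l-1}_\Omega W_{\Omega\Omega}$ and
per-relation neighbour messages $Z_\Gamma = \hat A_{\Omega\Gamma}
H^{l-1}_\Gamma W_{\Gamma\Omega}$, where $\hat A$ is the row-normalized
adjacency (zero rows stay zero, so isolated nodes receive a zero message and
the forward pass is total). The candidate messages are mixed per node by
type-level attention: the logit of relation $r$ at node $v$ is
$\mathrm{ELU}([Z_r(v) W_k^r \,\|\, Z_\Omega(v) W_q]\cdot w_a)$ and the
coefficients are a softmax over the node's relation set — the only reading
under which the convex combination in the layer update is well defined and
coefficients sum to one per node. The layer output is
$\mathrm{ELU}(a_\Omega \odot Z_\Omega + \sum_\Gamma a_\Gamma \odot
Z_\Gamma)$; the ELU is applied at every layer, including the last, whose
2-column encounter output feeds a row-wise softmax. Training minimizes
binary cross-entropy with probabilities clamped at $10^{-7}$.

**Featureless types.** Providers and care units carry no input covariates.
They are given trainable per-node embedding vectors (width `embed_dim`), the
standard heterogeneous-GNN convention that avoids $|V|$-wide one-hot inputs;
an identity one-hot option (`featureless_init = "onehot"`) exists for
exactness tests. In the no-encounter-feature ablation the encounter type is
treated the same way.

**Optimization.** Adam on mini-batches of at most 512 labeled training
encounters. Message passing is always full-graph (the graph is transductive
and of desk scale); the batch only selects which labeled rows contribute to
the loss of a step. Early stopping monitors validation AUROC with patience
10 (default) and restores the best epoch's parameters. All gradients are
reverse-mode and hand-derived for this fixed architecture; the test suite
checks them against central finite differences on a 5-encounter fixture,
with and without batch normalization.

**Regularization.** Dropout acts on layer inputs; batch normalization (no
learnable affine) acts on the encounter pre-activation of hidden layers —
featureless single-node types are exempt, since normalizing a one-row batch
would zero it out. Weight decay applies to layer weights but *not* to the
per-node embeddings: the embeddings are the only place where
provider-specific information can live, and decaying them erases exactly the
signal the model is supposed to find (we observed this directly: with
embeddings penalized, planted provider effects become unlearnable while
planted unit effects survive, because the three unit embeddings are shared
by thousands of encounters).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `hidden_dim` | 32 | width of the two hidden layers (search grid 32–256) |
| `attn_dim` | 16 | attention key/query width (grid 8–128) |
| `embed_dim` | `hidden_dim` | embedding width of featureless types |
| `lr` | 1e-2 | Adam learning rate (search range 1e-7–1e-1, log scale) |
| `l2` | 1e-5 | weight decay on layer weights, per step |
| `dropout` | 0 | input dropout rate (range 0–0.8) |
| `batch_norm` | FALSE | batch-norm on hidden encounter pre-activations |
| `batch_size` | 512 | labeled encounters per loss mini-batch |
| `patience` | 10 | early-stopping patience in epochs |

`tune_iehgcn()` searches this space by seeded random search or a simplified
tree-structured Parzen estimator (independent per-dimension Parzen densities,
good/bad split at the top quartile); the baseline tuner uses seeded random
search over the boosted-tree/LR/MLP grids.

## Meta-path importance

For each layer, target type and relation the per-node attention
coefficients are averaged over nodes; a meta-path's importance is the
product of these means along its relation chain, read from the output layer
inward. A path shorter than the model depth is padded with the terminal
type's self-coefficients on the remaining inner layers, so that a length-1
path `ENC–Technician` from a 3-layer model is comparable to a length-2
`ENC–Acute–ENC`. Averaging before multiplying (rather than multiplying
per-node products) matches the per-layer recording of coefficients and
keeps the conservation property: over all full-length relation sequences
(self steps allowed anywhere) the importances sum to exactly 1, because each
factor set is a softmax. The pure self chain `ENC` is reported too — it is
the "encounter's own features" pathway and is the natural comparator for
the connectivity paths.

Two caveats are documented rather than hidden. First, attention magnitude is
not identifiable in general (a model can route signal through a relation
while giving it a modest coefficient and a large projection norm);
regularization — input dropout 0.3 with weight decay 1e-4 in the canned
recovery experiments — empirically concentrates attention on informative
relations. Second, signal can reach the output through an inner layer (the
sequence self→acute) rather than the outermost step (acute→…); the canonical
ranking can therefore split one causal pathway across several sequences.
The planted-recovery experiments (`metapath_recovery()`) measure exactly
this end-to-end behaviour: with risk planted solely on one provider
subgroup's latent team risk, that subgroup's length-1 path should rank first
among length-1 paths; with risk planted solely on acute-unit exposure, an
acute-unit path should rank in the top two non-self paths.

## The synthetic cohort generator

The generator emulates the schema and statistical structure of an inpatient
surgical EHR extract. What it emulates, and its defaults:

- **Outcome base rates** target roughly 25% PLOS, 3.2% 30-day and 5.3%
  90-day mortality. PLOS prevalence is self-calibrating (the label is a
  cohort quantile); the mortality baselines are variance-corrected for the
  default planted effects with the logit-normal approximation
  `logit(p)·sqrt(1 + 0.346·Σw²)`, because a planted effect adds variance to
  the linear predictor and would otherwise inflate the marginal rate. The
  two mortality labels are nested by sampling death offsets uniformly on
  [1, 30] days for 30-day deaths and on [31, 90] for 90-day-only deaths.
- **Covariate marginals** are plausible rather than calibrated: age
  N(55.7, 18.0) truncated to adults, 60/40 female/male, a 65/13/5/18
  race-ethnicity mix, sex-specific height/weight with BMI computed from
  them, Poisson comorbidity scores, ordinal ASA-PS on 1–5, Gamma procedure
  intervals, a weekday-dominated calendar.
- **Connectivity**: each encounter draws 1–3 surgical-team members, 1–3
  other clinicians, 1–4 nurses, 0–3 technicians and 0–2 others from shared
  role-specific pools (sizes 60/80/120/50/40), which induces provider
  co-occurrence across encounters; unit stays number 1 + Poisson(1.2) with
  Gamma durations.
- **Planted effects**: outcome log-odds are
  `baseline + Σ w_k · z_k` over standardized terms; terms may be numeric
  covariates, assignment counts (`n_<role>`), latent team risk
  (`team_risk_<role>`, the mean of per-provider N(0,1) risk scores over the
  encounter's providers of that role), stay counts or unit hours. The
  default plants a moderate acute-hours and comorbidity effect on PLOS and
  age/comorbidity effects on mortality. Latent team risk is the provider
  plant used in the recovery experiment because a pure assignment-count
  effect is invisible to row-normalized mean aggregation (every nonzero row
  sums to one), whereas per-provider risk survives averaging.
- **LOS encoding**: PLOS-positive encounters receive `6 + Gamma` days and
  negatives `6·Beta` days, so the 75th-percentile rule applied to the
  generated table recovers the planted label at the default prevalence.
- **Missingness** is MCAR at the rates of the masking experiment (BMI and
  height 4.3%, marital status 2.11%, CCI 8.3%, ASA-PS 1.7%).

What it does **not** emulate: informative missingness, temporal drift,
coding noise, site effects, correlated comorbidity structure, and real
provider-team assortativity. Passing tests on this generator therefore
demonstrate mechanical and statistical correctness of the pipeline and
recoverability of planted effects — not clinical validity on real EHR data.

## Outcome and feature conventions

- PLOS threshold: the 0.75 quantile of postoperative LOS with linear
  interpolation between order statistics (R type 7), computed on the
  training split by default (configurable; computing it on all rows is a
  minor leak we default away from). Mortality windows are inclusive
  (`death_offset <= 30`).
- Continuous covariates: plausibility ranges (BMI 10–80, height 120–220 cm,
  weight 30–300 kg, age 18–110, intervals/durations ≥ 0) null out
  impossible values; mean and *population* SD are fitted on observed
  training values; missing entries are imputed with the training mean;
  zero-variance columns are dropped with a warning rather than divided by
  zero.
- Categorical covariates: "Unknown" absorbs missing values and categories
  unseen in training; one-hot groups sum to one per row.
- Splits default to encounter-level 8:1:1; a patient-grouped split is
  offered because repeat encounters of one patient are correlated, and the
  source convention does not state patient disjointness.
- Resampling (undersample negatives to balance / oversample positives to
  the negative count) applies to training ids only.

## Evaluation statistics

AUROC uses the midrank Mann–Whitney formulation (ties count one half);
AUPRC uses precision–recall step integration (average-precision form).
Confusion-matrix metrics default to threshold 0.5 with an optional Youden-J
threshold chosen on validation data; either way the threshold is recorded in
the report, since recall comparisons are meaningless without it. DeLong's
test uses midrank structural components; identical score vectors return z =
0, p = 1 by convention. Bootstrap intervals are percentile intervals over
stratified resampling (positives and negatives resampled separately), which
keeps rare-outcome resamples two-class; BCa was not used because percentile
intervals are adequate at the n ≥ 500 scales reported and are simpler to
audit.

## Network-science arm

The provider graph counts shared encounters as edge weights and is built
from training encounters by default (a leakage guard; the holistic
all-encounter variant is available to mirror the single-graph convention).
Per-encounter features aggregate metrics of the subgraph induced by the
encounter's own providers; the battery is degree/betweenness/closeness/
eigenvector centrality, average degree connectivity, local clustering, HITS
authority (rescaled to unit Euclidean norm; on undirected graphs it
coincides with the principal eigenvector of the adjacency) and PageRank at
damping 0.85, each summarized by max/min/mean/median/IQR, plus density,
node count and total edge weight. Transfer digraphs exclude self-transitions
(unit X back to X); re-entries still show up in stay counts and unit-hour
covariates. The LR baseline is an IRLS (Newton) ridge-penalized logistic
regression capped at 500 iterations; the MLP is a two-hidden-layer ReLU
network trained with Adam (lr 1e-3, mini-batch 200, ≤ 200 epochs); boosted
trees use xgboost with L2 = 1, L1 = 0 and validation-AUROC early stopping.

## Problem sizes and numerical choices

The canned experiments run at sizes chosen to make their statistical checks
meaningful on a single CPU: recovery experiments use cohorts of ~5,000
encounters (3,800 patients), hidden/attention/embedding width 8, 40 epochs
with patience 10; calibration checks use 500 DeLong simulations at n = 200
and 200 bootstrap-coverage replications at n = 500 with 200 resamples each.
Probabilities are clamped at 1e-7 before logs; attention and softmax
computations subtract row maxima; batch-norm uses eps = 1e-5; ELU uses
alpha = 1 with `exp(min(x, 0))` guarding overflow. All randomness descends
from named seeds through a splitmix-style child-seed function, so every
stage is independently reproducible and two runs with one seed are
bit-identical.

## Known limitations

- Transductive only: predictions require the encounter to be a node of the
  trained graph; there is no inductive out-of-graph inference.
- Attention-based importance is a heuristic explanation, with the
  identifiability caveats above; the Shapley/surrogate attributions are
  local and hold the graph fixed while perturbing one encounter's features.
- The Shapley estimator is permutation sampling against a sampled
  background row per permutation, not KernelSHAP; the surrogate explainer
  uses Gaussian perturbations and an exponential proximity kernel, not the
  original binary-interpretable-features construction.
- The TPE tuner treats dimensions independently.
- The generator's missingness is MCAR; imputation quality under informative
  missingness is untested by design.
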