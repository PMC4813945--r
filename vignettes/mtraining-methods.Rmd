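---
title: "M-training: model, design choices and what the synthetic benchmark shows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{M-training: model, design choices and what the synthetic benchmark shows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtraining)
```

## The model

M-training is a multi-class semi-supervised ensemble scheme. Given a
labeled pool $L$ and an unlabeled pool $U$, it maintains $M \ge 3$ base
classifiers $c_1, \dots, c_M$, each initially fitted on its own random
draw of $0.75\,|L|$ samples of $L$ (rounded half up; the
draws are what make the ensemble diverse). In every round $t$, each
$c_i$ in turn is the *main* classifier and the remaining $M-1$ models
form its committee $C_i$:

* **Pseudo-labeling.** $C_i$ votes on every sample of $U$. A sample
  enters the candidate set $L_i(t)$ when the modal label's vote share
  reaches the threshold $\theta \in (0.5, 1]$ (default $2/3$). Because
  $\theta > 0.5$ an accepted label is the unique strict majority, and
  with $M = 3$ the rule is exactly tri-training's "the other two
  agree". $U$ is re-examined from scratch every round; earlier rounds'
  pseudo-labels are conceptually returned to $U$.
* **Error bound.** The committee's error $e_i(t)$ cannot be measured on
  $U$, so it is estimated on $L$, assuming $L$ and $U$ are draws from
  one distribution. By default the estimate is taken over the
  committee-agreed part of $L$ — the same subpopulation that produces
  pseudo-labels, mirroring the tri-training estimator. If the committee
  never reaches agreement on $L$, the worst case $e_i(t) = 0.5$ is
  reported with a no-evidence marker and the round is skipped.
* **Noise compensation.** Refitting with noisy pseudo-labels only helps
  if the effective training utility $u = m(1 - 2\eta)^2$ grows, where
  $m$ is the pool size and $\eta$ the classification noise rate
  $\eta_i(t) = (\eta_L |L| + e_i(t)\,|L_i(t)|)/(|L| + |L_i(t)|)$. The
  operational conditions are $e_i(t) < e_i(t-1)$,
  $|L_i(t-1)| < |L_i(t)|$ and
  $e_i(t)\,|L_i(t)| < e_i(t-1)\,|L_i(t-1)|$. When the last product
  condition fails but $|L_i(t-1)| > e_i(t) / (e_i(t-1) - e_i(t))$,
  $L_i(t)$ is uniformly sub-sampled to
  $s_i = \lceil e_i(t-1)\,|L_i(t-1)| / e_i(t) - 1 \rceil$ entries,
  which restores the product condition while still growing the set.
  The run history records $u$ before and after every refit; the test
  suite asserts that it strictly increases.
* **Refit and termination.** An accepted $c_i$ is refit on its own
  initial pool united with $L_i(t)$ (deduplicated by sample id, the
  labeled copy winning). The loop stops at the first round with no
  refit, or at `max_rounds` (default 50). Predictions are plurality
  votes over all $M$ models, ties broken by the lowest label in the
  sorted label ordering.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `M` | 4 | ensemble size; 3 recovers tri-training |
| `theta` | 2/3 | committee vote share needed to pseudo-label (fraction, unitless) |
| `init_fraction` | 0.75 | share of $L$ drawn per slot at initialization |
| `eta_L` | 0 | assumed label-noise rate of $L$ (diagnostics only) |
| `max_rounds` | 50 | safety cap; fixed points normally occur in 2–4 rounds |
| SVM `kernel_width` | 0.2749 | RBF coefficient $\gamma$ in $\exp(-\gamma d^2)$ on standardized features |
| SVM `penalty` | 0.4848 | soft-margin cost $C$ |
| PLS-DA `latent_variables` | 5 | capped at the feature dimension at fit time |
| RBFNN `goal_mse` / `spread` | 0.4329 / 0.0176 | error goal and Gaussian width of the network |

The classifier hyperparameter defaults are the tuned operating points
for the 4-sensor indoor-pollutant setup this package targets; all are
overridable. Two conventions deserve a note. First, the SVM kernel
value is interpreted as $\gamma$ multiplying the squared distance; we
also evaluated the alternative reading (a kernel width $\sigma$ with
$\gamma = 1/(2\sigma^2) \approx 6.6$) and rejected it empirically — at
cost 0.4848 such a near-delta kernel cannot even fit its training pool
and test accuracy collapses to chance. Second, the RBF network's error
goal is applied to the residual sum of squares of the one-hot output
layer, the stopping rule of classical incremental RBF design; read as a
per-entry mean squared error the printed value (0.4329) would stop
training before the first neuron, leaving a constant model.

## Decisions where the design was open

* **$\theta$ as a fraction.** The threshold is a vote *share* over the
  $M-1$ committee members, constrained to $(0.5, 1]$. This is the only
  reading under which $M=3$ degenerates exactly to tri-training
  (unanimity of two) while $M=4$ accepts 2-of-3 agreement at the
  default $2/3$.
* **First productive round.** With $|L_i(t-1)| = 0$ the product
  condition is vacuous, so a virtual previous size
  $\lfloor e_i(t)/(e_i(t-1) - e_i(t)) + 1 \rfloor$ is adopted (the
  tri-training bootstrap convention) and the rules re-evaluated against
  it; the history labels these decisions
  `update_with_bootstrap_prev`.
* **Refit pool.** Refits use the slot's own diversified pool plus the
  pseudo-labels; this keeps the printed pool accounting additive
  (e.g. an initial pool of 149 plus 454 accepted pseudo-labels trains
  on 603 samples) and preserves slot diversity across rounds. The
  alternative — union with the full $L$ — is available as
  `mtrain_config(refit_pool = "full_L")`.
* **Synchronous rounds.** All of a round's decisions are computed
  against the start-of-round models, so results are invariant to slot
  order; `scheduling = "sequential"` gives the variant where refits are
  visible within the round.
* **Error estimator.** `error_on = "all"` scores the committee's modal
  label on all of $L$ instead of the agreed part.
* **Degenerate inputs.** $e_i(t) = 0$ short-circuits the sub-sampling
  division and admits the full candidate set (zero measured noise);
  an empty $U$ terminates in one round with the initial ensemble;
  zero-variance features are scaled by 1 instead of failing; splits or
  initial pools that would lose a class entirely are redrawn from a
  derived seed (with a message).
* **Determinism.** Every random draw (slot pools, splits, sub-samples,
  noise) uses a seed derived from the root seed and the draw's indices
  by a fixed mixing scheme, so a run is reproducible for any $M$ and
  independent of evaluation order.
* **Rounding.** All fractional subset sizes round half up, one
  convention everywhere (149 from $0.75 \times 198$, 74 from
  $0.75 \times 99$, 223 from $0.75 \times 297$); reported accuracies
  are conventionally shown at 2 decimals with the same rule.

## The synthetic benchmark: what it emulates, and what it does not

The study design this package targets — three indoor-pollutant gases
measured by a 4-channel metal-oxide array — is emulated at two levels.

The **curve generator** (`simulate_response_curve()`,
`simulate_gas_dataset()`) reproduces the sampling protocol: 1 Hz
acquisition over 15 min (901 samples, phase marks at 120 s / 360 s /
900 s), a clean-air baseline, a saturating exposure rise toward
`baseline + sensitivity × concentration` with time constant
`tau_rise` (20 s), exponential recovery (`tau_decay` 60 s), additive
Gaussian noise, and per-gas concentration grids shaped like the real
campaign (12/11/21 points × 12 replicates = 144/132/252 samples).
With the noise turned off, the steady-state-maximum features equal
their closed form exactly; the test suite asserts closure to 1e-9.

The **feature-cluster generator** (`simulate_feature_clusters()`,
`benchmark_split()`) draws the 4-D features directly from one
multivariate normal per class in a *concentration-ray* geometry: each
class mean lies along a per-gas sensitivity direction and its
covariance is elongated along that direction (s.d. 1.5 along, 0.35
across, means at 2.4 from the origin in standardized units). The scale
constants were calibrated once so that the default M = 4 SVM ensemble
has an initial test accuracy of roughly 70–85% at unlabeled rate 0.5 —
the regime in which refinement is informative — and then frozen.
`separation` scales the class-mean spread: 0 gives chance-level
classes, large values a perfectly separable benchmark.

What the benchmark does **not** emulate: real MOS sensors are
nonlinear in concentration (power-law response), drift over time, and
depend on temperature and humidity; none of that is modeled, and the
Gaussian clusters are a stand-in for an unknown real feature geometry.
Consequently, passing the statistical tests here shows the *algorithm*
behaves as specified — the guards hold, tri-training is recovered at
$M = 3$, refinement does not degrade the ensemble — not that any
particular accuracy is attainable on real E-nose data.

A consequence worth stating plainly: on overlapping Gaussian clusters
the committee's error bound on $L$ settles around 0.10–0.15 and stops
decreasing, so the noise-compensation guard admits only small
pseudo-label batches and the measured improvement from refinement is
small (median ≈ +0.4 accuracy points at rate 0.5 across 20 seeds, with
most seeds unharmed). Large headline gains arise only when the
committee classifies $L$ almost perfectly (so that $e_i(t) \approx 0$
admits the bulk of $U$); that requires a nearly separable feature
geometry, which is incompatible with the 70–85% initial-accuracy regime
on purely Gaussian classes. The acceptance checks therefore assert the
direction and safety of the effect (median final ≥ median initial;
final ≥ initial in at least 70% of seeds), not its magnitude.

## Problem sizes used by the checks

The statistical suites run the canonical configuration: 528-sample
benchmark (396 train / 132 test, stratified 75/25), unlabeled rate 0.5
(|L| = |U| = 198), M = 4 SVM ensembles, 20 seeds; the tri-training
equivalence check uses 100 scripted-vote fixtures plus fitted-model
spot checks; leave-one-out baselines use ~150-sample subsets. These
sizes were chosen to estimate medians and fractions with useful
precision while keeping each suite comfortably fast.

## Known limitations

* $e_i(t)$ estimated on the committee-agreed part of $L$ is optimistic
  when slot errors are strongly correlated (the agreed set then
  includes the shared mistakes); this is intrinsic to the scheme.
* The worst-case-utility argument assumes i.i.d. samples and a uniform
  noise model; violations (drift, batch effects) void the guarantee,
  not just the estimate.
* `impro` is undefined at zero initial accuracy and noisy when the
  test set is small; per-class values on 33–63 test samples move in
  steps of 1.5–3 points.
* PLS-DA inherits mixOmics' requirement of at least one component per
  fit and is capped at the feature dimension, so the printed 5-latent
  configuration effectively runs with 4 components on 4-D features.
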