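---
title: "Selective particle attention: model, assumptions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective particle attention: model, assumptions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spattn)
```

## The problem

A reinforcement-learning agent that acts on pre-learned feature
representations — for example, the channel activations of a pretrained
convolutional network — faces a credit-assignment burden that grows with the
number of channels. Most channels are irrelevant for any one task, and when
the task changes without warning, a value function trained over all channels
must be slowly unlearned. Biological agents appear to solve this with
selective attention: a gate that amplifies the few task-relevant features
and suppresses the rest, re-configured quickly when the reward structure
changes, without touching the slowly-learned representations underneath.

`spattn` implements such a gate as a particle filter over binary
feature-relevance hypotheses, together with everything needed to study it in
a self-contained way: small value-learning agents, a synthetic feature
backend that emulates convolutional channel statistics, two revaluation
benchmarks, and the baseline attention sources against which the filter is
compared.

## The model

Attention is a vector $A \in [0,1]^K$ over $K$ feature channels, summing to
one. It is applied by element-wise multiplication: channel $k$ of the
feature tensor is scaled by $A_k$, the same weight replicated over all
spatial units of that channel, and the attended tensor is flattened and
passed to the downstream learner.

The filter maintains $N$ particles, each a binary vector
$x \in \{0,1\}^K$ — a hypothesis about which channels are useful now. One
update cycle (`update_attention()`) is:

1. **Movement (bottom-up attention).** Per-channel means $\bar f_k$ of the
   current feature tensor are normalised, $v_k = \bar f_k / \sum_j \bar
   f_j$, and converted to Bernoulli probabilities $p_k =
   \exp(v_k \tau_{BU}) / \max_j \exp(v_j \tau_{BU})$, so the most active
   channel always has $p = 1$. Each particle is redrawn wholesale with
   probability $\varphi$, entry $k$ set to one with probability $p_k$. This
   injects a prior toward currently salient channels.
2. **Observation (top-down attention).** Each particle induces an attention
   vector $A^i_k = x^i_k / \sum_j x^i_j$ (the all-zero state maps to the
   uniform vector). The particle's error is the squared difference between
   an observed return $R_t$ and the frozen value estimate $V(s_t; A^i)$ at
   the state that opened the return window:
   $\delta_i = (R_t - V(s_t; A^i))^2$. Identical particle states share one
   value evaluation.
3. **Resampling.** Weights $w_i \propto \exp(-(\delta_i - \min_j \delta_j)
   \tau_{TD})$ are normalised and $N$ particles are drawn i.i.d. with
   replacement.
4. **Output.** The emitted attention is the normalised particle mean,
   $A_k = \bar x_k / \sum_j \bar x_j$.

The filter never backpropagates: all task information enters through the
scalar return.

## Parameters

| Parameter | Meaning | Default (multiple choice / object collection) |
|---|---|---|
| `N` | particles | 250 |
| `tau_bu` | bottom-up strength | 10 / 1 |
| `tau_td` | top-down strength | 10 / 10 |
| `c_max` | steps between attention updates | 1 / 1000 |
| `t_max` | maximum return-window length | 1 / 10 |
| `phi` | per-particle refresh probability | 0.1 |
| `p_init` | initial Bernoulli occupancy | 0.5 |

`phi` and `p_init` are the package's own choices (a small refresh fraction
preserves the posterior while injecting the bottom-up prior; Bernoulli(0.5)
initialisation is an uninformative prior over hypotheses). The rest follow
the task presets of the original study design, available as `spa_config_mc()` and
`spa_config_oc()`. The value-learner presets (`value_config()`) likewise
carry the same study defaults: $\varepsilon = 0.2$, RMSProp
($\lambda = 2.5\times10^{-4}$, $\kappa = 0.95$, $\iota = 0.01$) for the
one-step Monte Carlo network; $\beta = 0.01$, $\gamma = 0.99$, frame skip 8,
Adam ($\alpha = 10^{-4}$) for the advantage actor-critic; query/key
dimension $d = 128$ for the self-attention baseline.

## Degenerate inputs and numerical choices

* An all-zero particle would make $A^i$ undefined; it is mapped to the
  uniform vector (the same semantics as the attend-to-everything baseline).
  `spa_config(redraw_empty = TRUE)` instead redraws empty particles at
  initialisation.
* All-zero channel means make the bottom-up normalisation undefined;
  `bottom_up_probs()` raises an error and leaves the fallback to the caller.
* Exponent arguments in the resampling weights are clipped at $-700$:
  weight ratios below $e^{-700}$ are operationally zero, and clipping keeps
  extreme error gaps from producing `NaN`.
* Ties in the bottom-up argmax need no tie-break (all maxima get $p = 1$);
  ties in the error minimum need none either (the minimum is over values).
* Resampling is plain multinomial with replacement. Lower-variance schemes
  (systematic, stratified) exist but change the distribution of the
  resampled ensemble; the package keeps the replacement-sampling definition.
* Movement redraws a selected particle's whole state, not individual
  entries: the refresh probability `phi` selects particles, and a selected
  particle is drawn fresh from the bottom-up Bernoulli profile.

## Value learners

Both learners are intentionally small feed-forward networks on the
flattened attended features — one leaky-rectified hidden layer
(`hidden_units`, default 256; slope 0.01), then either a scalar value head
(Monte Carlo variant) or a shared trunk with softmax-policy and value heads
(A2C). Two implementation details matter:

* **Leaky rectification.** Feature activations are nonnegative, so with a
  hard rectifier a hidden unit whose bias drifts negative can never
  recover: its gradient is exactly zero for every input in the domain. In
  early experiments whole trunks died this way, leaving the value head
  constant — which silently removes the filter's top-down signal, since all
  particles then predict identically. The leaky slope keeps a small
  gradient alive.
* **Gradient clipping.** A2C gradients are clipped by global norm (at 5),
  standard actor-critic practice that prevents occasional large-advantage
  updates from destabilising the policy.

The n-step return bootstraps with the current value estimate at the state
closing the window, $R_t = \sum_i \gamma^i r_i + \gamma^n V(s_{t+n}; A)$,
with 0 at terminal states; the same return definition feeds both learner
updates and particle scoring. Particle scoring always uses frozen forward
passes.

## The synthetic feature backend

The backend emulates the statistics that make the attention problem
meaningful for convolutional features: each object category has a few
strongly active *discriminative* channels over a common background level.
`backend_spec()` controls the channel count `K`, the number of
discriminative channels per category, their activation advantage
(`signal_ratio`, mean relative to background), the overlap between category
channel sets, and the render noise (`noise_cv`, the coefficient of
variation of gamma-distributed activations around the profile means — gamma
because rectified-network activations are nonnegative and right-skewed; no
claim of distributional fidelity is made). Spatial scenes add each object's
signature at its grid cell and a reserved agent signature at the agent's
cell, so the learner can see where it is.

What the generator does *not* emulate: correlated channels, within-category
exemplar structure, heavy-tailed activation distributions, or any spatial
autocorrelation of real convolutional maps. Passing tests therefore show
that the filter does what its equations say under controllable conditions —
not that it would behave identically on features from a real pretrained
network. A `cnn_adapter()` contract is declared for plugging in a real
backend.

`profile_distances()` reproduces the separation analysis used to compare
easy and hard category combinations: category mean-profiles as points in
$\mathbb{R}^K$, pairwise Euclidean distances, and their off-diagonal mean.
Raising `signal_ratio` provably increases the mean distance, and attention
recovery is empirically faster and more complete on the more separated
backend.

## The benchmarks and the study conditions

**Multiple choice.** Three categories, one stimulus each per trial in random
screen order; picking the current target pays +1, anything else 0; the
target is resampled uniformly at every block boundary (optionally forced to
change). Train and test phases use disjoint stimulus-noise substreams — the
synthetic analogue of held-out exemplars — and the test phase freezes
learner weights, so only attention can adapt. The ideal observer (told the
previous trial's rewarded category, exploring with $\varepsilon$) has
within-block expected reward $(1-\varepsilon) + \varepsilon/3 = 0.8667$ at
$\varepsilon = 0.2$, the ceiling every condition is compared against.

**Object collection.** Objects spawn at the top of a grid at fixed
intervals, fall one row per step, and are caught when they reach the bottom
row in the agent's column; catching a rewarded identity pays +1. At the
midpoint either the rewarded identity switches (reward revaluation) or the
set of identities present switches, all rewarded (state revaluation). A
breadth-first reachability check (`oc_catchable()`) guarantees every spawn
column can be reached before landing, so the reward ceiling is positive.

**Problem sizes.** The package's tests and acceptance script run desk-scale
versions chosen once: the multiple-choice benchmark uses 80 training blocks
and 10 test blocks of 50 trials, `K = 32`, a hidden layer of 64, and the
easy backend (`signal_ratio = 8`, `noise_cv = 0.15`); the full-scale 200
training blocks remain a configuration choice away. The object-collection
benchmark uses a 5×5 grid, `K = 12`, spawns every 2 steps, 40-step
episodes, 400 episodes either side of the revaluation, attention updates
every 100 steps with `phi = 0.05`, a desk learning rate of 0.02 and entropy
weight 0.02. The 5×5 grid (rather than a larger one) was chosen because a
hand-built ideal attention vector demonstrably learns the task there within
the episode budget (final reward ≈ 2.5–3.4 versus ≈ 1.8–1.9 for uniform
attention), which is the precondition for any between-condition ordering to
be observable.

**Observation buffering.** With `c_max > 1` the filter is updated from
completed return windows. Scoring only the single most recent window is the
literal reading of the observation step, but with sparse rewards most
windows carry a zero return and provide no discriminative signal — worse,
they reward particles that blind the value network into a constant
predictor. `run_oc()` therefore averages particle errors over a buffer of
the last 25 completed windows (`obs_buffer`); setting `obs_buffer = 1`
restores the single-window reading.

## Known limitations

The top-down observation step identifies informative channels only when the
value function explains some of the variance in observed returns *and*
candidate particles keep the network reasonably close to its training
distribution. At desk scale the object-collection game sits in a regime
where neither condition is comfortably met: with few channels, sparse
particles (attention weight 1/2 on two channels versus a uniform 1/12)
drive the network far off-distribution, so genuinely informative particles
can score worse than "blind" ones that reduce the network to a
well-calibrated constant; with many channels, all particles are
near-uniform and the error spread collapses below what
$\tau_{TD} = 10$ can amplify. The mechanism therefore needs either long
horizons (many attention updates over which a weak selection gradient can
accumulate) or a return signal whose variance the value network captures
early. The multiple-choice benchmark, with its dense 0/1 returns and
single-step windows, satisfies this easily — attention mass on the rewarded
channels exceeds 0.99 after 200 trials under an oracle value function, and
re-orients within about ten trials of a target switch. The
object-collection game at desk scale does not, and the package's
object-collection ordering check reflects that honestly rather than by
construction.

Other limitations: the filter is the plain sequential importance resampling
scheme (no adaptive particle counts, no learned proposals, no
Rao-Blackwellisation); the self-attention baseline is a single head with
per-channel keys computed from channel means; and environments are
step-counted abstractions with no pixel rendering.
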