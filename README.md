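# spattn

Reward-driven soft attention over pre-learned feature channels, inferred by
a particle filter instead of backpropagation.

## The problem

An agent that learns values or policies on top of a fixed feature extractor
(say, the 512 channel activations of a pretrained convolutional network)
pays for every irrelevant channel twice: learning is slower because the
function ranges over all channels, and task changes are costlier because
the learned function must be overwritten. Selective attention fixes both if
the right channels can be found quickly *from reward feedback alone*.

`spattn` implements that mechanism as a sequential importance resampling
particle filter. Each of `N` particles is a binary vector over the `K`
channels — a hypothesis about which channels matter now. A *movement* step
refreshes a small fraction of particles toward the currently most active
channels (bottom-up salience); an *observation* step scores every particle
by how well the downstream value function, evaluated under that particle's
induced attention, predicts the observed return,
`delta_i = (R_t - V(s_t; A_i))^2`; particles are then resampled with
weights proportional to `exp(-(delta_i - min delta) * tau_td)`, and the
emitted attention is the normalised particle mean. The attended features —
channel `k` scaled by `A_k`, spatial layout preserved — feed an
epsilon-greedy Monte Carlo value network (single-step decisions) or an
advantage actor-critic (sequential decisions).

The package is self-contained: a synthetic category-signature backend
emulates convolutional channel statistics (a few strongly active
discriminative channels per category over a common background), two
revaluation benchmarks (a changing-target multiple-choice task and an
object-collection game whose reward function or state space switches
mid-run) provide the tasks, and uniform (`1/K`), frozen-random,
ideal-observer, and trained query/key self-attention baselines provide the
comparisons.

## A worked example

Infer attention on a three-category multiple-choice task with a perfectly
calibrated (oracle) value function, isolating the filter itself:

```r
library(spattn)

backend <- backend_spec(K = 32, n_categories = 3, n_discriminative = 2,
                        signal_ratio = 8, seed = 11)
task <- mc_task_spec(backend, block_length = 200, train_blocks = 1,
                     test_blocks = 1, seed = 1)
run <- run_mc(task, conditions = "spa", seeds = 1:5, value = "oracle")

library(dplyr)
tidy(run) |>
  filter(phase == "train", trial == 200) |>
  summarise(median_mass = median(attention_mass_on_target))
#> # A tibble: 1 × 1
#>   median_mass
#>         <dbl>
#> 1       0.997
```

After 200 trials the filter concentrates 99.7% (median over five seeds) of
its attention mass on the two channels that actually discriminate the
rewarded category — starting from 250 uninformative Bernoulli(0.5)
hypotheses over 2^32 possible channel subsets, guided only by the trial
rewards.

The full benchmark with learned value networks compares conditions:

```r
task <- mc_task_spec(backend_spec(K = 32, noise_cv = 0.15, seed = 11),
                     train_blocks = 80, test_blocks = 10, seed = 1)
run <- run_mc(task, conditions = c("spa", "all", "ideal"), seeds = 1:5,
              learner = value_config("monte_carlo", hidden_units = 64))
glance(run)
#> # A tibble: 3 × 4
#>   condition train_reward test_reward n_seeds
#>   <chr>            <dbl>       <dbl>   <int>
#> 1 all              0.399       0.424       5
#> 2 ideal            0.857       0.859       5
#> 3 spa              0.735       0.796       5
autoplot(run)   # reward curves, 1-sd ribbons across seeds
```

The filter (`spa`) reaches 93% of the ideal observer's test-phase reward;
attending to all channels uniformly (`all`) stays close to the 1/3 chance
level, because each target switch forces the frozen network to be wrong
about two-thirds of trials.

`run_oc()` runs the object-collection game the same way (`conditions =
c("spa", "random", "all", "self_attention")`), `summarize_runs()`
aggregates either kind of run into per-bin means and switch-recovery
latencies, and `write_run_csv()` / `summarize_runs(<csv paths>)` round-trip
the logs. A command-line front end with `run-mc`, `run-oc`, `summarize` and
`make-fixtures` subcommands lives at `inst/cli/spa-experiments.R`.

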