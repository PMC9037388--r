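# Independent brute-force references for the filter equations, written as
# directly as possible from their definitions (loops, no reuse of package
# internals), plus small fixture builders shared across test files.

bf_bottom_up <- function(means, tau_bu) {
  v <- means / sum(means)
  e <- exp(v * tau_bu)
  e / max(e)
}

bf_particle_attention <- function(state) {
  s <- sum(state)
  if (s == 0) rep(1 / length(state), length(state)) else state / s
}

bf_errors <- function(states, features, rt, value_fn) {
  out <- numeric(nrow(states))
  for (i in seq_len(nrow(states))) {
    a <- bf_particle_attention(states[i, ])
    out[i] <- (rt - value_fn(features, a))^2
  }
  out
}

bf_weights <- function(errors, tau_td) {
  w <- numeric(length(errors))
  for (i in seq_along(errors)) {
    w[i] <- exp(-(errors[i] - min(errors)) * tau_td)
  }
  w / sum(w)
}

bf_ensemble_attention <- function(states) {
  xbar <- numeric(ncol(states))
  for (k in seq_len(ncol(states))) xbar[k] <- mean(states[, k])
  if (sum(xbar) == 0) rep(1 / length(xbar), length(xbar)) else xbar / sum(xbar)
}

# a value function wrapper that counts calls (for the dedup property)
counting_value_fn <- function(fn) {
  calls <- 0L
  f <- function(features, attention) {
    calls <<- calls + 1L
    fn(features, attention)
  }
  attr(f, "calls") <- function() calls
  f
}

make_ensemble <- function(states) {
  spattn:::new_ensemble(as.matrix(states))
}

# small, fast MC task used across experiment tests
tiny_mc_task <- function(...) {
  mc_task_spec(
    backend_spec(K = 12, n_categories = 3, n_discriminative = 2,
                 signal_ratio = 8, seed = 4),
    block_length = 10L, train_blocks = 3L, test_blocks = 1L, seed = 9, ...
  )
}

tiny_oc_task <- function(...) {
  oc_task_spec(
    backend_spec(K = 8, H = 6, W = 6, n_categories = 2,
                 n_discriminative = 1, signal_ratio = 8, noise_cv = 0.1,
                 n_agent_channels = 2, seed = 4),
    spawn_interval = 3L, episode_length = 20L, n_episodes = 6L,
    revaluation_episode = 3L, seed = 9, ...
  )
}

fast_mc_learner <- function(...) {
  value_config("monte_carlo", hidden_units = 16L, ...)
}

fast_a2c_learner <- function(...) {
  value_config("a2c", hidden_units = 16L, frame_skip = 1L, ...)
}
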