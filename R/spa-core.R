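#' Selective particle attention: the filter core
#'
#' The attention mechanism maintains `N` binary particles of length `K`,
#' each a hypothesis about which feature channels are useful for the current
#' task. One update cycle is movement (a fraction `phi` of particles is
#' redrawn toward the currently most active channels — bottom-up attention),
#' observation (each particle is scored by how well the value function,
#' evaluated under that particle's induced attention, predicts the observed
#' return — top-down attention), multinomial resampling with replacement,
#' and finally the emitted attention vector: the normalised particle mean.
#'
#' @name spa-core
NULL

#' Initialise a particle ensemble
#'
#' Draws an `N x K` binary matrix with i.i.d. Bernoulli(`p_init`) entries.
#' Seeds the session RNG from `config$seed`, so a full run (initialisation
#' plus every subsequent stochastic filter operation) is reproducible from
#' the config alone.
#'
#' @param config An [spa_config()].
#' @param set_seed If `TRUE` (default) seed the RNG from `config$seed`
#'   before drawing; set `FALSE` when the caller manages the RNG stream.
#' @return An integer matrix of class `particle_ensemble` (`N x K`, entries
#'   in `{0, 1}`).
#' @export
#' @examples
#' ens <- init_ensemble(spa_config(K = 4, N = 6, seed = 7))
#' dim(ens)
init_ensemble <- function(config, set_seed = TRUE) {
  stopifnot(inherits(config, "spa_config"))
  if (isTRUE(set_seed)) set.seed(config$seed)
  states <- matrix(
    as.integer(stats::runif(config$N * config$K) < config$p_init),
    nrow = config$N, ncol = config$K
  )
  if (config$redraw_empty) {
    empty <- rowSums(states) == 0L
    while (any(empty)) {
      states[empty, ] <- matrix(
        as.integer(stats::runif(sum(empty) * config$K) < config$p_init),
        nrow = sum(empty)
      )
      empty <- rowSums(states) == 0L
    }
  }
  new_ensemble(states)
}

new_ensemble <- function(states) {
  storage.mode(states) <- "integer"
  structure(states, class = c("particle_ensemble", "matrix", "array"))
}

#' @export
print.particle_ensemble <- function(x, ...) {
  cat(sprintf("<particle_ensemble> %d particles x %d channels\n",
              nrow(x), ncol(x)))
  cat(sprintf("  mean occupancy: %.3f, unique states: %d\n",
              mean(x), nrow(unique(unclass(x)))))
  invisible(x)
}

#' Bottom-up channel probabilities from current activations
#'
#' Normalises the per-channel mean activations to sum to one (removing
#' overall gain differences between time steps), exponentiates with the
#' bottom-up strength and divides by the maximum, so the most active channel
#' always gets probability exactly 1 and every channel gets a probability in
#' `(0, 1]`. These are the Bernoulli probabilities used to redraw particles
#' in the movement step.
#'
#' @param channel_means Length-`K` nonnegative channel means, not all zero.
#' @param tau_bu Bottom-up strength (nonnegative); `0` makes every channel
#'   probability 1.
#' @return Length-`K` vector of probabilities in `(0, 1]`.
#' @export
#' @examples
#' bottom_up_probs(c(2, 1, 1, 0), tau_bu = 10)
bottom_up_probs <- function(channel_means, tau_bu) {
  channel_means <- as.numeric(channel_means)
  check_nonneg(tau_bu, "tau_bu")
  if (anyNA(channel_means) || any(channel_means < 0)) {
    stop("Channel means must be nonnegative.", call. = FALSE)
  }
  s <- sum(channel_means)
  if (s == 0) {
    stop("All-zero channel means: bottom-up probabilities undefined.",
         call. = FALSE)
  }
  v <- channel_means / s
  z <- v * tau_bu
  exp(z - max(z))
}

#' Movement step: refresh a fraction of particles toward active channels
#'
#' Each particle is independently selected with probability `phi`; a
#' selected particle has its whole state redrawn, entry `k` set to 1 with
#' probability `probs[k]`. Unselected particles pass through unchanged.
#'
#' @param ensemble A `particle_ensemble`.
#' @param probs Length-`K` Bernoulli probabilities, typically from
#'   [bottom_up_probs()].
#' @param phi Per-particle refresh probability in `[0, 1]`.
#' @return The updated `particle_ensemble`.
#' @export
movement_step <- function(ensemble, probs, phi) {
  stopifnot(inherits(ensemble, "particle_ensemble"))
  probs <- as.numeric(probs)
  if (length(probs) != ncol(ensemble) || anyNA(probs) ||
      any(probs < 0) || any(probs > 1)) {
    stop("`probs` must be length-K probabilities.", call. = FALSE)
  }
  if (phi < 0 || phi > 1) stop("`phi` must lie in [0, 1].", call. = FALSE)
  if (phi == 0) return(ensemble)
  n <- nrow(ensemble)
  move <- stats::runif(n) < phi
  m <- sum(move)
  if (m > 0L) {
    redrawn <- matrix(
      as.integer(stats::runif(m * length(probs)) <
                   matrix(probs, nrow = m, ncol = length(probs), byrow = TRUE)),
      nrow = m
    )
    ensemble[move, ] <- redrawn
  }
  ensemble
}

#' Attention induced by a single particle
#'
#' Normalises a binary hypothesis to an attention vector, dividing by the
#' number of attended channels so hypotheses of different sizes are
#' comparable. The all-zero state maps to the uniform vector `1/K`.
#'
#' @param state Length-`K` binary vector.
#' @return Length-`K` attention vector.
#' @export
#' @examples
#' particle_attention(c(1, 0, 1, 0))
particle_attention <- function(state) {
  state <- as.numeric(state)
  if (any(!state %in% c(0, 1))) stop("Particle state must be binary.", call. = FALSE)
  attention_vector(state)
}

#' Observation step: squared return-prediction errors per particle
#'
#' Scores each particle by the squared error between the observed return and
#' the value function evaluated under that particle's induced attention at
#' the state that opened the return window. The value function is evaluated
#' at most once per unique particle state (per observation); as the ensemble
#' converges this collapses to a handful of evaluations.
#'
#' When `obs` is a list of return observations, each particle's error is the
#' mean of its squared errors over the buffer. Averaging over several recent
#' windows stabilises the top-down signal when rewards are sparse and most
#' single windows carry a zero return.
#'
#' @param ensemble A `particle_ensemble`.
#' @param obs A [return_observation()], or a list of them.
#' @param value_fn Function `(features, attention) -> scalar value`; must not
#'   mutate learner state (see [value_fn()] for learners).
#' @return Length-`N` vector of nonnegative squared errors.
#' @export
particle_errors <- function(ensemble, obs, value_fn) {
  stopifnot(inherits(ensemble, "particle_ensemble"))
  obs_list <- if (inherits(obs, "return_observation")) list(obs) else obs
  stopifnot(length(obs_list) >= 1L,
            all(vapply(obs_list, inherits, logical(1), "return_observation")))
  keys <- apply(unclass(ensemble), 1L, paste, collapse = "")
  uniq_idx <- which(!duplicated(keys))
  delta_u <- vapply(uniq_idx, function(i) {
    a <- particle_attention(ensemble[i, ])
    mean(vapply(obs_list, function(o) {
      (o$return_value - as.numeric(value_fn(o$start_features, a)))^2
    }, numeric(1)))
  }, numeric(1))
  names(delta_u) <- keys[uniq_idx]
  delta <- delta_u[keys]
  names(delta) <- NULL
  delta
}

#' A return observation for particle scoring
#'
#' Pairs the feature tensor at the state opening a return window with the
#' scalar return observed over that window (up to `t_max` steps, optionally
#' bootstrapped; see [compute_nstep_return()]).
#'
#' @param start_features A [feature_tensor()].
#' @param return_value Finite scalar return.
#' @return An object of class `return_observation`.
#' @export
return_observation <- function(start_features, return_value) {
  stopifnot(inherits(start_features, "feature_tensor"),
            is.numeric(return_value), length(return_value) == 1L,
            is.finite(return_value))
  structure(
    list(start_features = start_features, return_value = as.numeric(return_value)),
    class = "return_observation"
  )
}

#' Resampling weights from particle errors
#'
#' Converts squared return-prediction errors into a probability distribution
#' over particles: `w_i` is proportional to `exp(-(delta_i - min(delta)) *
#' tau_td)`. Subtracting the minimum before exponentiating makes the weights
#' invariant to a common error offset and numerically safe; exponent
#' arguments are clipped at -700 so extreme error gaps underflow to an exact
#' zero weight rather than NaN.
#'
#' @param errors Length-`N` finite nonnegative errors.
#' @param tau_td Top-down strength; `0` gives uniform weights.
#' @return Length-`N` probabilities summing to 1.
#' @export
#' @examples
#' resampling_weights(c(0, 1), tau_td = 10)
resampling_weights <- function(errors, tau_td) {
  errors <- as.numeric(errors)
  check_nonneg(tau_td, "tau_td")
  if (anyNA(errors) || any(!is.finite(errors))) {
    stop("Errors must be finite.", call. = FALSE)
  }
  z <- -(errors - min(errors)) * tau_td
  w <- exp(pmax(z, -700))
  w / sum(w)
}

#' Multinomial resampling with replacement
#'
#' Draws `N` particle indices i.i.d. from the given weights and rebuilds the
#' ensemble from copies of the drawn particles.
#'
#' @param ensemble A `particle_ensemble`.
#' @param weights Length-`N` probabilities summing to 1 (within `1e-8`).
#' @return The resampled `particle_ensemble`.
#' @export
resample_particles <- function(ensemble, weights) {
  stopifnot(inherits(ensemble, "particle_ensemble"))
  weights <- as.numeric(weights)
  if (length(weights) != nrow(ensemble) || anyNA(weights) || any(weights < 0)) {
    stop("`weights` must be length-N nonnegative numbers.", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-8) {
    stop("`weights` must sum to one.", call. = FALSE)
  }
  idx <- sample.int(nrow(ensemble), size = nrow(ensemble),
                    replace = TRUE, prob = weights)
  new_ensemble(unclass(ensemble)[idx, , drop = FALSE])
}

#' Attention emitted by the ensemble
#'
#' The per-channel mean of the particle states, normalised to sum to one.
#' An all-zero ensemble maps to the uniform vector.
#'
#' @param ensemble A `particle_ensemble`.
#' @return Length-`K` attention vector.
#' @export
#' @examples
#' ens <- spattn:::new_ensemble(rbind(c(1L, 0L, 1L), c(1L, 1L, 0L)))
#' ensemble_attention(ens)
ensemble_attention <- function(ensemble) {
  stopifnot(inherits(ensemble, "particle_ensemble"))
  attention_vector(colMeans(ensemble))
}

#' One full attention update
#'
#' Composes the filter steps in order: movement (bottom-up probabilities
#' computed from the current feature tensor), observation (squared
#' return-prediction errors), resampling weights, multinomial resampling,
#' and the emitted ensemble attention.
#'
#' @param ensemble A `particle_ensemble`.
#' @param current The [feature_tensor()] observed at the update step; its
#'   channel means drive the movement step.
#' @param obs A [return_observation()] for the most recently completed
#'   return window, or a list of recent ones (errors are then averaged over
#'   the buffer; see [particle_errors()]).
#' @param value_fn Function `(features, attention) -> scalar`.
#' @param config An [spa_config()].
#' @return A list with elements `ensemble` (post-update) and `attention`
#'   (length-`K` vector).
#' @export
update_attention <- function(ensemble, current, obs, value_fn, config) {
  stopifnot(inherits(config, "spa_config"),
            inherits(current, "feature_tensor"))
  probs <- bottom_up_probs(current$channel_means, config$tau_bu)
  ensemble <- movement_step(ensemble, probs, config$phi)
  delta <- particle_errors(ensemble, obs, value_fn)
  w <- resampling_weights(delta, config$tau_td)
  ensemble <- resample_particles(ensemble, w)
  list(ensemble = ensemble, attention = ensemble_attention(ensemble))
}

#' Serialise ensembles and attention traces
#'
#' Writes a particle ensemble (one row per particle, one column per channel)
#' or an attention vector (one row per channel) to CSV for resuming or
#' external analysis.
#'
#' @param ensemble A `particle_ensemble`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "particle_ensemble"))
  df <- as.data.frame(unclass(ensemble))
  names(df) <- paste0("channel_", seq_len(ncol(ensemble)))
  df <- cbind(particle = seq_len(nrow(ensemble)), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ensemble_csv
#' @export
read_ensemble_csv <- function(path) {
  df <- utils::read.csv(path)
  new_ensemble(as.matrix(df[, -1, drop = FALSE]))
}

#' @rdname write_ensemble_csv
#' @param attention Length-`K` attention vector.
#' @export
write_attention_csv <- function(attention, path) {
  validate_attention(attention)
  utils::write.csv(
    data.frame(channel = seq_along(attention), weight = as.numeric(attention)),
    path, row.names = FALSE
  )
  invisible(path)
}
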