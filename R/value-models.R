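#' Value-learner configuration
#'
#' Hyper-parameters for the two downstream learners. Defaults reproduce the
#' task presets: the epsilon-greedy one-step Monte Carlo value network
#' (`epsilon = 0.2`, RMSProp with `lr = 0.00025`, `rmsprop_momentum = 0.95`,
#' `rmsprop_eps = 0.01`) and the advantage actor-critic
#' (`entropy_beta = 0.01`, `gamma = 0.99`, `frame_skip = 8`, Adam with
#' `adam_lr = 0.0001`).
#'
#' @param variant `"monte_carlo"` or `"a2c"`.
#' @param epsilon Exploration probability for epsilon-greedy action selection.
#' @param lr RMSProp learning rate (Monte Carlo variant).
#' @param rmsprop_momentum RMSProp moving-average coefficient.
#' @param rmsprop_eps RMSProp denominator constant.
#' @param entropy_beta Entropy-bonus weight (A2C).
#' @param gamma Discount factor for future rewards (A2C).
#' @param frame_skip Number of environment ticks each chosen action is
#'   repeated for (A2C; applied by the object-collection loop).
#' @param adam_lr Adam learning rate (A2C).
#' @param hidden_units Width of the single rectified hidden layer.
#'
#' @return A list of class `value_config`.
#' @export
value_config <- function(variant = c("monte_carlo", "a2c"),
                         epsilon = 0.2, lr = 0.00025,
                         rmsprop_momentum = 0.95, rmsprop_eps = 0.01,
                         entropy_beta = 0.01, gamma = 0.99,
                         frame_skip = 8L, adam_lr = 0.0001,
                         hidden_units = 256L) {
  variant <- match.arg(variant)
  structure(
    list(variant = variant, epsilon = epsilon, lr = lr,
         rmsprop_momentum = rmsprop_momentum, rmsprop_eps = rmsprop_eps,
         entropy_beta = entropy_beta, gamma = gamma,
         frame_skip = as.integer(frame_skip), adam_lr = adam_lr,
         hidden_units = as.integer(hidden_units)),
    class = "value_config"
  )
}

#' Create a value learner
#'
#' A small feed-forward network on the flattened attended features: one
#' rectified hidden layer, then a scalar value head (Monte Carlo variant) or
#' shared trunk with separate softmax-policy and value heads (A2C variant).
#' Parameters live in an environment so update functions train in place;
#' evaluation never mutates them.
#'
#' @param K Number of feature channels.
#' @param config A [value_config()].
#' @param H,W Spatial grid per channel (input dimension is `K * H * W`).
#' @param n_actions Number of discrete actions (A2C variant).
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `value_learner` (an environment).
#' @export
#' @examples
#' vl <- value_learner(K = 4, config = value_config("monte_carlo"), seed = 1)
#' evaluate_value(vl, feature_tensor(c(1, 0, 2, 1)), rep(0.25, 4))
value_learner <- function(K, config = value_config(), H = 1L, W = 1L,
                          n_actions = 2L, seed = 1L) {
  stopifnot(inherits(config, "value_config"))
  D <- as.integer(K * H * W)
  hid <- config$hidden_units
  rng <- local_rng(seed)
  init_mat <- function(nr, nc) {
    matrix(rng$rnorm(nr * nc, sd = 1 / sqrt(nc)), nrow = nr, ncol = nc)
  }
  lrn <- new.env(parent = emptyenv())
  lrn$config <- config
  lrn$K <- as.integer(K); lrn$H <- as.integer(H); lrn$W <- as.integer(W)
  lrn$D <- D
  lrn$n_actions <- as.integer(n_actions)
  lrn$W1 <- init_mat(hid, D)
  lrn$b1 <- numeric(hid)
  lrn$wv <- init_mat(1L, hid)
  lrn$bv <- 0
  if (config$variant == "a2c") {
    lrn$Wp <- init_mat(n_actions, hid)
    lrn$bp <- numeric(n_actions)
  }
  lrn$opt <- new.env(parent = emptyenv())  # per-parameter optimiser caches
  lrn$step <- 0L
  class(lrn) <- "value_learner"
  lrn
}

#' @export
print.value_learner <- function(x, ...) {
  cat(sprintf("<value_learner> variant = %s, input %d -> hidden %d\n",
              x$config$variant, x$D, length(x$b1)))
  invisible(x)
}

# forward pass; returns value, policy logits and the cached intermediates
# needed for backprop. The hidden layer is leaky-rectified: feature inputs
# are nonnegative, so hard rectification lets units die irrecoverably once
# their bias goes negative.
LEAK <- 0.01

forward_pass <- function(lrn, input) {
  z1 <- drop(lrn$W1 %*% input) + lrn$b1
  h <- ifelse(z1 > 0, z1, LEAK * z1)
  v <- drop(lrn$wv %*% h) + lrn$bv
  out <- list(input = input, z1 = z1, h = h, value = v)
  if (lrn$config$variant == "a2c") {
    logits <- drop(lrn$Wp %*% h) + lrn$bp
    logits <- logits - max(logits)
    p <- exp(logits); p <- p / sum(p)
    out$policy <- p
    out$logits <- logits
  }
  out
}

flatten_attended <- function(features, attention) {
  as.numeric(apply_attention(features, attention))
}

#' Evaluate the value head under a given attention vector
#'
#' A pure forward pass on the attended, flattened features. Used both for
#' action selection and (with frozen weights) for scoring particles; it
#' never changes learner parameters.
#'
#' @param learner A [value_learner()].
#' @param features A [feature_tensor()].
#' @param attention Length-`K` attention vector.
#' @return Scalar value estimate.
#' @export
evaluate_value <- function(learner, features, attention) {
  stopifnot(inherits(learner, "value_learner"))
  if (length(attention) != learner$K) {
    stop("Attention length does not match the learner's channel count.",
         call. = FALSE)
  }
  forward_pass(learner, flatten_attended(features, attention))$value
}

#' Value-function closure for particle scoring
#'
#' Wraps a learner into the `(features, attention) -> value` contract that
#' [particle_errors()] expects: frozen forward passes of the current network.
#'
#' @param learner A [value_learner()].
#' @return A function of `(features, attention)`.
#' @export
value_fn <- function(learner) {
  force(learner)
  function(features, attention) evaluate_value(learner, features, attention)
}

#' Epsilon-greedy action selection
#'
#' With probability `1 - epsilon` picks an argmax of the candidate values
#' (uniformly among exact ties), otherwise a uniform random candidate.
#'
#' @param values Numeric vector of candidate action values (length >= 1).
#' @param epsilon Exploration probability.
#' @return A single index into `values`.
#' @export
select_action_egreedy <- function(values, epsilon) {
  if (length(values) < 1L) stop("No candidate actions.", call. = FALSE)
  if (stats::runif(1) < epsilon) {
    return(sample.int(length(values), 1L))
  }
  best <- which(values == max(values))
  if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
}

# one RMSProp step for a named parameter
rmsprop_step <- function(lrn, name, grad) {
  cfg <- lrn$config
  cache_name <- paste0("ms_", name)
  cache <- lrn$opt[[cache_name]]
  if (is.null(cache)) cache <- grad * 0
  cache <- cfg$rmsprop_momentum * cache + (1 - cfg$rmsprop_momentum) * grad^2
  lrn$opt[[cache_name]] <- cache
  lrn[[name]] <- lrn[[name]] - cfg$lr * grad / (sqrt(cache) + cfg$rmsprop_eps)
  invisible(NULL)
}

# one Adam step for a named parameter
adam_step <- function(lrn, name, grad, t) {
  cfg <- lrn$config
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  m <- lrn$opt[[paste0("m_", name)]]
  v <- lrn$opt[[paste0("v_", name)]]
  if (is.null(m)) { m <- grad * 0; v <- grad * 0 }
  m <- b1 * m + (1 - b1) * grad
  v <- b2 * v + (1 - b2) * grad^2
  lrn$opt[[paste0("m_", name)]] <- m
  lrn$opt[[paste0("v_", name)]] <- v
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  lrn[[name]] <- lrn[[name]] - cfg$adam_lr * mhat / (sqrt(vhat) + eps)
  invisible(NULL)
}

#' One-step Monte Carlo update of the value network
#'
#' One RMSProp step on the squared error between the observed reward and
#' the predicted value of the chosen stimulus under the current attention.
#'
#' @param learner A `monte_carlo` [value_learner()].
#' @param features [feature_tensor()] of the chosen stimulus.
#' @param attention Attention vector in force when the choice was made.
#' @param reward Observed scalar reward.
#' @param return_input_grad If `TRUE`, also return the gradient of the loss
#'   with respect to the (attended, flattened) input — used by the
#'   self-attention baseline to train its query/key maps.
#' @return The squared error before the update (invisibly unless
#'   `return_input_grad`, in which case a list with `loss` and `input_grad`).
#' @export
mc_update <- function(learner, features, attention, reward,
                      return_input_grad = FALSE) {
  stopifnot(inherits(learner, "value_learner"),
            learner$config$variant == "monte_carlo")
  x <- flatten_attended(features, attention)
  fw <- forward_pass(learner, x)
  err <- reward - fw$value
  # d(loss)/dV with loss = (r - V)^2
  dV <- -2 * err
  dh <- drop(dV * learner$wv)
  dz1 <- dh * ifelse(fw$z1 > 0, 1, LEAK)
  gW1 <- tcrossprod(dz1, x)
  input_grad <- if (return_input_grad) drop(crossprod(learner$W1, dz1)) else NULL
  rmsprop_step(learner, "wv", matrix(dV * fw$h, nrow = 1L))
  rmsprop_step(learner, "bv", dV)
  rmsprop_step(learner, "W1", gW1)
  rmsprop_step(learner, "b1", dz1)
  learner$step <- learner$step + 1L
  if (return_input_grad) {
    list(loss = err^2, input_grad = input_grad)
  } else {
    invisible(err^2)
  }
}

#' Discounted n-step return
#'
#' `R_t = sum_i gamma^i r_i + gamma^n * bootstrap` with `n = length(rewards)`
#' and a bootstrap of 0 for terminal windows.
#'
#' @param rewards Numeric rewards, `1 <= length(rewards) <= t_max`.
#' @param bootstrap_value Value estimate at the state closing the window, or
#'   `NULL` / 0 for terminal windows.
#' @param gamma Discount factor.
#' @param t_max Maximum window length.
#' @return A list of class `nstep_return` with `return_value` and `length`.
#' @export
#' @examples
#' compute_nstep_return(c(1, 0, 0), bootstrap_value = 2, gamma = 0.99, t_max = 10)
compute_nstep_return <- function(rewards, bootstrap_value = NULL, gamma,
                                 t_max) {
  n <- length(rewards)
  if (n < 1L) stop("Empty reward window.", call. = FALSE)
  if (n > t_max) stop("Reward window longer than `t_max`.", call. = FALSE)
  if (is.null(bootstrap_value)) bootstrap_value <- 0
  disc <- gamma^(seq_len(n) - 1L)
  rt <- sum(disc * rewards) + gamma^n * bootstrap_value
  structure(list(return_value = rt, length = n), class = "nstep_return")
}

#' Advantage actor-critic update on a short trajectory
#'
#' One Adam step on the combined loss over a trajectory of at most `t_max`
#' transitions: policy gradient weighted by the advantage `R_t - V`, value
#' regression `(R_t - V)^2`, and an entropy bonus weighted by
#' `entropy_beta`. Returns are n-step with a bootstrap from the value head
#' at the state after the last transition (0 when terminal). All forward
#' passes use the attended features under the supplied attention vector.
#'
#' @param learner An `a2c` [value_learner()].
#' @param trajectory List of transitions, each a list with `features`
#'   ([feature_tensor()]), `action` (1-based index), `reward` (scalar), and
#'   optionally `next_features` (`NULL` when terminal) on the last element.
#' @param attention Attention vector in force over the trajectory.
#' @param return_input_grads If `TRUE`, also return per-step gradients of the
#'   loss with respect to the attended inputs (for the self-attention
#'   baseline).
#' @return Invisibly, the total loss (or a list with `loss` and
#'   `input_grads`).
#' @export
a2c_update <- function(learner, trajectory, attention,
                       return_input_grads = FALSE) {
  stopifnot(inherits(learner, "value_learner"),
            learner$config$variant == "a2c")
  cfg <- learner$config
  n <- length(trajectory)
  if (n < 1L) stop("Empty trajectory.", call. = FALSE)
  # attention may be one vector for the whole segment or one per transition
  # (the self-attention baseline recomputes it every step)
  attn_list <- if (is.list(attention)) attention else rep(list(attention), n)
  stopifnot(length(attn_list) == n)
  last <- trajectory[[n]]
  bootstrap <- if (is.null(last$next_features)) 0 else {
    evaluate_value(learner, last$next_features, attn_list[[n]])
  }
  rewards <- vapply(trajectory, `[[`, numeric(1), "reward")
  # n-step return at each position, sharing the single bootstrap at the end
  returns <- numeric(n)
  acc <- bootstrap
  for (i in rev(seq_len(n))) {
    acc <- rewards[i] + cfg$gamma * acc
    returns[i] <- acc
  }
  grads <- list()
  input_grads <- if (return_input_grads) vector("list", n) else NULL
  total_loss <- 0
  for (i in seq_len(n)) {
    tr <- trajectory[[i]]
    x <- flatten_attended(tr$features, attn_list[[i]])
    fw <- forward_pass(learner, x)
    p <- fw$policy
    adv <- returns[i] - fw$value
    logp <- fw$logits - log(sum(exp(fw$logits)))
    entropy <- -sum(p * logp)
    total_loss <- total_loss +
      (-logp[tr$action] * adv) + 0.5 * adv^2 - cfg$entropy_beta * entropy
    # gradient wrt logits: policy-gradient term + entropy term
    onehot <- numeric(learner$n_actions); onehot[tr$action] <- 1
    dlogits <- (p - onehot) * adv                 # -d(logp[a] * adv)/dlogits
    dlogits <- dlogits + cfg$entropy_beta * p * (logp + entropy)
    dV <- -adv                                    # d(0.5 * adv^2)/dV
    dh <- drop(crossprod(learner$Wp, dlogits)) + drop(dV * learner$wv)
    dz1 <- dh * ifelse(fw$z1 > 0, 1, LEAK)
    g <- list(
      Wp = tcrossprod(dlogits, fw$h), bp = dlogits,
      wv = matrix(dV * fw$h, nrow = 1L), bv = dV,
      W1 = tcrossprod(dz1, x), b1 = dz1
    )
    grads <- if (length(grads) == 0L) g else Map(`+`, grads, g)
    if (return_input_grads) {
      input_grads[[i]] <- drop(crossprod(learner$W1, dz1))
    }
  }
  learner$step <- learner$step + 1L
  # clip by global norm (standard actor-critic practice) for stability
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1)))) / n
  scale <- if (gnorm > 5) 5 / gnorm else 1
  for (name in names(grads)) {
    adam_step(learner, name, scale * grads[[name]] / n, learner$step)
  }
  if (return_input_grads) {
    list(loss = total_loss / n, input_grads = input_grads)
  } else {
    invisible(total_loss / n)
  }
}

#' Sample an action from the A2C policy
#'
#' @param learner An `a2c` [value_learner()].
#' @param features A [feature_tensor()].
#' @param attention Attention vector.
#' @return A list with `action` (1-based index) and `policy` (probabilities).
#' @export
a2c_act <- function(learner, features, attention) {
  fw <- forward_pass(learner, flatten_attended(features, attention))
  action <- sample.int(learner$n_actions, 1L, prob = fw$policy)
  list(action = action, policy = fw$policy, value = fw$value)
}

#' Save or restore learner parameters
#'
#' Checkpoints are plain lists of numeric arrays, written as an RDS-free
#' CSV-backed container is unnecessary here: use `learner_weights()` to
#' extract, `set_learner_weights()` to restore.
#'
#' @param learner A [value_learner()].
#' @return A named list of parameter arrays.
#' @export
learner_weights <- function(learner) {
  nm <- c("W1", "b1", "wv", "bv", if (learner$config$variant == "a2c") c("Wp", "bp"))
  stats::setNames(lapply(nm, function(n) learner[[n]]), nm)
}

#' @rdname learner_weights
#' @param weights A list as returned by `learner_weights()`.
#' @export
set_learner_weights <- function(learner, weights) {
  for (n in names(weights)) learner[[n]] <- weights[[n]]
  invisible(learner)
}

# isolated RNG stream exposing just rnorm (see R/rng.R)
local_rng <- function(seed) {
  stream <- rng_stream(seed)
  stream$rnorm <- function(n, sd = 1) {
    with_stream(stream, stats::rnorm(n, sd = sd))
  }
  stream
}
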