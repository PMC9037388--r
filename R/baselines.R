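#' Baseline attention sources
#'
#' Four comparison conditions share the particle filter's attention-vector
#' contract: a uniform vector over all channels, a frozen random binary
#' vector, an ideal observer that ignores features entirely, and a single
#' query/key self-attention head trained by backpropagation through the
#' learner's loss.
#'
#' @name baselines
NULL

#' Uniform attention over all channels
#'
#' Attends to every channel equally with weight `1/K`; the no-selection
#' control condition.
#'
#' @param K Number of channels.
#' @return Length-`K` attention vector.
#' @export
#' @examples
#' all_attention(4)
all_attention <- function(K) {
  if (K < 1) stop("`K` must be positive.", call. = FALSE)
  rep(1 / K, K)
}

#' Frozen random binary attention
#'
#' Draws a binary vector with i.i.d. Bernoulli(0.5) entries (redrawn if all
#' zero, so normalisation is defined) and normalises it to sum to one. The
#' vector is fixed for a whole run: random dimensionality reduction without
#' task guidance.
#'
#' @param K Number of channels.
#' @param seed Integer seed; the same seed always gives the same vector.
#' @return Length-`K` attention vector.
#' @export
random_attention <- function(K, seed) {
  if (K < 1) stop("`K` must be positive.", call. = FALSE)
  stream <- rng_stream(seed)
  repeat {
    bits <- with_stream(stream, as.integer(stats::runif(K) < 0.5))
    if (sum(bits) > 0L) break
  }
  attention_vector(bits)
}

#' Ideal-observer choice for the multiple-choice task
#'
#' Ceiling baseline: with probability `1 - epsilon` picks the stimulus whose
#' category matches the rewarded category of the previous trial (uniform
#' random before any history exists), else explores uniformly. It reads
#' category labels and reward history only — never feature values.
#'
#' @param categories Category ids of the on-screen stimuli, in screen order.
#' @param last_rewarded_category Rewarded category of the previous trial, or
#'   `NA` on the first trial.
#' @param epsilon Exploration probability.
#' @return A 1-based choice index.
#' @export
ideal_observer_choice <- function(categories, last_rewarded_category, epsilon) {
  n <- length(categories)
  if (n < 1L) stop("No stimuli.", call. = FALSE)
  if (stats::runif(1) < epsilon || is.na(last_rewarded_category)) {
    return(sample.int(n, 1L))
  }
  match(last_rewarded_category, categories)
}

#' A single query/key self-attention head
#'
#' The learned-attention baseline: a query vector `q` is computed from the
#' channel means by a learned linear map, and each channel's key from its
#' own mean through a shared learned affine map; attention is the softmax of
#' the scaled dot products `q . k_j / sqrt(d)`. Parameters train by
#' backpropagating the learner's loss through the attention vector
#' ([self_attention_backward()]), in contrast to the particle filter which
#' never backpropagates.
#'
#' @param K Number of channels.
#' @param d Query/key dimensionality (default 128).
#' @param lr SGD learning rate for the attention parameters.
#' @param seed Integer seed for initialisation.
#' @param init_scale Scale of the random initial weights; `0` gives exactly
#'   uniform attention at step 0 (but zero gradients, so training needs a
#'   positive scale).
#' @return An environment of class `self_attention`.
#' @export
self_attention <- function(K, d = 128L, lr = 0.01, seed = 1L,
                           init_scale = 0.1) {
  if (d < 1) stop("`d` must be >= 1.", call. = FALSE)
  rng <- local_rng(seed)
  sa <- new.env(parent = emptyenv())
  sa$K <- as.integer(K); sa$d <- as.integer(d); sa$lr <- lr
  sa$Wq <- matrix(rng$rnorm(d * K, sd = init_scale / sqrt(K)), nrow = d)
  sa$u <- rng$rnorm(d, sd = init_scale)
  sa$b <- rng$rnorm(d, sd = init_scale)
  class(sa) <- "self_attention"
  sa
}

#' @export
print.self_attention <- function(x, ...) {
  cat(sprintf("<self_attention> K = %d channels, d = %d\n", x$K, x$d))
  invisible(x)
}

#' Forward pass of the self-attention head
#'
#' @param sa A [self_attention()] head.
#' @param features A [feature_tensor()].
#' @return A list with `attention` (length-`K`, sums to 1) and `cache`
#'   (intermediates for the backward pass).
#' @export
self_attention_vector <- function(sa, features) {
  stopifnot(inherits(sa, "self_attention"), inherits(features, "feature_tensor"))
  f <- features$channel_means
  q <- drop(sa$Wq %*% f)                       # d
  keys <- outer(sa$u, f) + sa$b                # d x K, key_j = u * f_j + b
  logits <- drop(crossprod(keys, q)) / sqrt(sa$d)
  logits <- logits - max(logits)
  a <- exp(logits); a <- a / sum(a)
  list(attention = a,
       cache = list(f = f, q = q, keys = keys, attention = a))
}

#' Backward pass: train the self-attention head from a loss gradient
#'
#' Chains the gradient of the learner's loss with respect to the attention
#' vector through the softmax and the query/key maps, then takes one SGD
#' step. The loss gradient with respect to attention weight `k` is the sum
#' over spatial units of the input gradient times the raw feature values
#' (because the attended input is `A_k * f_ku`).
#'
#' @param sa A [self_attention()] head.
#' @param cache The `cache` from [self_attention_vector()].
#' @param features The [feature_tensor()] the attention was applied to.
#' @param input_grad Gradient of the learner's loss with respect to the
#'   attended, flattened input (as returned by [mc_update()] /
#'   [a2c_update()] with input gradients enabled).
#' @return Invisibly, the gradient with respect to the attention vector.
#' @export
self_attention_backward <- function(sa, cache, features, input_grad) {
  stopifnot(inherits(sa, "self_attention"))
  K <- sa$K
  gmat <- matrix(input_grad, nrow = K)
  dA <- rowSums(gmat * features$values)
  a <- cache$attention
  dlogits <- a * (dA - sum(dA * a))            # softmax Jacobian
  dq <- drop(cache$keys %*% dlogits) / sqrt(sa$d)
  dkeys <- outer(cache$q, dlogits) / sqrt(sa$d)  # d x K
  dWq <- tcrossprod(dq, cache$f)
  du <- drop(dkeys %*% cache$f)
  db <- rowSums(dkeys)
  sa$Wq <- sa$Wq - sa$lr * dWq
  sa$u <- sa$u - sa$lr * du
  sa$b <- sa$b - sa$lr * db
  invisible(dA)
}
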