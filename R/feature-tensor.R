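#' Feature tensors: channelwise nonnegative activations
#'
#' A `feature_tensor` holds one observation's activations over `K` feature
#' channels, each channel an `H x W` spatial grid (vector features use
#' `H = W = 1`). Internally values are stored as a `K x (H*W)` matrix;
#' per-channel means are cached because both the movement step of the
#' attention filter and the category profiles work on them.
#'
#' @param values Either a length-`K` numeric vector, a `K x M` matrix (rows
#'   are channels), or a 3-d array with dimensions `c(K, H, W)`. All values
#'   must be nonnegative and finite.
#' @param H,W Spatial grid dimensions. Inferred from `values` when it is an
#'   array; for a matrix, `H` and `W` must multiply to `ncol(values)`
#'   (default a single row, `H = 1`).
#'
#' @return An object of class `feature_tensor` with elements `values`
#'   (`K x (H*W)` matrix), `H`, `W`, and `channel_means` (length `K`).
#' @export
#' @examples
#' ft <- feature_tensor(c(2, 1, 1, 0))
#' ft$channel_means
feature_tensor <- function(values, H = NULL, W = NULL) {
  if (is.array(values) && length(dim(values)) == 3L) {
    d <- dim(values)
    H <- d[2]; W <- d[3]
    values <- matrix(values, nrow = d[1], ncol = H * W)
  } else if (is.matrix(values)) {
    if (is.null(H) && is.null(W)) { H <- 1L; W <- ncol(values) }
    if (is.null(W)) W <- ncol(values) / H
    if (is.null(H)) H <- ncol(values) / W
    if (H * W != ncol(values)) {
      stop("`H * W` must equal the number of spatial units per channel.",
           call. = FALSE)
    }
  } else if (is.numeric(values)) {
    values <- matrix(values, ncol = 1L)
    H <- 1L; W <- 1L
  } else {
    stop("`values` must be a numeric vector, matrix or 3-d array.", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values)) || any(values < 0)) {
    stop("Feature activations must be finite and nonnegative.", call. = FALSE)
  }
  structure(
    list(
      values = values,
      H = as.integer(H), W = as.integer(W),
      channel_means = rowMeans(values)
    ),
    class = "feature_tensor"
  )
}

#' @export
print.feature_tensor <- function(x, ...) {
  cat(sprintf("<feature_tensor> %d channels x (%d x %d)\n",
              nrow(x$values), x$H, x$W))
  cat("  channel means: ", paste(signif(utils::head(x$channel_means, 8), 3),
                                 collapse = ", "),
      if (length(x$channel_means) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Number of channels of a feature tensor
#' @param features A [feature_tensor()].
#' @return Integer channel count.
#' @export
n_channels <- function(features) {
  stopifnot(inherits(features, "feature_tensor"))
  nrow(features$values)
}

#' Apply a soft-attention vector to a feature tensor
#'
#' Each channel is scaled by its attention weight, the weight being
#' replicated across all spatial units of the channel so that spatial
#' structure is preserved. The result can be flattened to a single numeric
#' vector (`as.numeric()`) for a downstream value network.
#'
#' @param features A [feature_tensor()].
#' @param attention A length-`K` attention vector (nonnegative, summing to 1;
#'   see [attention_vector()]).
#' @return A matrix with the same `K x (H*W)` shape as `features$values`,
#'   with attributes `H` and `W`.
#' @export
#' @examples
#' ft <- feature_tensor(matrix(c(1, 2, 3, 4, 5, 5, 5, 5), nrow = 2, byrow = TRUE))
#' apply_attention(ft, c(1, 0))
apply_attention <- function(features, attention) {
  stopifnot(inherits(features, "feature_tensor"))
  attention <- as.numeric(attention)
  if (length(attention) != nrow(features$values)) {
    stop("Attention length must match the number of feature channels.",
         call. = FALSE)
  }
  out <- features$values * attention   # column-wise recycling over K rows
  attr(out, "H") <- features$H
  attr(out, "W") <- features$W
  out
}

#' Construct and validate an attention vector
#'
#' Attention vectors are plain numeric vectors of nonnegative weights over
#' the `K` feature channels, summing to one. `attention_vector()` normalises
#' nonnegative weights; an all-zero input maps to the uniform vector, the
#' documented degenerate fallback shared by the whole package.
#'
#' @param weights Nonnegative numeric weights of length `K`.
#' @return Numeric vector of length `K` summing to 1.
#' @export
#' @examples
#' attention_vector(c(1, 0, 1, 0))
#' attention_vector(c(0, 0, 0))  # uniform fallback
attention_vector <- function(weights) {
  weights <- as.numeric(weights)
  if (length(weights) < 1L || anyNA(weights) || any(weights < 0) ||
      any(!is.finite(weights))) {
    stop("Attention weights must be finite and nonnegative.", call. = FALSE)
  }
  s <- sum(weights)
  if (s == 0) {
    return(rep(1 / length(weights), length(weights)))
  }
  weights / s
}

#' Check the attention-vector invariants
#'
#' @param x Numeric vector.
#' @param tol Tolerance on the sum-to-one invariant.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_attention <- function(x, tol = 1e-9) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stop("Attention vector must be nonnegative.", call. = FALSE)
  }
  if (abs(sum(x) - 1) > tol) {
    stop("Attention vector must sum to one.", call. = FALSE)
  }
  invisible(TRUE)
}
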