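#' Synthetic feature-backend specification
#'
#' Describes a generator of category-signature feature tensors emulating the
#' statistics of convolutional feature maps after a pretrained network: each
#' object category has a few strongly active *discriminative* channels on
#' top of a common background level, and per-render activations are
#' gamma-distributed around the category's mean profile. Pairwise Euclidean
#' separation between category mean-profiles is controlled by
#' `signal_ratio`.
#'
#' @param K Number of feature channels (default 32; 512 gives channel-count
#'   parity with a large pretrained backbone).
#' @param H,W Spatial grid per channel (1 x 1 for vector stimuli).
#' @param n_categories Number of object categories.
#' @param n_discriminative Discriminative channels per category.
#' @param signal_ratio Mean activation of a discriminative channel relative
#'   to the background level (> 1; 1 makes categories indistinguishable).
#' @param overlap Expected fraction of a category's discriminative channels
#'   shared with other categories, in `[0, 1]` (0 draws disjoint sets).
#' @param noise_cv Coefficient of variation of per-render activations
#'   (0 renders the mean profile exactly).
#' @param background Background mean activation level.
#' @param n_agent_channels Reserved channels carrying the agent's signature
#'   in rendered scenes (outside every category's discriminative set).
#' @param seed Integer seed for profile construction.
#'
#' @return A list of class `backend_spec`.
#' @export
backend_spec <- function(K = 32L, H = 1L, W = 1L, n_categories = 3L,
                         n_discriminative = 2L, signal_ratio = 8,
                         overlap = 0, noise_cv = 0.25, background = 0.5,
                         n_agent_channels = 2L, seed = 1L) {
  if (signal_ratio < 1) stop("`signal_ratio` must be >= 1.", call. = FALSE)
  if (overlap < 0 || overlap > 1) stop("`overlap` must lie in [0, 1].", call. = FALSE)
  if (overlap == 0 &&
      n_categories * n_discriminative + n_agent_channels > K) {
    stop("Infeasible spec: disjoint discriminative sets need ",
         "n_categories * n_discriminative + n_agent_channels <= K.",
         call. = FALSE)
  }
  structure(
    list(K = as.integer(K), H = as.integer(H), W = as.integer(W),
         n_categories = as.integer(n_categories),
         n_discriminative = as.integer(n_discriminative),
         signal_ratio = as.numeric(signal_ratio),
         overlap = as.numeric(overlap), noise_cv = as.numeric(noise_cv),
         background = as.numeric(background),
         n_agent_channels = as.integer(n_agent_channels),
         seed = as.integer(seed)),
    class = "backend_spec"
  )
}

#' Build category mean-activation profiles
#'
#' Draws each category's discriminative channel set (disjoint across
#' categories when `overlap = 0`; with positive overlap, a fraction of each
#' set is drawn from previously used channels) and assigns it mean
#' activation `signal_ratio * background`; all other channels sit at the
#' background level. The last `n_agent_channels` channels are reserved for
#' the agent signature and never discriminative.
#'
#' @param spec A [backend_spec()].
#' @return A list of `category_profile` objects, each with `category`,
#'   `mean_activations` (length `K`) and `discriminative_channels`.
#' @export
#' @examples
#' profs <- make_profiles(backend_spec(K = 16, n_categories = 3, seed = 2))
#' profs[[1]]$discriminative_channels
make_profiles <- function(spec) {
  stopifnot(inherits(spec, "backend_spec"))
  rng <- local_rng(spec$seed)
  available <- seq_len(spec$K - spec$n_agent_channels)
  used <- integer(0)
  free <- available
  profiles <- vector("list", spec$n_categories)
  for (ci in seq_len(spec$n_categories)) {
    n_shared <- min(round(spec$overlap * spec$n_discriminative), length(used))
    shared <- if (n_shared > 0) rng_sample(rng, used, n_shared) else integer(0)
    n_new <- spec$n_discriminative - length(shared)
    if (n_new > length(free)) stop("Infeasible spec: not enough free channels.",
                                   call. = FALSE)
    fresh <- if (n_new > 0) rng_sample(rng, free, n_new) else integer(0)
    channels <- sort(c(shared, fresh))
    used <- union(used, channels)
    free <- setdiff(free, channels)
    means <- rep(spec$background, spec$K)
    means[channels] <- spec$signal_ratio * spec$background
    profiles[[ci]] <- structure(
      list(category = ci, mean_activations = means,
           discriminative_channels = channels),
      class = "category_profile"
    )
  }
  profiles
}

rng_sample <- function(rng, x, n) {
  if (length(x) == 1L) return(rep(x, min(n, 1L)))
  idx <- order(rng$rnorm(length(x)))[seq_len(n)]
  x[idx]
}

#' @export
print.category_profile <- function(x, ...) {
  cat(sprintf("<category_profile> category %s, discriminative channels: %s\n",
              x$category, paste(x$discriminative_channels, collapse = ", ")))
  invisible(x)
}

# gamma draws with a given mean vector and coefficient of variation;
# cv = 0 degenerates to the mean
gamma_noise <- function(means, noise_cv) {
  if (noise_cv == 0) return(means)
  shape <- 1 / noise_cv^2
  stats::rgamma(length(means), shape = shape, scale = means / shape)
}

#' Render one stimulus from a category profile
#'
#' Every spatial unit of channel `k` is drawn from a gamma distribution with
#' the profile's channel mean and coefficient of variation `noise_cv`
#' (exactly the mean profile when `noise_cv = 0`). Channel means of the
#' returned tensor are recomputed from the sample.
#'
#' @param profile A `category_profile` from [make_profiles()].
#' @param spec The [backend_spec()].
#' @return A [feature_tensor()] of shape `K x H x W`.
#' @export
render_stimulus <- function(profile, spec) {
  stopifnot(inherits(profile, "category_profile"), inherits(spec, "backend_spec"))
  M <- spec$H * spec$W
  means <- rep(profile$mean_activations, times = M)
  vals <- gamma_noise(means, spec$noise_cv)
  feature_tensor(matrix(vals, nrow = spec$K, ncol = M), H = spec$H, W = spec$W)
}

#' Render a spatial scene with objects and an agent
#'
#' Builds the mean tensor cell by cell: empty cells carry background noise
#' in every channel; a cell occupied by an object adds that identity's
#' discriminative signal in the object's channels; the agent's cell (bottom
#' row) adds the reserved agent-signature channels. Gamma noise with
#' `noise_cv` is then applied to the whole tensor.
#'
#' @param objects A list of lists with `profile` (a `category_profile`),
#'   `row`, `col` (1-based grid positions).
#' @param agent_col Agent column on the bottom row (`NULL` for no agent).
#' @param spec A [backend_spec()] with `H`, `W` > 1.
#' @return A [feature_tensor()].
#' @export
render_scene <- function(objects, agent_col, spec) {
  stopifnot(inherits(spec, "backend_spec"))
  K <- spec$K; H <- spec$H; W <- spec$W
  means <- matrix(spec$background, nrow = K, ncol = H * W)
  cell <- function(row, col) (col - 1L) * H + row
  for (ob in objects) {
    if (ob$row < 1 || ob$row > H || ob$col < 1 || ob$col > W) {
      stop("Object position outside the grid.", call. = FALSE)
    }
    ch <- ob$profile$discriminative_channels
    means[ch, cell(ob$row, ob$col)] <-
      means[ch, cell(ob$row, ob$col)] + (spec$signal_ratio - 1) * spec$background
  }
  if (!is.null(agent_col)) {
    if (agent_col < 1 || agent_col > W) stop("Agent outside the grid.", call. = FALSE)
    agent_ch <- (spec$K - spec$n_agent_channels + 1L):spec$K
    means[agent_ch, cell(H, agent_col)] <-
      means[agent_ch, cell(H, agent_col)] + (spec$signal_ratio - 1) * spec$background
  }
  vals <- gamma_noise(as.numeric(means), spec$noise_cv)
  feature_tensor(matrix(vals, nrow = K), H = H, W = W)
}

#' Pairwise Euclidean distances between category profiles
#'
#' Expresses each category's mean-activation profile as a point in
#' `K`-dimensional Euclidean space and returns all pairwise distances; the
#' mean over off-diagonal pairs summarises how separable the categories are
#' for the attention filter.
#'
#' @param profiles A list of `category_profile` objects (length >= 2).
#' @return A list with `distances` (symmetric matrix, zero diagonal) and
#'   `mean_distance` (mean over off-diagonal pairs).
#' @export
#' @examples
#' profs <- make_profiles(backend_spec(K = 16, seed = 3))
#' profile_distances(profs)$mean_distance
profile_distances <- function(profiles) {
  if (length(profiles) < 2L) stop("Need at least two profiles.", call. = FALSE)
  mat <- do.call(rbind, lapply(profiles, `[[`, "mean_activations"))
  if (any(is.na(mat))) stop("Profile length mismatch.", call. = FALSE)
  d <- as.matrix(stats::dist(mat))
  dimnames(d) <- NULL
  list(distances = d, mean_distance = mean(d[upper.tri(d)]))
}

#' Serialise category profiles to a tidy CSV
#'
#' One row per (category, channel) pair with the channel's mean activation
#' and a flag for discriminative channels.
#'
#' @param profiles List of `category_profile` objects.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(category = p$category,
               channel = seq_along(p$mean_activations),
               mean = p$mean_activations,
               discriminative = seq_along(p$mean_activations) %in%
                 p$discriminative_channels)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Adapter contract for a real pretrained CNN backend
#'
#' The synthetic backend is the testable default; a real convolutional
#' backend can be plugged in by supplying a function that maps an
#' `H x W x 3` image array to a [feature_tensor()]. This helper only checks
#' the contract; no image pipeline ships with the package.
#'
#' @param fn A function of one argument (an image array) returning a
#'   [feature_tensor()].
#' @return `fn`, classed as `cnn_adapter`.
#' @export
cnn_adapter <- function(fn) {
  stopifnot(is.function(fn))
  structure(fn, class = c("cnn_adapter", "function"))
}
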