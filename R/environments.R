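#' Multiple-choice task specification
#'
#' A changing-target multiple-choice task: on each trial one fresh stimulus
#' per category is shown in randomised screen order, choosing the current
#' target category pays +1 and anything else 0, and the target is resampled
#' uniformly at every block boundary. Train and test phases draw stimulus
#' noise from disjoint RNG substreams, the synthetic analogue of held-out
#' exemplars; the caller freezes learner weights during test.
#'
#' @param backend A [backend_spec()] (its `n_categories` is the number of
#'   on-screen choices; default 3).
#' @param block_length Trials per block (target fixed within a block).
#' @param train_blocks,test_blocks Number of blocks per phase.
#' @param reward_target,reward_other Rewards for target / non-target picks.
#' @param force_change If `TRUE` the resampled target always differs from
#'   the previous one; default `FALSE` (uniform, may repeat).
#' @param seed Integer seed; drives target scheduling, screen order and the
#'   per-phase stimulus streams.
#' @return A list of class `mc_task_spec`.
#' @export
mc_task_spec <- function(backend = backend_spec(), block_length = 50L,
                         train_blocks = 200L, test_blocks = 10L,
                         reward_target = 1, reward_other = 0,
                         force_change = FALSE, seed = 1L) {
  stopifnot(inherits(backend, "backend_spec"))
  structure(
    list(backend = backend, n_choices = backend$n_categories,
         block_length = as.integer(block_length),
         train_blocks = as.integer(train_blocks),
         test_blocks = as.integer(test_blocks),
         reward_target = reward_target, reward_other = reward_other,
         force_change = isTRUE(force_change), seed = as.integer(seed)),
    class = "mc_task_spec"
  )
}

#' Reset the multiple-choice task
#'
#' @param spec An [mc_task_spec()].
#' @param phase `"train"` or `"test"`; phases share category profiles and
#'   target schedule logic but use disjoint stimulus-noise substreams.
#' @return An environment of class `mc_env`; advance it with
#'   [mc_observe()] / [mc_step()].
#' @export
mc_reset <- function(spec, phase = c("train", "test")) {
  stopifnot(inherits(spec, "mc_task_spec"))
  phase <- match.arg(phase)
  e <- new.env(parent = emptyenv())
  e$spec <- spec
  e$phase <- phase
  e$profiles <- make_profiles(spec$backend)
  e$task_rng <- rng_stream(derive_seed(spec$seed, paste0("task-", phase)))
  e$stim_rng <- rng_stream(derive_seed(spec$seed, paste0("stim-", phase)))
  e$trial <- 0L
  e$block <- 0L
  e$target <- with_stream(e$task_rng, sample.int(spec$n_choices, 1L))
  e$prev_target <- NA_integer_
  e$pending <- NULL
  class(e) <- "mc_env"
  e
}

#' Observe the current multiple-choice trial
#'
#' Renders one fresh stimulus per category and shuffles screen order.
#' Category labels in the returned metadata exist for logging and for the
#' ideal-observer baseline only; feature-based agents must not read them.
#'
#' @param env An `mc_env` from [mc_reset()].
#' @return A list with `stimuli` (list of [feature_tensor()] in screen
#'   order), `categories` (their category ids), `trial`, `block`, and
#'   `prev_target` (the rewarded category of the previous trial,
#'   `NA` on the first trial; ideal-observer use only).
#' @export
mc_observe <- function(env) {
  stopifnot(inherits(env, "mc_env"))
  if (!is.null(env$pending)) return(env$pending)
  spec <- env$spec
  order <- with_stream(env$task_rng, sample.int(spec$n_choices))
  stimuli <- with_stream(env$stim_rng, lapply(order, function(ci) {
    render_stimulus(env$profiles[[ci]], spec$backend)
  }))
  env$pending <- list(stimuli = stimuli, categories = order,
                      trial = env$trial + 1L, block = env$block,
                      prev_target = env$prev_target)
  env$pending
}

#' Act on the current multiple-choice trial
#'
#' @param env An `mc_env`.
#' @param choice 1-based index into the on-screen stimuli.
#' @return A list with `reward`, `target` (the rewarded category this
#'   trial), `block`, `trial`, and `switched` (`TRUE` if the *next* trial
#'   starts a new block, at which point the target is resampled).
#' @export
mc_step <- function(env, choice) {
  stopifnot(inherits(env, "mc_env"))
  obs <- mc_observe(env)
  if (!is.numeric(choice) || length(choice) != 1L || choice < 1 ||
      choice > env$spec$n_choices) {
    stop("Invalid choice index.", call. = FALSE)
  }
  spec <- env$spec
  chosen_cat <- obs$categories[[choice]]
  reward <- if (chosen_cat == env$target) spec$reward_target else spec$reward_other
  out <- list(reward = reward, target = env$target,
              block = env$block, trial = env$trial + 1L)
  env$prev_target <- env$target
  env$trial <- env$trial + 1L
  env$pending <- NULL
  switched <- FALSE
  if (env$trial %% spec$block_length == 0L) {
    env$block <- env$block + 1L
    new_target <- with_stream(env$task_rng, {
      if (spec$force_change && spec$n_choices > 1L) {
        cand <- setdiff(seq_len(spec$n_choices), env$target)
        cand[sample.int(length(cand), 1L)]
      } else {
        sample.int(spec$n_choices, 1L)
      }
    })
    switched <- new_target != env$target
    env$target <- new_target
  }
  out$switched <- switched
  out
}

#' Object-collection game specification
#'
#' A gridworld game: objects spawn at the top of an `H x W` grid at regular
#' intervals, fall one row per step, and are caught when they reach the
#' bottom row in the agent's column. Catching an object pays +1 if its
#' identity is currently rewarded, else 0. At `revaluation_episode` either
#' the rewarded identity switches (`reward_revaluation`) or the set of
#' identities present switches (`state_revaluation`, all identities
#' rewarded). Defaults are the desk-scale configuration; the full-scale
#' game (2000 episodes) is reached by raising `n_episodes` and
#' `revaluation_episode`.
#'
#' @param backend A [backend_spec()] with spatial dimensions `H`, `W` equal
#'   to the grid and `n_categories >= n_identities`.
#' @param n_identities Number of object identities (shape/colour pairs).
#' @param spawn_interval Steps between spawns.
#' @param fall_rate Rows fallen per step.
#' @param episode_length Steps per episode.
#' @param n_episodes Total episodes.
#' @param revaluation_episode Episode index (1-based) at whose start the
#'   switch happens; must be < `n_episodes`.
#' @param mode `"reward_revaluation"` or `"state_revaluation"`.
#' @param seed Integer seed for spawn scheduling and scene noise.
#' @return A list of class `oc_task_spec`.
#' @export
oc_task_spec <- function(backend = backend_spec(K = 16L, H = 12L, W = 12L,
                                                n_categories = 2L),
                         n_identities = 2L, spawn_interval = 6L,
                         fall_rate = 1L, episode_length = 100L,
                         n_episodes = 400L, revaluation_episode = 200L,
                         mode = c("reward_revaluation", "state_revaluation"),
                         seed = 1L) {
  stopifnot(inherits(backend, "backend_spec"))
  mode <- match.arg(mode)
  if (revaluation_episode >= n_episodes) {
    stop("`revaluation_episode` must be smaller than `n_episodes`.",
         call. = FALSE)
  }
  if (backend$n_categories < n_identities) {
    stop("Backend must define at least `n_identities` categories.",
         call. = FALSE)
  }
  structure(
    list(backend = backend, n_identities = as.integer(n_identities),
         spawn_interval = as.integer(spawn_interval),
         fall_rate = as.integer(fall_rate),
         episode_length = as.integer(episode_length),
         n_episodes = as.integer(n_episodes),
         revaluation_episode = as.integer(revaluation_episode),
         mode = mode, seed = as.integer(seed)),
    class = "oc_task_spec"
  )
}

#' Reset the object-collection game
#'
#' @param spec An [oc_task_spec()].
#' @return An environment of class `oc_env`. Start each episode with
#'   [oc_episode_reset()] and advance with [oc_step()].
#' @export
oc_reset <- function(spec) {
  stopifnot(inherits(spec, "oc_task_spec"))
  e <- new.env(parent = emptyenv())
  e$spec <- spec
  e$profiles <- make_profiles(spec$backend)
  e$task_rng <- rng_stream(derive_seed(spec$seed, "oc-task"))
  e$stim_rng <- rng_stream(derive_seed(spec$seed, "oc-stim"))
  e$episode <- 0L
  # phase-1 identity bookkeeping
  ids <- seq_len(spec$n_identities)
  if (spec$mode == "reward_revaluation") {
    e$active <- ids
    e$rewarded <- with_stream(e$task_rng, ids[sample.int(length(ids), 1L)])
  } else {
    e$active <- ids[1L]
    e$rewarded <- ids  # every active identity pays in state mode
  }
  class(e) <- "oc_env"
  e
}

#' Begin a new episode of the object-collection game
#'
#' Clears the board, recentres the agent, and applies the revaluation
#' switch when the incoming episode is `revaluation_episode + 1`.
#'
#' @param env An `oc_env`.
#' @return The first observation, a [feature_tensor()] of the empty scene.
#' @export
oc_episode_reset <- function(env) {
  stopifnot(inherits(env, "oc_env"))
  spec <- env$spec
  env$episode <- env$episode + 1L
  if (env$episode == spec$revaluation_episode + 1L) {
    ids <- seq_len(spec$n_identities)
    if (spec$mode == "reward_revaluation") {
      cand <- setdiff(ids, env$rewarded)
      env$rewarded <- with_stream(env$task_rng,
                                  cand[sample.int(length(cand), 1L)])
    } else {
      old <- env$active
      cand <- setdiff(ids, old)
      env$active <- with_stream(env$task_rng,
                                cand[sample.int(length(cand), 1L)])
      env$rewarded <- ids
    }
  }
  env$step_in_episode <- 0L
  env$agent_col <- as.integer(ceiling(spec$backend$W / 2))
  env$objects <- list()
  oc_render(env)
}

oc_render <- function(env) {
  with_stream(env$stim_rng,
              render_scene(env$objects, env$agent_col, env$spec$backend))
}

#' Advance the object-collection game one step
#'
#' Moves the agent one column left or right (clamped), drops every object
#' `fall_rate` rows, scores catches at the bottom row, removes landed
#' objects, and spawns a fresh object of a random active identity at a
#' random column every `spawn_interval` steps.
#'
#' @param env An `oc_env`.
#' @param action 1 = left, 2 = right.
#' @return A list with `reward`, `observation` (a [feature_tensor()]),
#'   `done` (episode finished), and `info` (caught identities, episode,
#'   step).
#' @export
oc_step <- function(env, action) {
  stopifnot(inherits(env, "oc_env"))
  if (!action %in% c(1L, 2L)) stop("Invalid action.", call. = FALSE)
  spec <- env$spec
  W <- spec$backend$W; H <- spec$backend$H
  env$agent_col <- max(1L, min(W, env$agent_col + ifelse(action == 1L, -1L, 1L)))
  reward <- 0
  caught <- integer(0)
  keep <- list()
  for (ob in env$objects) {
    ob$row <- ob$row + spec$fall_rate
    if (ob$row >= H) {
      if (ob$col == env$agent_col) {
        caught <- c(caught, ob$identity)
        if (ob$identity %in% env$rewarded) reward <- reward + 1
      }
    } else {
      keep[[length(keep) + 1L]] <- ob
    }
  }
  env$objects <- keep
  env$step_in_episode <- env$step_in_episode + 1L
  if (env$step_in_episode %% spec$spawn_interval == 0L) {
    sp <- with_stream(env$task_rng, {
      list(identity = env$active[sample.int(length(env$active), 1L)],
           col = sample.int(W, 1L))
    })
    env$objects[[length(env$objects) + 1L]] <-
      list(identity = sp$identity, profile = env$profiles[[sp$identity]],
           row = 1L, col = sp$col)
  }
  done <- env$step_in_episode >= spec$episode_length
  list(reward = reward, observation = oc_render(env), done = done,
       info = list(caught = caught, episode = env$episode,
                   step = env$step_in_episode, rewarded = env$rewarded))
}

#' Check that every spawn column is catchable
#'
#' Breadth-first reachability over (column, step) states: from any starting
#' agent column, can the agent reach every column before an object spawned
#' now lands? Guarantees the reward ceiling of the game is positive.
#'
#' @param spec An [oc_task_spec()].
#' @return `TRUE` if every column is reachable from every start within the
#'   object fall time, else `FALSE`.
#' @export
oc_catchable <- function(spec) {
  stopifnot(inherits(spec, "oc_task_spec"))
  W <- spec$backend$W; H <- spec$backend$H
  steps <- floor((H - 1) / spec$fall_rate)  # steps before a fresh spawn lands
  for (start in seq_len(W)) {
    reached <- rep(FALSE, W)
    frontier <- start
    reached[start] <- TRUE
    for (s in seq_len(steps)) {
      nxt <- unique(unlist(lapply(frontier, function(cl) {
        c(max(1L, cl - 1L), min(W, cl + 1L))
      })))
      nxt <- nxt[!reached[nxt]]
      if (length(nxt) == 0L) break
      reached[nxt] <- TRUE
      frontier <- nxt
    }
    if (!all(reached)) return(FALSE)
  }
  TRUE
}

#' Channels discriminative for the currently rewarded identities
#'
#' Convenience accessor used for logging attention mass on target channels.
#'
#' @param env An `mc_env` or `oc_env`.
#' @return Integer vector of channel indices.
#' @export
target_channels <- function(env) {
  if (inherits(env, "mc_env")) {
    env$profiles[[env$target]]$discriminative_channels
  } else if (inherits(env, "oc_env")) {
    ids <- intersect(env$rewarded, env$active)
    sort(unique(unlist(lapply(ids, function(i) {
      env$profiles[[i]]$discriminative_channels
    }))))
  } else {
    stop("Unknown environment.", call. = FALSE)
  }
}
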