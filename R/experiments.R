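#' Attention-trace summaries
#'
#' `attention_entropy()` is the Shannon entropy of an attention vector in
#' nats (`0 log 0 = 0`); `attention_mass()` is the total weight on a set of
#' channels, the quantity tracked to ask whether the filter has found the
#' rewarded category's discriminative channels.
#'
#' @param attention Length-`K` attention vector.
#' @param channels Integer channel indices.
#' @return A scalar.
#' @export
attention_entropy <- function(attention) {
  a <- attention[attention > 0]
  -sum(a * log(a))
}

#' @rdname attention_entropy
#' @export
attention_mass <- function(attention, channels) {
  sum(attention[channels])
}

#' Oracle value function for a multiple-choice environment
#'
#' A reward-perfect value function used to study the attention filter in
#' isolation from value learning: it returns the attention mass on the
#' current target category's discriminative channels, but only when those
#' channels are actually active in the presented stimulus (above the
#' midpoint between background and signal levels). Under it, a particle
#' attending exactly the rewarded channels predicts the reward of a target
#' stimulus perfectly.
#'
#' @param env An `mc_env`; the oracle tracks its live target.
#' @return A function `(features, attention) -> value`.
#' @export
mc_oracle_value_fn <- function(env) {
  stopifnot(inherits(env, "mc_env"))
  be <- env$spec$backend
  threshold <- be$background * (1 + be$signal_ratio) / 2
  function(features, attention) {
    ch <- env$profiles[[env$target]]$discriminative_channels
    active <- features$channel_means[ch] > threshold
    sum(attention[ch] * active)
  }
}

new_run <- function(trials, attention, manifest, subclass) {
  structure(list(trials = trials, attention = attention, manifest = manifest),
            class = c(subclass, "spa_run"))
}

#' @export
print.spa_run <- function(x, ...) {
  cat(sprintf("<%s> %d conditions x %d seeds, %d logged rows\n",
              class(x)[1],
              length(unique(x$trials$condition)),
              length(unique(x$trials$seed)),
              nrow(x$trials)))
  print(glance(x))
  invisible(x)
}

#' Run the multiple-choice experiment
#'
#' The full training/test protocol: a train phase with value-network updates
#' enabled, then a test phase on held-out stimulus streams with network
#' weights frozen, during which only the particle filter (or the
#' self-attention head's forward pass) can adapt. Each (condition, seed)
#' pair is an independent, fully seeded run.
#'
#' @param task An [mc_task_spec()]. The backend (category layout) is shared
#'   across seeds; stimulus and scheduling streams vary per seed.
#' @param conditions Character vector from `"spa"`, `"all"`, `"random"`,
#'   `"ideal"`, `"self_attention"`.
#' @param seeds Integer seeds (default `1:5`).
#' @param spa An [spa_config()]; default [spa_config_mc()] for the task's
#'   channel count (the per-run seed is derived from each run's seed).
#' @param learner A [value_config()] with variant `"monte_carlo"`.
#' @param value `"learned"` (the value network) or `"oracle"`
#'   ([mc_oracle_value_fn()]; isolates the filter from value learning).
#' @param sa_d,sa_lr Self-attention head dimensionality and learning rate.
#' @param snapshot_every Record the full attention vector every this many
#'   trials (`Inf` to disable).
#' @return An object of class `spa_mc_run`: tibbles `trials` and
#'   `attention` plus the run manifest. Use [tidy()], [glance()],
#'   [autoplot()], [summarize_runs()].
#' @export
run_mc <- function(task = mc_task_spec(), conditions = "spa", seeds = 1:5,
                   spa = NULL, learner = value_config("monte_carlo"),
                   value = c("learned", "oracle"),
                   sa_d = 128L, sa_lr = 0.01, snapshot_every = Inf) {
  stopifnot(inherits(task, "mc_task_spec"))
  value <- match.arg(value)
  conditions <- match.arg(conditions,
                          c("spa", "all", "random", "ideal", "self_attention"),
                          several.ok = TRUE)
  K <- task$backend$K
  rows <- list(); snaps <- list()
  for (condition in conditions) {
    for (seed in seeds) {
      res <- run_mc_single(task, condition, seed, spa, learner, value,
                           sa_d, sa_lr, snapshot_every)
      rows[[length(rows) + 1L]] <- res$trials
      snaps[[length(snaps) + 1L]] <- res$attention
    }
  }
  manifest <- list(experiment = "multiple_choice", task = task,
                   conditions = conditions, seeds = seeds, value = value,
                   learner = learner, K = K)
  new_run(dplyr::bind_rows(rows), dplyr::bind_rows(snaps), manifest,
          "spa_mc_run")
}

run_mc_single <- function(task, condition, seed, spa_cfg, lcfg, value,
                          sa_d, sa_lr, snapshot_every) {
  K <- task$backend$K
  set.seed(derive_seed(seed, paste0("mc-", condition)))
  task2 <- task
  task2$seed <- derive_seed(seed, "mc-env")
  if (is.null(spa_cfg)) spa_cfg <- spa_config_mc(K)
  spa_cfg$seed <- derive_seed(seed, "spa")
  lrn <- if (condition != "ideal") {
    value_learner(K, lcfg, H = task$backend$H, W = task$backend$W,
                  seed = derive_seed(seed, "learner"))
  }
  ens <- if (condition == "spa") init_ensemble(spa_cfg, set_seed = FALSE)
  frozen_random <- if (condition == "random") {
    random_attention(K, derive_seed(seed, "random-attn"))
  }
  sa <- if (condition == "self_attention") {
    self_attention(K, d = sa_d, lr = sa_lr,
                   seed = derive_seed(seed, "self-attn"))
  }
  attn <- switch(condition,
                 spa = ensemble_attention(ens),
                 random = frozen_random,
                 all_attention(K))
  rows <- vector("list", 0L); snaps <- vector("list", 0L)
  for (phase in c("train", "test")) {
    env <- mc_reset(task2, phase)
    vfn <- if (condition == "spa") {
      if (value == "oracle") mc_oracle_value_fn(env) else value_fn(lrn)
    }
    n_blocks <- if (phase == "train") task$train_blocks else task$test_blocks
    n_trials <- n_blocks * task$block_length
    phase_rows <- vector("list", n_trials)
    for (t in seq_len(n_trials)) {
      obs <- mc_observe(env)
      caches <- NULL
      if (condition == "ideal") {
        choice <- ideal_observer_choice(obs$categories, obs$prev_target,
                                        lcfg$epsilon)
      } else {
        if (condition == "self_attention") {
          caches <- lapply(obs$stimuli, function(s) self_attention_vector(sa, s))
          vals <- vapply(seq_along(obs$stimuli), function(j) {
            evaluate_value(lrn, obs$stimuli[[j]], caches[[j]]$attention)
          }, numeric(1))
        } else {
          vals <- vapply(obs$stimuli, function(s) {
            evaluate_value(lrn, s, attn)
          }, numeric(1))
        }
        choice <- select_action_egreedy(vals, lcfg$epsilon)
      }
      out <- mc_step(env, choice)
      chosen <- obs$stimuli[[choice]]
      chosen_attn <- if (condition == "self_attention") {
        caches[[choice]]$attention
      } else {
        attn
      }
      if (phase == "train" && condition %in% c("all", "random", "spa")) {
        mc_update(lrn, chosen, chosen_attn, out$reward)
      } else if (phase == "train" && condition == "self_attention") {
        upd <- mc_update(lrn, chosen, chosen_attn, out$reward,
                         return_input_grad = TRUE)
        self_attention_backward(sa, caches[[choice]]$cache, chosen,
                                upd$input_grad)
      }
      if (condition == "spa" && (t %% spa_cfg$c_max == 0L)) {
        res <- update_attention(ens, chosen,
                                return_observation(chosen, out$reward),
                                vfn, spa_cfg)
        ens <- res$ensemble
        attn <- res$attention
      }
      tc <- env$profiles[[out$target]]$discriminative_channels
      phase_rows[[t]] <- list(
        condition = condition, seed = seed, phase = phase,
        block = out$block, trial = out$trial, reward = out$reward,
        target = out$target,
        attention_entropy = if (condition == "ideal") NA_real_ else
          attention_entropy(chosen_attn),
        attention_mass_on_target = if (condition == "ideal") NA_real_ else
          attention_mass(chosen_attn, tc)
      )
      if (is.finite(snapshot_every) && condition != "ideal" &&
          t %% snapshot_every == 0L) {
        snaps[[length(snaps) + 1L]] <- tibble::tibble(
          condition = condition, seed = seed, phase = phase, trial = t,
          channel = seq_len(K), weight = as.numeric(chosen_attn)
        )
      }
    }
    rows[[length(rows) + 1L]] <- dplyr::bind_rows(phase_rows)
  }
  list(trials = dplyr::bind_rows(rows), attention = dplyr::bind_rows(snaps))
}

#' Run the object-collection experiment
#'
#' Trains an advantage actor-critic agent on the object-collection game with
#' the configured revaluation at the midpoint, under one of the attention
#' conditions. Attention updates (SPA condition) happen every `c_max`
#' environment steps, scoring the most recently completed `t_max`-step
#' return window; the learner updates on every completed `t_max`-step
#' trajectory segment.
#'
#' @param task An [oc_task_spec()].
#' @param conditions Character vector from `"spa"`, `"all"`, `"random"`,
#'   `"self_attention"`.
#' @param seeds Integer seeds (default `1:5`).
#' @param spa An [spa_config()]; default [spa_config_oc()] for the task's
#'   channel count.
#' @param learner A [value_config()] with variant `"a2c"`.
#' @param sa_d,sa_lr Self-attention head dimensionality and learning rate.
#' @param obs_buffer Number of recent completed return windows whose errors
#'   are averaged at each attention update (default 25). `1` scores only
#'   the single most recent window; with the game's sparse rewards a buffer
#'   is needed for a usable top-down signal.
#' @return An object of class `spa_oc_run` with tibbles `trials` (one row
#'   per episode) and `attention` (per-episode snapshots of summary
#'   statistics are in `trials`; full vectors at revaluation boundaries).
#' @export
run_oc <- function(task = oc_task_spec(), conditions = "spa", seeds = 1:5,
                   spa = NULL, learner = value_config("a2c"),
                   sa_d = 128L, sa_lr = 0.01, obs_buffer = 25L) {
  stopifnot(inherits(task, "oc_task_spec"))
  conditions <- match.arg(conditions,
                          c("spa", "all", "random", "self_attention"),
                          several.ok = TRUE)
  rows <- list(); snaps <- list()
  for (condition in conditions) {
    for (seed in seeds) {
      res <- run_oc_single(task, condition, seed, spa, learner, sa_d, sa_lr,
                           obs_buffer)
      rows[[length(rows) + 1L]] <- res$trials
      snaps[[length(snaps) + 1L]] <- res$attention
    }
  }
  manifest <- list(experiment = "object_collection", task = task,
                   conditions = conditions, seeds = seeds, learner = learner,
                   K = task$backend$K)
  new_run(dplyr::bind_rows(rows), dplyr::bind_rows(snaps), manifest,
          "spa_oc_run")
}

run_oc_single <- function(task, condition, seed, spa_cfg, lcfg, sa_d, sa_lr,
                          obs_buffer = 25L) {
  K <- task$backend$K
  set.seed(derive_seed(seed, paste0("oc-", condition)))
  task2 <- task
  task2$seed <- derive_seed(seed, "oc-env")
  if (is.null(spa_cfg)) spa_cfg <- spa_config_oc(K)
  spa_cfg$seed <- derive_seed(seed, "spa")
  env <- oc_reset(task2)
  lrn <- value_learner(K, lcfg, H = task$backend$H, W = task$backend$W,
                       n_actions = 2L, seed = derive_seed(seed, "learner"))
  ens <- if (condition == "spa") init_ensemble(spa_cfg, set_seed = FALSE)
  sa <- if (condition == "self_attention") {
    self_attention(K, d = sa_d, lr = sa_lr,
                   seed = derive_seed(seed, "self-attn"))
  }
  attn <- switch(condition,
                 spa = ensemble_attention(ens),
                 random = random_attention(K, derive_seed(seed, "random-attn")),
                 all_attention(K))
  vfn <- value_fn(lrn)
  m <- max(1L, lcfg$frame_skip)
  env_steps <- 0L
  cur_win <- NULL    # return window being accumulated (decision granularity)
  win_buf <- list()  # completed windows scored at attention updates
  rewards_log <- numeric(task$n_episodes)
  ep_rows <- vector("list", task$n_episodes)
  snaps <- list()
  for (ep in seq_len(task$n_episodes)) {
    obs <- oc_episode_reset(env)
    done <- FALSE
    ep_reward <- 0
    traj <- list()
    traj_attn <- list()
    while (!done) {
      cur_attn <- if (condition == "self_attention") {
        sa_fw <- self_attention_vector(sa, obs)
        sa_fw$attention
      } else {
        attn
      }
      act <- a2c_act(lrn, obs, cur_attn)
      if (is.null(cur_win)) cur_win <- list(start = obs, rewards = numeric(0))
      r_acc <- 0
      for (tick in seq_len(m)) {
        st <- oc_step(env, act$action)
        r_acc <- r_acc + st$reward
        env_steps <- env_steps + 1L
        done <- st$done
        # attention update on the c_max schedule (environment steps); errors
        # averaged over the buffered completed return windows
        if (condition == "spa" && env_steps %% spa_cfg$c_max == 0L &&
            length(win_buf) >= 1L) {
          obs_list <- lapply(win_buf, function(w) {
            boot <- if (is.null(w$end)) NULL else {
              evaluate_value(lrn, w$end, attn)
            }
            rt <- compute_nstep_return(w$rewards, boot, lcfg$gamma,
                                       spa_cfg$t_max)
            return_observation(w$start, rt$return_value)
          })
          res <- update_attention(ens, st$observation, obs_list, vfn, spa_cfg)
          ens <- res$ensemble
          attn <- res$attention
        }
        if (done) break
      }
      ep_reward <- ep_reward + r_acc
      tr <- list(features = obs, action = act$action, reward = r_acc,
                 next_features = if (done) NULL else st$observation)
      traj[[length(traj) + 1L]] <- tr
      traj_attn[[length(traj_attn) + 1L]] <- if (condition == "self_attention")
        list(cache = sa_fw$cache, features = obs, attention = cur_attn)
      cur_win$rewards <- c(cur_win$rewards, r_acc)
      if (length(cur_win$rewards) >= spa_cfg$t_max || done) {
        cur_win$end <- if (done) NULL else st$observation
        win_buf[[length(win_buf) + 1L]] <- cur_win
        if (length(win_buf) > obs_buffer) win_buf <- win_buf[-1L]
        cur_win <- NULL
      }
      if (length(traj) >= lcfg$t_max_segment %||% spa_cfg$t_max || done) {
        if (condition == "self_attention") {
          upd <- a2c_update(lrn, traj,
                            lapply(traj_attn, `[[`, "attention"),
                            return_input_grads = TRUE)
          for (i in seq_along(traj)) {
            self_attention_backward(sa, traj_attn[[i]]$cache,
                                    traj_attn[[i]]$features,
                                    upd$input_grads[[i]])
          }
        } else {
          a2c_update(lrn, traj, attn)
        }
        traj <- list(); traj_attn <- list()
      }
      obs <- st$observation
    }
    rewards_log[ep] <- ep_reward
    lo <- max(1L, ep - 19L)
    tc <- target_channels(env)
    ep_rows[[ep]] <- list(
      condition = condition, seed = seed,
      phase = if (ep <= task$revaluation_episode) "pre" else "post",
      episode = ep, reward = ep_reward,
      rolling_reward_20 = mean(rewards_log[lo:ep]),
      attention_entropy = attention_entropy(attn),
      attention_mass_on_target = attention_mass(attn, tc)
    )
    if (ep %in% c(task$revaluation_episode, task$n_episodes)) {
      snaps[[length(snaps) + 1L]] <- tibble::tibble(
        condition = condition, seed = seed, episode = ep,
        channel = seq_len(K), weight = as.numeric(attn)
      )
    }
  }
  list(trials = dplyr::bind_rows(ep_rows), attention = dplyr::bind_rows(snaps))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Summarise runs across seeds and conditions
#'
#' Aggregates per-trial (multiple choice) or per-episode (object collection)
#' rewards into bins, reporting mean and standard deviation across seeds,
#' plus the switch-recovery latency: how many trials/episodes after the
#' revaluation (or after each target switch) until the 20-unit rolling
#' reward regains 90% of its pre-switch level.
#'
#' @param x An `spa_run` object, a tibble shaped like its `trials`, or a
#'   character vector of CSV paths written by [write_run_csv()].
#' @param bin_width Number of trials/episodes per bin (default one block for
#'   MC runs, 20 for OC runs).
#' @return A list with tibbles `by_bin` (condition, phase, bin, mean, sd)
#'   and `recovery` (condition, seed, latency).
#' @export
summarize_runs <- function(x, bin_width = NULL) {
  trials <- gather_trials(x)
  is_mc <- "trial" %in% names(trials)
  idx_col <- if (is_mc) "trial" else "episode"
  if (is.null(bin_width)) bin_width <- if (is_mc) 50L else 20L
  by_bin <- trials |>
    dplyr::mutate(bin = (.data[[idx_col]] - 1L) %/% bin_width + 1L) |>
    dplyr::group_by(.data$condition, .data$phase, .data$bin, .data$seed) |>
    dplyr::summarise(seed_mean = mean(.data$reward), .groups = "drop") |>
    dplyr::group_by(.data$condition, .data$phase, .data$bin) |>
    dplyr::summarise(mean_reward = mean(.data$seed_mean),
                     sd_reward = stats::sd(.data$seed_mean),
                     n_seeds = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(sd_reward = tidyr::replace_na(.data$sd_reward, 0))
  recovery <- trials |>
    dplyr::group_by(.data$condition, .data$seed) |>
    dplyr::group_modify(~ tibble::tibble(
      latency = recovery_latency(.x$reward,
                                 switch_at = attr(trials, "switch_at") %||%
                                   default_switch_at(.x, is_mc))
    )) |>
    dplyr::ungroup()
  list(by_bin = by_bin, recovery = recovery)
}

default_switch_at <- function(df, is_mc) {
  if (is_mc) return(NA_integer_)
  if (!"phase" %in% names(df)) return(NA_integer_)
  n_pre <- sum(df$phase == "pre")
  if (n_pre == 0L || n_pre == nrow(df)) NA_integer_ else n_pre
}

#' Recovery latency after an unannounced switch
#'
#' Number of trials/episodes after `switch_at` until the trailing mean
#' reward (window 20) first regains 90% of its level on the 20 units before
#' the switch. `0` when performance never drops below that level;
#' `NA` when it never recovers within the log.
#'
#' @param rewards Numeric reward series.
#' @param switch_at Index of the last pre-switch unit.
#' @param window Rolling window size.
#' @param frac Fraction of the pre-switch level to regain.
#' @return Integer latency (or `NA`).
#' @export
recovery_latency <- function(rewards, switch_at, window = 20L, frac = 0.9) {
  if (is.na(switch_at) || switch_at < 1L || switch_at >= length(rewards)) {
    return(NA_integer_)
  }
  pre <- mean(rewards[max(1L, switch_at - window + 1L):switch_at])
  target <- frac * pre
  post <- rewards[(switch_at + 1L):length(rewards)]
  for (i in seq_along(post)) {
    trailing <- post[max(1L, i - window + 1L):i]
    if (mean(trailing) >= target) return(i - 1L)
  }
  NA_integer_
}

gather_trials <- function(x) {
  if (inherits(x, "spa_run")) return(x$trials)
  if (is.character(x)) {
    return(dplyr::bind_rows(lapply(x, function(p) {
      tibble::as_tibble(utils::read.csv(p))
    })))
  }
  tibble::as_tibble(x)
}

#' Write run logs to CSV
#'
#' The per-trial/per-episode log is the single source of truth for
#' analysis; plots and summaries derive from it.
#'
#' @param run An `spa_run`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_run_csv <- function(run, path) {
  stopifnot(inherits(run, "spa_run"))
  utils::write.csv(run$trials, path, row.names = FALSE)
  invisible(path)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a run into its per-trial/per-episode tibble
#'
#' @param x An `spa_run`.
#' @param ... Unused.
#' @return A tibble, one row per trial (MC) or episode (OC).
#' @export
tidy.spa_run <- function(x, ...) {
  tibble::as_tibble(x$trials)
}

#' One-row-per-condition summary of a run
#'
#' For multiple-choice runs: mean train and test reward. For
#' object-collection runs: mean rolling reward in the final pre-revaluation
#' and final overall bins.
#'
#' @param x An `spa_run`.
#' @param ... Unused.
#' @return A tibble with one row per condition.
#' @export
glance.spa_run <- function(x, ...) {
  tr <- x$trials
  if (inherits(x, "spa_mc_run")) {
    tr |>
      dplyr::group_by(.data$condition) |>
      dplyr::summarise(
        train_reward = mean(.data$reward[.data$phase == "train"]),
        test_reward = mean(.data$reward[.data$phase == "test"]),
        n_seeds = length(unique(.data$seed)), .groups = "drop"
      )
  } else {
    final_ep <- max(tr$episode)
    reval <- x$manifest$task$revaluation_episode
    tr |>
      dplyr::group_by(.data$condition) |>
      dplyr::summarise(
        pre_revaluation_reward = mean(
          .data$rolling_reward_20[.data$episode == reval]),
        final_reward = mean(.data$rolling_reward_20[.data$episode == final_ep]),
        n_seeds = length(unique(.data$seed)), .groups = "drop"
      )
  }
}

#' Plot reward trajectories by condition
#'
#' Mean reward per bin with a one-standard-deviation ribbon across seeds,
#' one colour per condition; the multiple-choice plot facets train/test
#' phases, the object-collection plot marks the revaluation episode.
#'
#' @param object An `spa_run`.
#' @param bin_width Bin width in trials/episodes.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spa_run <- function(object, bin_width = NULL, ...) {
  s <- summarize_runs(object, bin_width = bin_width)$by_bin
  p <- ggplot2::ggplot(
    s, ggplot2::aes(x = .data$bin, y = .data$mean_reward,
                    colour = .data$condition, fill = .data$condition)
  ) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_reward - .data$sd_reward,
                                      ymax = .data$mean_reward + .data$sd_reward),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "bin", y = "mean reward", colour = "condition",
                  fill = "condition") +
    ggplot2::theme_minimal()
  if (inherits(object, "spa_mc_run")) {
    p <- p + ggplot2::facet_wrap(~phase, scales = "free_x")
  } else {
    reval <- object$manifest$task$revaluation_episode
    bw <- if (is.null(bin_width)) 20L else bin_width
    p <- p + ggplot2::geom_vline(xintercept = reval / bw, linetype = "dashed")
  }
  p
}

#' Plot an attention snapshot
#'
#' Channel-weight bars for the stored attention snapshots, faceted by
#' condition and seed.
#'
#' @param run An `spa_run` with a non-empty `attention` tibble.
#' @return A ggplot object.
#' @export
plot_attention <- function(run) {
  stopifnot(inherits(run, "spa_run"))
  if (nrow(run$attention) == 0L) stop("No attention snapshots stored.",
                                      call. = FALSE)
  snap_col <- if ("trial" %in% names(run$attention)) "trial" else "episode"
  ggplot2::ggplot(run$attention,
                  ggplot2::aes(x = .data$channel, y = .data$weight,
                               fill = factor(.data[[snap_col]]))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(condition ~ seed) +
    ggplot2::labs(fill = snap_col) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
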