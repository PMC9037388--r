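# Benchmark environments: block and revaluation scheduling, reward rules,
# stream separation, catchability, and the ideal-observer ceiling.

test_that("multiple-choice resets are reproducible and phase streams differ", {
  task <- tiny_mc_task()
  e1 <- mc_reset(task, "train")
  e2 <- mc_reset(task, "train")
  expect_identical(e1$target, e2$target)
  o1 <- mc_observe(e1); o2 <- mc_observe(e2)
  expect_identical(o1$categories, o2$categories)
  expect_identical(o1$stimuli[[1]]$values, o2$stimuli[[1]]$values)

  # held-out test stream: same seed, disjoint stimulus noise
  et <- mc_reset(task, "test")
  ot <- mc_observe(et)
  expect_false(isTRUE(all.equal(o1$stimuli[[1]]$values, ot$stimuli[[1]]$values)))

  expect_identical(task$n_choices, 3L)
})

test_that("multiple-choice rewards and block scheduling are exact", {
  task <- tiny_mc_task()
  env <- mc_reset(task, "train")
  rewards <- integer(0)
  targets <- integer(0)
  for (t in 1:30) {
    obs <- mc_observe(env)
    # choose the target knowingly to probe the reward rule
    choice <- match(env$target, obs$categories)
    out <- mc_step(env, choice)
    expect_identical(out$reward, 1)
    targets <- c(targets, out$target)
  }
  # target is constant within each 10-trial block
  expect_identical(length(unique(targets[1:10])), 1L)
  expect_identical(length(unique(targets[11:20])), 1L)

  env2 <- mc_reset(task, "train")
  obs <- mc_observe(env2)
  wrong <- setdiff(seq_len(3), match(env2$target, obs$categories))[1]
  expect_identical(mc_step(env2, wrong)$reward, 0)
  expect_error(mc_step(env2, 99), "Invalid")

  # block index increments exactly at multiples of block_length
  env3 <- mc_reset(task, "train")
  for (t in 1:10) out <- mc_step(env3, 1L)
  expect_identical(env3$block, 1L)
  expect_identical(mc_observe(env3)$block, 1L)

  # force_change guarantees a switch at every boundary
  taskf <- tiny_mc_task(force_change = TRUE)
  envf <- mc_reset(taskf, "train")
  tgts <- integer(0)
  for (t in 1:40) {
    tgts <- c(tgts, envf$target)
    mc_step(envf, 1L)
  }
  expect_true(all(tgts[10 * (1:3)] != tgts[10 * (1:3) + 1]))
})

test_that("the ideal observer hits its analytic ceiling", {
  eps <- 0.2
  analytic <- (1 - eps) + eps / 3
  expect_equal(analytic, 0.8667, tolerance = 5e-5)

  # simulation: the observer is told the previous trial's rewarded category;
  # within a block (first trial excluded) its expected reward is analytic
  set.seed(123)
  n <- 100000
  correct <- rbinom(n, 1, 1 - eps)           # picked last rewarded category
  explore_hit <- rbinom(n, 1, 1 / 3)
  reward <- ifelse(correct == 1, 1, explore_hit)
  sigma <- sqrt(analytic * (1 - analytic) / n)
  expect_lt(abs(mean(reward) - analytic), 3 * sigma)

  # through the environment machinery: non-first trials of each block
  task <- tiny_mc_task()
  env <- mc_reset(task, "train")
  rs <- numeric(0)
  set.seed(7)
  for (t in 1:300) {
    obs <- mc_observe(env)
    ch <- ideal_observer_choice(obs$categories, obs$prev_target, eps)
    out <- mc_step(env, ch)
    if ((out$trial - 1) %% task$block_length != 0) rs <- c(rs, out$reward)
  }
  expect_lt(abs(mean(rs) - analytic), 3 * sqrt(analytic * (1 - analytic) / length(rs)))
})

test_that("the ideal observer never reads feature values", {
  # stimuli carry deliberately corrupted features; choice must not change
  set.seed(5)
  cats <- c(2L, 3L, 1L)
  c1 <- ideal_observer_choice(cats, last_rewarded_category = 3L, epsilon = 0)
  expect_identical(cats[c1], 3L)
  set.seed(5)
  c2 <- ideal_observer_choice(cats, 3L, epsilon = 0)
  expect_identical(c1, c2)
  # no history: uniform random choice
  set.seed(6)
  draws <- replicate(6000, ideal_observer_choice(cats, NA, epsilon = 0))
  p <- tabulate(draws, 3) / 6000
  expect_true(all(abs(p - 1 / 3) < 3 * sqrt((1 / 3) * (2 / 3) / 6000)))
})

test_that("object-collection physics, rewards and spawning follow the rules", {
  task <- tiny_oc_task()
  env <- oc_reset(task)
  obs <- oc_episode_reset(env)
  expect_s3_class(obs, "feature_tensor")
  expect_identical(env$agent_col, 3L)

  # agent moves left and clamps at the wall
  oc_step(env, 1L); oc_step(env, 1L)
  expect_identical(env$agent_col, 1L)
  oc_step(env, 1L)
  expect_identical(env$agent_col, 1L)
  expect_error(oc_step(env, 5L), "Invalid")

  # plant an object one row above the bottom in the agent's path; catching
  # a rewarded identity pays one
  env$objects <- list(list(identity = env$rewarded[1],
                           profile = env$profiles[[env$rewarded[1]]],
                           row = task$backend$H - 1L, col = 2L))
  st <- oc_step(env, 2L)   # move right onto column 2 as the object lands
  expect_identical(st$reward, 1)
  expect_length(env$objects, 0L)

  # a non-rewarded identity in reward-revaluation mode pays zero
  other <- setdiff(env$active, env$rewarded)[1]
  env$objects <- list(list(identity = other, profile = env$profiles[[other]],
                           row = task$backend$H - 1L, col = 1L))
  st <- oc_step(env, 1L)
  expect_identical(st$reward, 0)

  # spawns appear every spawn_interval steps with active identities
  env2 <- oc_reset(task)
  oc_episode_reset(env2)
  for (i in 1:3) st <- oc_step(env2, 1L)
  expect_length(env2$objects, 1L)
  expect_true(env2$objects[[1]]$identity %in% env2$active)
})

test_that("revaluation happens exactly once, at the configured episode", {
  task <- tiny_oc_task()   # reward revaluation at episode 3 of 6
  env <- oc_reset(task)
  rewarded <- integer(0)
  for (ep in 1:6) {
    oc_episode_reset(env)
    rewarded <- c(rewarded, env$rewarded[1])
    while (!oc_step(env, 1L)$done) NULL
  }
  expect_identical(length(unique(rewarded[1:3])), 1L)
  expect_identical(length(unique(rewarded[4:6])), 1L)
  expect_false(rewarded[4] == rewarded[3])

  # state revaluation switches the active identity set instead
  ts <- tiny_oc_task(mode = "state_revaluation")
  envs <- oc_reset(ts)
  active <- integer(0)
  for (ep in 1:6) {
    oc_episode_reset(envs)
    expect_length(envs$active, 1L)
    active <- c(active, envs$active)
    while (!oc_step(envs, 1L)$done) NULL
  }
  expect_false(active[4] == active[3])
  # every active identity is rewarded in state mode
  expect_true(all(active %in% envs$rewarded))
})

test_that("every spawn column is catchable under default geometry", {
  expect_true(oc_catchable(tiny_oc_task()))
  expect_true(oc_catchable(oc_task_spec()))
  # a pathologically fast fall defeats the agent
  fast <- tiny_oc_task()
  fast$fall_rate <- 5L
  expect_false(oc_catchable(fast))
})

test_that("environment runs are deterministic given the spec seed", {
  roll <- function() {
    env <- oc_reset(tiny_oc_task())
    oc_episode_reset(env)
    out <- numeric(0)
    for (i in 1:20) {
      st <- oc_step(env, sample(1:2, 1))
      out <- c(out, st$reward, mean(st$observation$values))
    }
    out
  }
  set.seed(55); a <- roll()
  set.seed(55); b <- roll()
  expect_identical(a, b)
})
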