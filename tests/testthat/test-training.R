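test_that("rollouts pool transitions per brain with exact counts", {
  env <- tank_env(arena_square(12), n_fish = 4, n_rays = 16)
  env_reset(env, seed = 1)
  brains <- list(make_policy(16))
  set.seed(2)
  batch <- collect_rollout(env, brains, rep(1L, 4), steps = 250)
  expect_length(batch, 1)
  expect_equal(nrow(batch[[1]]$obs), 1000)  # 4 bodies x 250 steps
  expect_equal(sort(unique(batch[[1]]$body)), 1:4)
  # one body, 1000 steps
  env1 <- tank_env(arena_square(12), n_fish = 1, n_rays = 16)
  env_reset(env1, seed = 3)
  set.seed(4)
  b1 <- collect_rollout(env1, brains, 1L, steps = 300)
  expect_equal(nrow(b1[[1]]$obs), 300)
  expect_equal(b1[[1]]$t, 1:300)
})

test_that("rollouts are reproducible under a fixed seed", {
  run_once <- function() {
    env <- tank_env(arena_square(12), n_fish = 2, n_rays = 16)
    env_reset(env, seed = 7)
    set.seed(8)
    brains <- list(make_policy(16), make_policy(16))
    set.seed(9)
    collect_rollout(env, brains, 1:2, steps = 50)
  }
  b1 <- run_once(); b2 <- run_once()
  expect_identical(b1[[1]]$obs, b2[[1]]$obs)
  expect_identical(b1[[2]]$act, b2[[2]]$act)
})

test_that("a PPO step moves the policy toward rewarded actions", {
  set.seed(11)
  p <- make_policy(16)
  D <- 48
  obs <- matrix(runif(200 * D), 200, D)
  a <- policy_act(p, obs)
  batch <- list(obs = obs, obs_next = obs, act = a$actions, logp = a$logp,
                value = a$value, body = rep(1L, 200), t = 1:200)
  rewards <- as.numeric(a$actions[, 2] == 1L)   # only left turns pay
  p_before <- mean(policy_act(p, obs)$p_rot[, 1])
  cfg <- ppo_config(episodes = 1, steps_per_episode = 200, batch_size = 64,
                    epochs = 5, n_checkpoints = 1, seed = 1)
  ppo_update(p, batch, rewards, cfg, lr = 5e-3)
  p_after <- mean(policy_act(p, obs)$p_rot[, 1])
  expect_gt(p_after, p_before)
  # frozen policies refuse updates
  fp <- freeze_policy(p)
  expect_error(ppo_update(fp, batch, rewards, cfg), "frozen")
})

test_that("desk-scale training yields equally spaced restorable checkpoints", {
  env <- tank_env(arena_square(12), n_fish = 2, n_rays = 16)
  cfg <- ppo_config(episodes = 10, steps_per_episode = 30, update_every = 5,
                    batch_size = 64, n_checkpoints = 5, seed = 21)
  tr <- train_population(env, "rnd", cfg)
  expect_equal(tr$checkpoints$n, 5)
  expect_equal(sapply(tr$checkpoints$checkpoints, `[[`, "episode"),
               c(2, 4, 6, 8, 10))
  expect_equal(nrow(tr$log), 10)
  expect_true(all(is.finite(tr$log$mean_pairwise_dist)))
  # restored checkpoint reproduces the live policy bit-exactly on probes
  cp <- tr$checkpoints$checkpoints[[5]]
  obs <- matrix(runif(5 * 48), 5, 48)
  live <- curiofish:::policy_forward(tr$brains[[1]], obs)
  saved <- curiofish:::policy_forward(cp$policies[[1]], obs)
  expect_identical(live$logits_loc, saved$logits_loc)
  expect_identical(live$logits_rot, saved$logits_rot)
  # frozen copy behaves identically and survives evaluation untouched
  fp <- freeze_policy(cp$policies[[1]])
  W0 <- curiofish:::policy_params(fp)
  a1 <- policy_act(fp, obs, deterministic = TRUE)$actions
  a2 <- policy_act(fp, obs, deterministic = TRUE)$actions
  expect_identical(a1, a2)
  expect_identical(curiofish:::policy_params(fp), W0)
})

test_that("checkpoint pair deployments produce tagged trajectories", {
  env <- tank_env(arena_square(12), n_fish = 4, n_rays = 16)
  cfg <- ppo_config(episodes = 4, steps_per_episode = 20, update_every = 2,
                    batch_size = 64, n_checkpoints = 2, seed = 31)
  tr <- train_population(env, "icm_random", cfg)
  pt <- evaluate_checkpoint_pairs(tr$checkpoints, arena = arena_circle(8),
                                  n_pairs = 2, trials = 2,
                                  steps_per_trial = 40,
                                  env_args = list(n_rays = 16), seed = 5)
  expect_equal(sort(unique(pt$age)), 1:2)
  # rows per age = pairs x trials x steps x 2 fish
  expect_equal(nrow(pt[pt$age == 1, ]), 2 * 2 * 40 * 2)
  expect_equal(sort(unique(pt$pair_id)), 1:2)
})

test_that("separate rearing uses single-fish environments with color metadata", {
  cfg <- ppo_config(episodes = 2, steps_per_episode = 15, update_every = 2,
                    batch_size = 32, n_checkpoints = 2, seed = 41)
  reared <- run_experiment3("reared_separately", cfg = cfg,
                            algorithm = "icm_random", fish_per_color = 1,
                            cup = arena_circle(6), n_rays = 16)
  expect_length(reared$policies, 2)
  expect_equal(reared$metadata$familiar_color, c("orange", "blue"))
  expect_true(all(sapply(reared$policies, function(p) p$frozen)))
  expect_equal(reared$metadata$mode, rep("reared_separately", 2))
})
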