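test_that("every algorithm emits nonnegative, deterministic rewards", {
  for (alg in c("icm", "icm_random", "rnd", "crl")) {
    set.seed(10)
    m <- curiosity_module(alg, n_rays = 16)
    b <- random_batch(32, seed = 11)
    r1 <- curiosity_rewards(m, b)
    r2 <- curiosity_rewards(m, b)
    expect_length(r1, 32)
    expect_true(all(r1 >= 0), info = alg)
    expect_identical(r1, r2)
  }
})

test_that("RND reward vanishes when predictor equals target", {
  set.seed(12)
  m <- curiosity_module("rnd", n_rays = 16)
  m$predictor$layers <- m$target$layers
  r <- rnd_reward(matrix(runif(5 * 48), 5, 48), m)
  expect_equal(r, rep(0, 5))
})

test_that("contrastive rewards are bounded and zero for identical frames", {
  set.seed(13)
  m <- curiosity_module("crl", n_rays = 16)
  b <- random_batch(16, seed = 14)
  b$obs_next <- b$obs
  expect_equal(crl_reward(b, m), rep(0, 16), tolerance = 1e-10)
  b2 <- random_batch(64, seed = 15)
  r <- crl_reward(b2, m)
  expect_true(all(r >= 0 & r <= 2))
})

test_that("module training reduces its own loss and spares frozen parts", {
  for (alg in c("icm", "icm_random", "rnd", "crl")) {
    set.seed(16)
    m <- curiosity_module(alg, n_rays = 16)
    b <- random_batch(48, seed = 17)
    frozen_before <- switch(alg,
      rnd = curiofish:::net_params(m$target),
      icm_random = curiofish:::net_params(m$encoder),
      NULL)
    losses <- sapply(1:60, function(i) update_module(m, b, lr = 1e-3))
    expect_lt(losses[60], losses[1], label = alg)
    if (!is.null(frozen_before)) {
      frozen_after <- switch(alg,
        rnd = curiofish:::net_params(m$target),
        icm_random = curiofish:::net_params(m$encoder))
      expect_identical(frozen_before, frozen_after, info = alg)
    }
  }
})

test_that("converged modules assign higher reward to novel scenes", {
  # two-scene toy world: train on scene A only, then compare A vs held-out B
  set.seed(18)
  D <- 48
  scene_obs <- function(center, n) {
    base <- matrix(rep(center, each = n), n, D)
    pmin(pmax(base + matrix(rnorm(n * D, sd = 0.02), n, D), 0), 1)
  }
  cA <- runif(D); cB <- runif(D)
  for (alg in c("icm_random", "rnd")) {
    m <- curiosity_module(alg, n_rays = 16)
    for (i in 1:150) {
      A <- scene_obs(cA, 32)
      b <- list(obs = A, obs_next = scene_obs(cA, 32),
                act = cbind(sample(1:2, 32, TRUE), sample(1:3, 32, TRUE)))
      update_module(m, b, lr = 1e-3)
    }
    bA <- list(obs = scene_obs(cA, 64), obs_next = scene_obs(cA, 64),
               act = cbind(sample(1:2, 64, TRUE), sample(1:3, 64, TRUE)))
    bB <- list(obs = scene_obs(cB, 64), obs_next = scene_obs(cB, 64),
               act = cbind(sample(1:2, 64, TRUE), sample(1:3, 64, TRUE)))
    expect_gt(mean(curiosity_rewards(m, bB)), mean(curiosity_rewards(m, bA)))
  }
})

test_that("ICM reward equals the forward prediction error", {
  set.seed(19)
  m <- curiosity_module("icm", n_rays = 16)
  b <- random_batch(8, seed = 20)
  out <- icm_reward(b, m)
  x1 <- curiofish:::net_forward(m$encoder, b$obs_next)$out
  x <- curiofish:::net_forward(m$encoder, b$obs)$out
  xhat <- curiofish:::net_forward(m$forward,
    cbind(x, curiofish:::onehot_actions(b$act)))$out
  expect_equal(out$reward, rowSums((xhat - x1)^2))
  expect_equal(out$forward_loss, mean(out$reward))
})

test_that("reward scaling and normalization behave as documented", {
  expect_equal(scale_rewards(c(2, 4), 0.001), c(0.002, 0.004))
  expect_equal(scale_rewards(c(1, 2, 3), 1), c(1, 2, 3))
  expect_error(scale_rewards(1:3, 0), "strength")
  r <- c(5, 1, 3, 2)
  expect_identical(order(scale_rewards(r, 0.37)), order(r))
  # shaped rewards preserve ordering within a batch
  set.seed(21)
  m <- curiosity_module("rnd", n_rays = 16, strength = 0.001)
  b <- random_batch(16, seed = 22)
  raw <- curiosity_rewards(m, b)
  shaped <- shaped_rewards(m, b)
  expect_identical(order(shaped), order(raw))
  expect_true(all(shaped >= 0))
})

test_that("CRL refuses batches without temporally distant negatives", {
  set.seed(23)
  m <- curiosity_module("crl", n_rays = 16, crl_min_gap = 5)
  b <- random_batch(4, seed = 24)
  expect_error(update_module(m, b), "too small")
})
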