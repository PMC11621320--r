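test_that("pairwise distance curve follows its definition in body lengths", {
  # two static fish 2 units apart = exactly 1 body length
  expect_equal(pairwise_distance_curve(static_pair_traj(d = 2))$mean_bl, 1)
  # averaging across trials within an age, SEM over trials
  tr <- rbind(static_pair_traj(d = 2, trial_id = 1),
              static_pair_traj(d = 6, trial_id = 2))
  out <- pairwise_distance_curve(tr)
  expect_equal(out$mean_bl, 2)
  expect_equal(out$sem, sd(c(1, 3)) / sqrt(2))
  expect_equal(out$n_trials, 2)
  # isometry: global rotation + translation leaves distances unchanged
  set.seed(1)
  tr2 <- simulate_independent_walkers(3, 100, seed = 2)
  th <- 0.7
  tr2_rot <- data.table::copy(tr2)
  tr2_rot[, `:=`(x = cos(th) * x - sin(th) * y + 5,
                 y = sin(th) * x + cos(th) * y - 3)]
  expect_equal(pairwise_distance_curve(tr2)$mean_bl,
               pairwise_distance_curve(tr2_rot)$mean_bl, tolerance = 1e-10)
  one_fish <- static_pair_traj()[fish_id == 1]
  expect_error(pairwise_distance_curve(one_fish), "2 fish")
})

test_that("the focal frame places neighbors relative to the velocity vector", {
  # neighbor dead ahead at distance 1
  expect_equal(as.vector(to_focal_frame(c(0, 0), c(0, 2), c(0, 1))), c(0, 1))
  # neighbor at the focal position
  expect_equal(as.vector(to_focal_frame(c(3, 4), c(1, 0), c(3, 4))), c(0, 0))
  # neighbor to the right of an eastward swimmer has positive x
  expect_equal(as.vector(to_focal_frame(c(0, 0), c(1, 0), c(0, -1))), c(1, 0))
  # round trip recovers world coordinates
  set.seed(3)
  f <- runif(2, -5, 5); v <- rnorm(2); n <- runif(2, -5, 5)
  rel <- as.vector(to_focal_frame(f, v, n))
  sp <- sqrt(sum(v^2)); u <- v / sp
  world <- f + rel[2] * u + rel[1] * c(u[2], -u[1])
  expect_equal(world, n, tolerance = 1e-12)
  # zero velocity is signalled with NA
  expect_true(all(is.na(to_focal_frame(c(0, 0), c(0, 0), c(1, 1)))))
})

test_that("relative-position maps normalize and expose attraction", {
  set.seed(4)
  null_tr <- simulate_independent_walkers(2, 4000, seed = 5)
  h0 <- relative_position_histogram(null_tr, grid = 10, nbin = 11,
                                    min_count = 5)
  expect_equal(sum(h0$density, na.rm = TRUE), 1, tolerance = 1e-12)
  # attracting pairs concentrate neighbors at small radii relative to null
  attr_tr <- simulate_rule_group(2, rule_params(0.9, seed = 6), 4000)
  h1 <- relative_position_histogram(attr_tr, grid = 10, nbin = 11,
                                    min_count = 5)
  near <- function(h) {
    mids <- (h$breaks[-1] + h$breaks[-length(h$breaks)]) / 2
    w <- outer(mids, mids, function(a, b) sqrt(a^2 + b^2)) < 4
    sum(h$density[w], na.rm = TRUE)
  }
  expect_gt(near(h1), near(h0))
})

test_that("turn-toward probability separates coupled from independent pairs", {
  # constructed: focal always turns toward its neighbor
  steps <- 400
  set.seed(7)
  follow <- simulate_rule_group(2, rule_params(1, decision_interval = 1,
                                               turn_step = 20), steps)
  out <- prob_turn_toward_neighbor(follow, turn_threshold = 0.5)
  expect_gt(out$p_toward, 0.8)
  # independent walkers sit at chance
  null_tr <- simulate_independent_walkers(2, 6000, seed = 8,
    params = rule_params(0, decision_interval = 1, turn_step = 20))
  out0 <- prob_turn_toward_neighbor(null_tr, turn_threshold = 0.5)
  expect_lt(abs(out0$p_toward - 0.5), 0.05)
})

test_that("attraction-parameter inversion recovers printed and simulated values", {
  f <- fit_ps(0.59, 0.23, 0.23)
  expect_equal(f$p_s, 0.54, tolerance = 1e-12)
  expect_equal(fit_ps(0.5, 0.5, 0.5)$p_s, 0)
  expect_true(all(fit_ps(0.9, 0.9, 0.01)$values >= 0 &
                  fit_ps(0.9, 0.9, 0.01)$values <= 1))
  # Monte-Carlo recovery through the generative mechanism
  d <- sample_turn_decisions(list(c(2, 1), c(0, 3), c(0, 1)), p_s = 0.47,
                             n = 2e5, seed = 9)
  f2 <- fit_ps(d$p_hat[1], d$p_hat[2], d$p_hat[3])
  expect_lt(abs(f2$p_s - 0.47), 0.01)
  # least-squares route agrees with the closed form on exact inputs
  expect_equal(fit_ps_lsq(0.59, 0.23, 0.23), 0.54, tolerance = 1e-4)
})

test_that("the 0:3 vs 1:2 scatter has zero residual on analytic points", {
  ps <- seq(0, 1, by = 0.1)
  tb <- data.table::data.table(
    age = seq_along(ps),
    P003 = interaction_rule_probability(c(0, 3), ps),
    P112 = interaction_rule_probability(c(1, 2), ps))
  sc <- eq2_scatter(tb)
  expect_equal(sc$residual, rep(0, length(ps)), tolerance = 1e-14)
  expect_equal(attr(sc, "rms_residual"), 0, tolerance = 1e-14)
  # adversarial point: residual is the vertical distance to the line
  sc2 <- eq2_scatter(data.table::data.table(age = 1, P003 = 0.5, P112 = 0.9))
  expect_equal(sc2$residual, 0.9 - 0.5)
})

test_that("probe-based turning tables respect symmetry and oracles", {
  nr <- 24
  env <- tank_env(arena_circle(16), n_fish = 1, colors = "orange",
                  n_rays = nr)
  # a uniform random policy turns either way equally often
  unif <- function(obs) c(1L, sample(1:3, 1))
  tb <- turning_probability_by_configuration(unif, list(c(2, 1)),
                                             n_images = 400, env = env,
                                             seed = 10)
  expect_lt(abs(tb$p_n1 - 0.5), 3 * sqrt(0.25 / tb$n_turns))
  # pixel-counting oracle: all fish on one side means always turn there
  oracle <- scripted_pixel_policy(nr)
  tb2 <- turning_probability_by_configuration(oracle, list(c(3, 0), c(2, 2)),
                                              n_images = 300, env = env,
                                              seed = 11)
  expect_gt(tb2$p_n1[1], 0.95)
  expect_lt(abs(tb2$p_n1[2] - 0.5), 3 * sqrt(0.25 / tb2$n_turns[2]))
  # mirrored probes swap the counts of a deterministic policy exactly
  set.seed(12)
  p1 <- place_configuration_probe(c(2, 1), n_images = 100, env = env,
                                  seed = 13)
  p2 <- place_configuration_probe(c(1, 2), n_images = 100, env = env,
                                  seed = 13, mirror = TRUE)
  act1 <- sapply(p1$obs, function(o) oracle(o)[2])
  act2 <- sapply(p2$obs, function(o) oracle(o)[2])
  swap <- c(`1` = 3L, `2` = 2L, `3` = 1L)
  expect_equal(unname(swap[as.character(act1)]), act2)
})
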