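test_that("side-choice probability matches the closed form", {
  # hand-evaluated cases
  expect_equal(interaction_rule_probability(configuration(1, 2), 0.54), 0.41)
  expect_equal(interaction_rule_probability(c(0, 3), 0.47), 0.265)
  # symmetric configurations are unbiased for any p_s
  for (p in c(0, 0.3, 0.77, 1))
    for (k in 1:3)
      expect_equal(interaction_rule_probability(c(k, k), p), 0.5)
  # no attraction means a fair coin for any configuration
  expect_equal(interaction_rule_probability(c(5, 1), 0), 0.5)
  expect_error(interaction_rule_probability(c(0, 0), 0.5), "invalid configuration")
  expect_error(interaction_rule_probability(c(1, 1), 1.2), "p_s")
})

test_that("the two side probabilities are complementary and monotone in p_s", {
  ps_grid <- c(0, 0.25, 0.5, 0.75, 1)
  for (n1 in 0:6) for (n2 in 0:6) {
    if (n1 + n2 < 1 || n1 + n2 > 6) next
    s <- interaction_rule_probability(c(n1, n2), ps_grid) +
         interaction_rule_probability(c(n2, n1), ps_grid)
    expect_equal(s, rep(1, length(ps_grid)), tolerance = 1e-15)
  }
  grid <- seq(0, 1, by = 0.05)
  p_incr <- interaction_rule_probability(c(3, 1), grid)
  expect_true(all(diff(p_incr) > 0))
  p_decr <- interaction_rule_probability(c(1, 3), grid)
  expect_true(all(diff(p_decr) < 0))
})

test_that("the 0:3 / 1:2 relation is parameter-free and consistent with the rule", {
  expect_equal(predicted_P112(0.5), 0.5)
  # identity on a dense grid: feeding the rule's 0:3 probability through the
  # relation reproduces the rule's 1:2 probability
  grid <- seq(0, 1, by = 0.001)
  lhs <- predicted_P112(interaction_rule_probability(c(0, 3), grid))
  rhs <- interaction_rule_probability(c(1, 2), grid)
  expect_equal(lhs, rhs, tolerance = 1e-14)
  expect_equal(predicted_P112(0.265),
               interaction_rule_probability(c(1, 2), 0.47))
})

test_that("linear growth in the neighbor fraction holds for 7-fish configurations", {
  p <- 0.6
  cfgs <- list(c(3, 3), c(4, 2), c(5, 1), c(6, 0))
  probs <- sapply(cfgs, interaction_rule_probability, p_s = p)
  fracs <- sapply(cfgs, function(cc) cc[1] / sum(cc))
  fit <- lm(probs ~ fracs)
  expect_equal(unname(coef(fit)[2]), p, tolerance = 1e-12)
  expect_equal(unname(coef(fit)[1]), (1 - p) / 2, tolerance = 1e-12)
})

test_that("sampled decisions follow the generative mechanism", {
  # all neighbors on one side and full attraction: never choose the empty side
  d <- sample_turn_decisions(list(c(0, 3)), p_s = 1, n = 500, seed = 1)
  expect_equal(d$toward_n1, 0)
  expect_equal(d$toward_n2, 500)
  # symmetry at 1:1 regardless of p_s
  d <- sample_turn_decisions(list(c(1, 1)), p_s = 0.7, n = 2e4, seed = 2)
  expect_lt(abs(d$p_hat - 0.5), 3 * sqrt(0.25 / 2e4))
  # Monte-Carlo frequency matches the closed form within 3 binomial SE
  d <- sample_turn_decisions(list(c(2, 1)), p_s = 0.54, n = 2e5, seed = 3)
  p_true <- interaction_rule_probability(c(2, 1), 0.54)
  expect_lt(abs(d$p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / 2e5))
  expect_equal(d$toward_n1 + d$toward_n2, d$n_samples)
  expect_error(sample_turn_decisions(list(), 0.5, 10), "at least one")
})

test_that("rule-based groups cohere and degenerate to the null at p_s = 0", {
  steps <- 3000
  set.seed(10)
  tr_hi <- simulate_rule_group(4, rule_params(0.9), steps)
  tr_null <- simulate_independent_walkers(4, steps, seed = 11)
  d_hi <- pairwise_distance_curve(tr_hi)$mean_bl
  d_null <- pairwise_distance_curve(tr_null)$mean_bl
  expect_lt(d_hi, d_null)
  # same seed reproduces the null walk exactly
  t1 <- simulate_independent_walkers(2, 200, seed = 5)
  t2 <- simulate_independent_walkers(2, 200, seed = 5)
  expect_identical(t1, t2)
  # arena bounds respected at every step
  arena <- arena_circle(16)
  expect_true(all(arena_contains(arena, cbind(t1$x, t1$y), margin = 0.49)))
  tr_sq <- simulate_independent_walkers(3, 500, arena = arena_square(10), seed = 6)
  expect_true(all(arena_contains(arena_square(10), cbind(tr_sq$x, tr_sq$y),
                                 margin = 0.49)))
})

test_that("fully attracting fish started together stay clustered", {
  p <- rule_params(1, turn_step = 30)
  init <- matrix(8, 4, 2) + matrix(runif(8, -0.1, 0.1), 4, 2)
  set.seed(7)
  tr <- simulate_rule_group(4, p, 1500, arena = arena_square(16),
                            init_pos = init)
  final <- tr[tr$t_step == max(tr$t_step), ]
  expect_lt(mean(dist(cbind(final$x, final$y))), 3)
  expect_error(simulate_rule_group(1, p, 100), "n_fish")
  expect_error(simulate_rule_group(2, rule_params(0.5, decision_interval = 10),
                                   5), "steps")
})

test_that("parameter validation rejects out-of-range inputs", {
  expect_error(rule_params(-0.1), "p_s")
  expect_error(rule_params(0.5, decision_interval = 0), "decision_interval")
  expect_error(rule_params(0.5, speed = 0), "speed")
})
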