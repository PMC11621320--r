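test_that("reset produces valid, reproducible, non-overlapping poses", {
  env <- tiny_env(n_fish = 8, arena = arena_square(20))
  env_reset(env, seed = 42)
  pos1 <- env$pos; h1 <- env$heading
  env_reset(env, seed = 42)
  expect_identical(env$pos, pos1)
  expect_identical(env$heading, h1)
  dd <- curiofish:::capsule_pair_dists_cpp(env$pos, env$heading,
                                           env$body$half_len)
  expect_gte(min(dd[upper.tri(dd)]), 2 * env$body$radius)
  expect_true(all(arena_contains(env$arena, env$pos, margin = 0.99)))
  # arena too small for the population
  crowded <- tiny_env(n_fish = 30, arena = arena_square(6))
  expect_error(env_reset(crowded, seed = 1, max_tries = 20), "placement")
})

test_that("actions rotate by the step angle and advance along the heading", {
  st <- list(pos = c(5, 5), heading_deg = 0)
  # identity action in the forward/stay set
  same <- apply_action(st, 2, 2, action_set = "exp2")
  expect_equal(same$pos, st$pos)
  expect_equal(same$heading_deg, 0)
  # left turn then advance along the new heading
  mv <- apply_action(st, 1, 1, action_set = "exp2", speed_slow = 0.07)
  expect_equal(mv$heading_deg, 2)
  expect_equal(mv$pos, c(5, 5) + 0.07 * c(cos(2 * pi / 180), sin(2 * pi / 180)))
  # 180 consecutive left rotations return to the starting heading
  s <- st
  for (i in 1:180) s <- apply_action(s, 2, 1, action_set = "exp2")
  expect_equal(s$heading_deg, 0)
  expect_equal(s$pos, st$pos)
})

test_that("collision resolution separates colliders and clamps at walls", {
  env <- tiny_env(n_fish = 2, arena = arena_square(20))
  env$pos <- rbind(c(10, 10), c(10, 10.8))   # side by side, overlapping move
  env$heading <- c(0, 0)
  env_step(env, rbind(c(2, 2), c(2, 2)), observe = FALSE)
  dd <- curiofish:::capsule_pair_dists_cpp(env$pos, env$heading, 0.5)
  expect_gte(dd[1, 2], 1.0 - 1e-6)
  # driving into a wall: position clamps, heading unchanged
  env2 <- tiny_env(n_fish = 1, arena = arena_square(20))
  env2$pos <- rbind(c(18.9, 10)); env2$heading <- 0
  for (i in 1:20) env_step(env2, rbind(c(1, 2)), observe = FALSE)
  expect_lte(env2$pos[1, 1], 19.0 + 1e-9)
  expect_equal(env2$heading, 0)
  # far-apart fish move unimpeded
  env3 <- tiny_env(n_fish = 2, arena = arena_square(20))
  env3$pos <- rbind(c(5, 5), c(15, 15)); env3$heading <- c(0, 0)
  p0 <- env3$pos
  env_step(env3, rbind(c(1, 2), c(1, 2)), observe = FALSE)
  expect_equal(env3$pos[, 1] - p0[, 1], rep(env3$speed_fast, 2))
})

test_that("the renderer sees walls, colored fish, occlusion and depth", {
  env <- tiny_env(n_fish = 1, arena = arena_square(20))
  env$pos <- rbind(c(10, 10)); env$heading <- 0
  obs <- render_egocentric(env, 1)
  expect_equal(dim(obs), c(env$n_rays, 3))
  expect_true(all(obs >= 0 & obs <= 1))
  # empty arena: achromatic wall on every ray
  expect_true(all(abs(obs[, 1] - obs[, 2]) < 1e-12))
  # an orange fish dead ahead colors the central rays
  env2 <- tiny_env(n_fish = 2, arena = arena_square(20))
  env2$pos <- rbind(c(10, 10), c(13, 10))
  env2$heading <- c(0, 90)
  obs2 <- render_egocentric(env2, 1)
  mid <- env2$n_rays / 2
  central <- obs2[c(mid, mid + 1), ]
  expect_true(all(central[, 1] > central[, 3]))   # orange: R > B
  # closer fish occludes a farther one on shared rays
  env3 <- tank_env(arena_square(20), n_fish = 3,
                   colors = c("neutral", "orange", "blue"), n_rays = 16)
  env3$pos <- rbind(c(10, 10), c(12, 10), c(16, 10))
  env3$heading <- c(0, 90, 90)
  obs3 <- render_egocentric(env3, 1)
  central3 <- obs3[c(8, 9), ]
  expect_true(all(central3[, 1] > central3[, 3]))  # orange in front of blue
})

test_that("the renderer is exactly mirror-equivariant", {
  # focal at the center of a circular arena: reflecting the scene about the
  # optical axis maps the arena onto itself, so the observation must be the
  # exact left-right mirror (reversed ray order)
  set.seed(3)
  env <- tank_env(arena_circle(14), n_fish = 4,
                  colors = c("orange", "blue", "orange", "blue"),
                  n_rays = 24)
  env$pos <- cbind(c(0, runif(3, -8, 8)), c(0, runif(3, -8, 8)))
  env$heading <- c(0, runif(3, 0, 360))
  obs <- render_egocentric(env, 1)
  env$pos[, 2] <- -env$pos[, 2]                 # reflect about the x axis
  env$heading <- wrap_heading(-env$heading)     # (the focal optical axis)
  obs_m <- render_egocentric(env, 1)
  expect_equal(obs_m, obs[rev(seq_len(24)), ], tolerance = 1e-9)
})

test_that("probe scenes honor sides, determinism, and mirroring", {
  p1 <- place_configuration_probe(c(3, 0), n_images = 8, seed = 11)
  p2 <- place_configuration_probe(c(3, 0), n_images = 8, seed = 11)
  expect_identical(p1$obs, p2$obs)
  # fish centers sit in the left half-field for 3:0; bodies may overhang
  # the axis by at most asin(1 / min_dist), so rays well to the right of
  # the axis stay achromatic while the left field shows fish
  env0 <- tank_env(arena_circle(16), n_fish = 1, colors = "orange")
  nr <- nrow(p1$obs[[1]])
  margin <- asin(1 / 2.5) * 180 / pi
  far_right <- which(env0$offsets < -margin)
  left <- which(env0$offsets > 0)
  for (ob in p1$obs) {
    chroma <- apply(ob, 1, max) - apply(ob, 1, min)
    expect_true(all(chroma[far_right] < 1e-9))
    expect_gt(sum(chroma[left]), 0)
  }
  # mirrored placement is the exact left-right mirror of the original
  pm <- place_configuration_probe(c(0, 3), n_images = 8, seed = 11,
                                  mirror = TRUE)
  for (k in 1:8)
    expect_equal(pm$obs[[k]], p1$obs[[k]][rev(seq_len(nr)), ],
                 tolerance = 1e-9)
  expect_error(place_configuration_probe(c(0, 0), 2), "invalid configuration")
})

test_that("2AFC scenes hold two full shoals with the test fish centered", {
  scene <- build_2afc_scene("orange", "blue", shoal_size = 11, seed = 21)
  expect_equal(sum(scene$scenery$color == "orange"), 11)
  expect_equal(sum(scene$scenery$color == "blue"), 11)
  fc <- attr(scene, "familiar_center"); nc <- attr(scene, "novel_center")
  d_f <- sqrt(sum((scene$pos[1, ] - fc)^2))
  d_n <- sqrt(sum((scene$pos[1, ] - nc)^2))
  expect_equal(d_f, d_n)
  # side assignment is balanced across trials
  sides <- replicate(400, {
    s <- build_2afc_scene("orange", "blue", shoal_size = 3)
    attr(s, "familiar_center")[1] < 12
  })
  expect_lt(abs(mean(sides) - 0.5), 3 * sqrt(0.25 / 400))
  expect_error(build_2afc_scene("orange", "orange"), "must differ")
})

test_that("observation flattening interleaves channels by ray", {
  env <- tiny_env(n_fish = 1)
  env_reset(env, seed = 2)
  obs <- render_egocentric(env, 1)
  v <- obs_to_vec(obs)
  expect_equal(length(v), 3 * env$n_rays)
  expect_equal(v[1:3], unname(obs[1, ]))
  expect_equal(v[4:6], unname(obs[2, ]))
})
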