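# Shared fixtures: everything is generated in code at test time.

# small tank used across environment tests
tiny_env <- function(n_fish = 3, n_rays = 16, arena = arena_square(12), ...) {
  tank_env(arena, n_fish = n_fish, colors = "orange", n_rays = n_rays, ...)
}

# random transition batch in retina space
random_batch <- function(B, n_rays = 16, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  D <- 3L * n_rays
  list(obs = matrix(runif(B * D), B, D),
       obs_next = matrix(runif(B * D), B, D),
       act = cbind(sample(1:2, B, TRUE), sample(1:3, B, TRUE)))
}

# hand-built trajectory table for metric unit tests
static_pair_traj <- function(d = 2, steps = 10, age = 1, trial_id = 1) {
  data.table::data.table(
    trial_id = trial_id, age = age,
    t_step = rep(seq_len(steps), times = 2),
    fish_id = rep(1:2, each = steps),
    color = "neutral",
    x = c(rep(0, steps), rep(d, steps)),
    y = 0, heading_deg = 0)
}

# numeric finite-difference gradient of a scalar function of one weight
fd_grad <- function(get, set, loss, eps = 1e-5) {
  w0 <- get()
  set(w0 + eps); lp <- loss()
  set(w0 - eps); lm <- loss()
  set(w0)
  (lp - lm) / (2 * eps)
}
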