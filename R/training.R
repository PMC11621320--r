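#' Train a population of artificial fish
#'
#' Rears `n_fish` embodied agents in a tank: every episode the poses are
#' randomized, each brain samples actions from its policy, and every
#' `update_every` episodes each brain's pooled transitions are used first
#' to update its curiosity module and compute intrinsic rewards, then to
#' update the policy with PPO (learning rate decays linearly to zero).
#' Policy snapshots are taken at `n_checkpoints` equally spaced episodes —
#' the "artificial days". Every fish starts from its own random weight
#' initialization.
#'
#' @param env a [tank_env()]
#' @param algorithm intrinsic-motivation algorithm (see
#'   [curiosity_module()])
#' @param cfg a [ppo_config()]
#' @param assignment brain index per fish body (default: one brain per
#'   body); bodies sharing a brain pool their experience
#' @param strength curiosity reward strength (1 normal, 0.001 reduced)
#' @param verbose print a line per update
#' @return a list of class `fish_training` with `checkpoints` (a
#'   `checkpoint_set`), `log` (per-episode table: episode, mean pairwise
#'   distance, mean shaped reward, learning rate), `brains`, `modules`,
#'   `assignment`, `cfg`
#' @export
train_population <- function(env, algorithm = "icm", cfg = ppo_config(),
                             assignment = seq_len(env$n_fish),
                             strength = 1.0, verbose = FALSE) {
  set.seed(cfg$seed)
  n_brains <- max(assignment)
  stopifnot(all(sort(unique(assignment)) == seq_len(n_brains)))
  brains <- lapply(seq_len(n_brains), function(b)
    make_policy(env$n_rays, env$action_set))
  modules <- lapply(seq_len(n_brains), function(b)
    curiosity_module(algorithm, env$n_rays, strength = strength))
  cp_eps <- unique(round(seq_len(cfg$n_checkpoints) *
                         cfg$episodes / cfg$n_checkpoints))
  stopifnot(length(cp_eps) == cfg$n_checkpoints)
  checkpoints <- vector("list", cfg$n_checkpoints)
  total_updates <- max(1L, cfg$episodes %/% cfg$update_every)
  upd <- 0L
  pending <- vector("list", 0)
  log_dist <- numeric(cfg$episodes)
  log_rew <- rep(NA_real_, cfg$episodes)
  log_lr <- rep(NA_real_, cfg$episodes)
  for (ep in seq_len(cfg$episodes)) {
    env_reset(env)
    batches <- collect_rollout(env, brains, assignment, cfg$steps_per_episode)
    for (b in seq_along(batches)) batches[[b]]$episode <-
      rep(ep, length(batches[[b]]$t))
    pending[[length(pending) + 1]] <- batches
    # episode monitor: mean over steps of mean pairwise distance
    log_dist[ep] <- attr(batches, "mean_pair_dist")
    if (ep %% cfg$update_every == 0L) {
      upd <- upd + 1L
      lr <- cfg$lr0 * (1 - (upd - 1) / total_updates)
      mean_rew <- 0
      for (b in seq_len(n_brains)) {
        batch <- concat_batches(lapply(pending, `[[`, b))
        ord <- order(batch$body, batch$episode, batch$t)
        batch <- reorder_batch(batch, ord)
        r <- shaped_rewards(modules[[b]], batch)
        update_module(modules[[b]], batch, lr = lr)
        ppo_update(brains[[b]], batch, r, cfg, lr = lr)
        mean_rew <- mean_rew + mean(r) / n_brains
      }
      pending <- vector("list", 0)
      log_rew[ep] <- mean_rew
      log_lr[ep] <- lr
      if (verbose)
        message(sprintf("episode %d: lr %.5f, mean reward %.4f, mean dist %.2f",
                        ep, lr, mean_rew, log_dist[ep]))
    }
    k <- match(ep, cp_eps)
    if (!is.na(k)) {
      checkpoints[[k]] <- list(age = k, episode = ep,
                               policies = lapply(brains, policy_clone),
                               colors = env$colors, assignment = assignment)
    }
  }
  cps <- structure(list(checkpoints = checkpoints, n = cfg$n_checkpoints,
                        algorithm = algorithm),
                   class = "checkpoint_set")
  structure(list(checkpoints = cps,
                 log = data.table::data.table(
                   episode = seq_len(cfg$episodes),
                   mean_pairwise_dist = log_dist,
                   mean_reward = log_rew, lr = log_lr),
                 brains = brains, modules = modules,
                 assignment = assignment, cfg = cfg),
            class = "fish_training")
}

concat_batches <- function(lst) {
  list(obs = do.call(rbind, lapply(lst, `[[`, "obs")),
       obs_next = do.call(rbind, lapply(lst, `[[`, "obs_next")),
       act = do.call(rbind, lapply(lst, `[[`, "act")),
       logp = unlist(lapply(lst, `[[`, "logp")),
       value = unlist(lapply(lst, `[[`, "value")),
       body = unlist(lapply(lst, `[[`, "body")),
       t = unlist(lapply(lst, `[[`, "t")),
       episode = unlist(lapply(lst, `[[`, "episode")))
}

reorder_batch <- function(batch, ord) {
  batch$obs <- batch$obs[ord, , drop = FALSE]
  batch$obs_next <- batch$obs_next[ord, , drop = FALSE]
  batch$act <- batch$act[ord, , drop = FALSE]
  batch$logp <- batch$logp[ord]
  batch$value <- batch$value[ord]
  batch$body <- batch$body[ord]
  batch$t <- batch$t[ord]
  batch$episode <- batch$episode[ord]
  batch
}

#' @export
print.checkpoint_set <- function(x, ...) {
  cat(sprintf("<checkpoint_set> %d checkpoints (ages), algorithm %s\n",
              x$n, x$algorithm))
  invisible(x)
}

#' Deploy checkpoint pairs in a test arena
#'
#' For each checkpoint ("age"), groups the trained fish into pairs, loads
#' the frozen policies, and records trajectories of each pair in the test
#' arena over `trials` trials of `steps_per_trial` steps with randomized
#' starting poses.
#'
#' @param cps a `checkpoint_set` from [train_population()]
#' @param arena test arena (default circular, radius 16)
#' @param n_pairs number of pairs (default: all fish paired in order)
#' @param trials test trials per pair
#' @param steps_per_trial steps per trial
#' @param ages checkpoint indices to evaluate (default all)
#' @param env_args extra arguments passed to [tank_env()] (retina must
#'   match the policies)
#' @param deterministic if `TRUE` (default) fish take the modal action of
#'   their policy during test trials; if `FALSE`, actions are sampled
#' @param seed integer seed
#' @return a trajectory `data.table` tagged with `age`, `trial_id` and a
#'   `pair` attribute column encoded in `trial_id`
#' @export
evaluate_checkpoint_pairs <- function(cps, arena = arena_circle(16),
                                      n_pairs = NULL, trials = 2,
                                      steps_per_trial = 5000, ages = NULL,
                                      env_args = list(), deterministic = TRUE,
                                      seed = 1L) {
  set.seed(seed)
  if (is.null(ages)) ages <- seq_len(cps$n)
  out <- vector("list", 0)
  trial_counter <- 0L
  for (k in ages) {
    cp <- cps$checkpoints[[k]]
    pols <- cp$policies[cp$assignment]   # policy per body
    nf <- length(pols)
    if (is.null(n_pairs)) n_pairs <- nf %/% 2
    for (pr in seq_len(n_pairs)) {
      ids <- c(2 * pr - 1, 2 * pr)
      fp <- lapply(pols[ids], freeze_policy)
      for (tr in seq_len(trials)) {
        trial_counter <- trial_counter + 1L
        env <- do.call(tank_env, c(list(arena = arena, n_fish = 2,
                                        colors = cp$colors[ids]),
                                   env_args))
        traj <- run_policy_episode(env, fp, steps_per_trial,
                                   trial_id = trial_counter, age = k,
                                   deterministic = deterministic)
        traj$pair_id <- pr
        out[[length(out) + 1]] <- traj
      }
    }
  }
  data.table::rbindlist(out)
}

# roll an environment under fixed (frozen or scripted) per-fish policies
# and record the trajectory; policies may be fish_policy objects or plain
# functions obs_matrix -> c(locomotion, rotation)
run_policy_episode <- function(env, policies, steps, trial_id = 1L, age = 1L,
                               reset = TRUE, deterministic = FALSE) {
  if (reset) env_reset(env)
  n <- env$n_fish
  xs <- matrix(NA_real_, steps, n); ys <- matrix(NA_real_, steps, n)
  hs <- matrix(NA_real_, steps, n)
  obs <- env_observe(env)
  for (s in seq_len(steps)) {
    actions <- matrix(NA_integer_, n, 2)
    for (i in seq_len(n)) {
      pol <- policies[[i]]
      if (is.function(pol)) {
        actions[i, ] <- pol(obs[[i]])
      } else {
        a <- policy_act(pol, obs_to_vec(obs[[i]]),
                        deterministic = deterministic)
        actions[i, ] <- a$actions[1, ]
      }
    }
    obs <- env_step(env, actions)
    xs[s, ] <- env$pos[, 1]; ys[s, ] <- env$pos[, 2]; hs[s, ] <- env$heading
  }
  data.table::data.table(
    trial_id = trial_id, age = age,
    t_step = rep(seq_len(steps), times = n),
    fish_id = rep(seq_len(n), each = steps),
    color = rep(env$colors, each = steps),
    x = as.vector(xs), y = as.vector(ys), heading_deg = as.vector(hs))
}

#' Rear fish for the social-preference experiment
#'
#' Group mode rears one group of orange fish and one group of blue fish,
#' each group together in its own white cup; separate mode rears every
#' fish alone in its own cup. Policies are frozen at the end of training
#' (the critical-period analogue).
#'
#' @param mode `"group_reared"` or `"reared_separately"`
#' @param strength curiosity reward strength
#' @param cfg a [ppo_config()]
#' @param algorithm intrinsic-motivation algorithm
#' @param fish_per_color fish per pigment group
#' @param cup arena used as the rearing cup
#' @param n_rays retina length
#' @return list with `policies` (frozen, one per fish), `metadata`
#'   (data.frame: fish, color, familiar_color, mode, strength)
#' @export
run_experiment3 <- function(mode = c("group_reared", "reared_separately"),
                            strength = 1.0, cfg = ppo_config(),
                            algorithm = "icm", fish_per_color = 4,
                            cup = arena_circle(8), n_rays = 32) {
  mode <- match.arg(mode)
  colors <- c("orange", "blue")
  policies <- list()
  meta <- NULL
  seed_off <- 0L
  for (col in colors) {
    if (mode == "group_reared") {
      env <- tank_env(cup, n_fish = fish_per_color, colors = col,
                      action_set = "exp2", n_rays = n_rays)
      cfg_g <- cfg; cfg_g$seed <- cfg$seed + seed_off
      tr <- train_population(env, algorithm, cfg_g, strength = strength)
      pols <- lapply(tr$brains, freeze_policy)
      seed_off <- seed_off + 1L
    } else {
      pols <- vector("list", fish_per_color)
      for (i in seq_len(fish_per_color)) {
        env <- tank_env(cup, n_fish = 1, colors = col,
                        action_set = "exp2", n_rays = n_rays)
        cfg_i <- cfg; cfg_i$seed <- cfg$seed + seed_off
        tr <- train_population(env, algorithm, cfg_i, strength = strength)
        pols[[i]] <- freeze_policy(tr$brains[[1]])
        seed_off <- seed_off + 1L
      }
    }
    policies <- c(policies, pols)
    meta <- rbind(meta, data.frame(
      fish = length(policies) - fish_per_color + seq_len(fish_per_color),
      color = col, familiar_color = col, mode = mode, strength = strength))
  }
  list(policies = policies, metadata = meta)
}
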