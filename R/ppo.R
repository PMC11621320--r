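#' PPO configuration
#'
#' Defaults follow the training protocol of the artificial-fish study:
#' discount 0.99, initial learning rate 0.001 with linear decay to zero
#' over training, updates every 5 episodes with batch size 500, and 20
#' equally spaced checkpoints. Clip ratio, epochs per update, GAE lambda
#' and entropy bonus are implementation conventions, all exposed here.
#'
#' @param episodes total training episodes
#' @param steps_per_episode environment steps per episode
#' @param update_every episodes between policy/module updates
#' @param batch_size PPO minibatch size
#' @param gamma reward discount factor
#' @param gae_lambda generalized-advantage-estimation lambda
#' @param lr0 initial learning rate (linearly decayed to 0)
#' @param clip PPO clipped-surrogate ratio
#' @param epochs optimization epochs per update
#' @param entropy_coef entropy bonus coefficient
#' @param value_coef value-loss coefficient
#' @param n_checkpoints number of equally spaced policy snapshots ("ages")
#' @param seed integer seed for the whole run
#' @return a list of class `ppo_config`
#' @export
ppo_config <- function(episodes = 2000, steps_per_episode = 1000,
                       update_every = 5, batch_size = 500, gamma = 0.99,
                       gae_lambda = 0.95, lr0 = 0.001, clip = 0.2,
                       epochs = 3, entropy_coef = 0.01, value_coef = 0.5,
                       n_checkpoints = 20, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(episodes >= n_checkpoints, steps_per_episode >= 1,
            update_every >= 1, gamma > 0, gamma <= 1, lr0 >= 0)
  class(cfg) <- "ppo_config"
  cfg
}

# discounted returns and GAE advantages for one contiguous episode segment
# (treated as terminal at its end)
gae_segment <- function(rewards, values, gamma, lam) {
  T_ <- length(rewards)
  adv <- numeric(T_)
  last <- 0
  for (s in rev(seq_len(T_))) {
    v_next <- if (s == T_) 0 else values[s + 1]
    delta <- rewards[s] + gamma * v_next - values[s]
    last <- delta + gamma * lam * last
    adv[s] <- last
  }
  list(adv = adv, ret = adv + values)
}

#' Collect a rollout from an environment
#'
#' Runs `steps` environment steps sampling every fish's action from its
#' brain's policy. Bodies assigned to the same brain pool their transitions
#' into that brain's batch.
#'
#' @param env a [tank_env()] (already reset)
#' @param brains list of [make_policy()] objects
#' @param assignment integer vector, brain index per fish body
#' @param steps number of steps to roll out
#' @return list of per-brain batches, each with `obs`, `obs_next`, `act`,
#'   `logp`, `value`, `body`, `t` (all row-aligned)
#' @export
collect_rollout <- function(env, brains, assignment, steps) {
  stopifnot(length(assignment) == env$n_fish,
            max(assignment) <= length(brains))
  n <- env$n_fish
  D <- 3L * env$n_rays
  obs <- matrix(unlist(lapply(env_observe(env), obs_to_vec)), n, D, byrow = TRUE)
  rows_by_brain <- lapply(seq_along(brains), function(b) which(assignment == b))
  obs_t <- vector("list", steps); next_t <- vector("list", steps)
  act_t <- vector("list", steps); logp_t <- vector("list", steps)
  val_t <- vector("list", steps)
  dsum <- 0
  for (s in seq_len(steps)) {
    actions <- matrix(NA_integer_, n, 2)
    logp <- numeric(n); value <- numeric(n)
    for (b in seq_along(brains)) {
      rows <- rows_by_brain[[b]]
      a <- policy_act(brains[[b]], obs[rows, , drop = FALSE])
      actions[rows, ] <- a$actions
      logp[rows] <- a$logp
      value[rows] <- a$value
    }
    nxt <- env_step(env, actions)
    obs_next <- matrix(unlist(lapply(nxt, obs_to_vec)), n, D, byrow = TRUE)
    obs_t[[s]] <- obs; next_t[[s]] <- obs_next
    act_t[[s]] <- actions; logp_t[[s]] <- logp; val_t[[s]] <- value
    obs <- obs_next
    if (n > 1) dsum <- dsum + mean(dist(env$pos))
  }
  OBS <- do.call(rbind, obs_t); NXT <- do.call(rbind, next_t)
  ACT <- do.call(rbind, act_t)
  LOGP <- unlist(logp_t); VAL <- unlist(val_t)
  body_all <- rep(seq_len(n), times = steps)
  t_all <- rep(seq_len(steps), each = n)
  out <- lapply(seq_along(brains), function(b) {
    sel <- body_all %in% rows_by_brain[[b]]
    list(obs = OBS[sel, , drop = FALSE], obs_next = NXT[sel, , drop = FALSE],
         act = ACT[sel, , drop = FALSE], logp = LOGP[sel], value = VAL[sel],
         body = body_all[sel], t = t_all[sel])
  })
  attr(out, "mean_pair_dist") <- if (n > 1) dsum / steps else NA_real_
  out
}

#' One PPO update of a policy
#'
#' Clipped-surrogate policy update with discounted intrinsic returns and
#' value regression. Advantages are computed with GAE per body (each
#' body's rows must be in temporal order, which [collect_rollout()]
#' guarantees after reordering by body).
#'
#' @param brain a [make_policy()] (errors if frozen)
#' @param batch a per-brain batch from [collect_rollout()] (possibly the
#'   concatenation of several episodes; episode boundaries are detected
#'   from the `t` column resetting)
#' @param rewards per-transition shaped intrinsic rewards
#' @param cfg a [ppo_config()]
#' @param lr learning rate for this update (defaults to `cfg$lr0`)
#' @return invisibly, a list of diagnostic losses
#' @export
ppo_update <- function(brain, batch, rewards, cfg, lr = NULL) {
  if (isTRUE(brain$frozen))
    stop("contract violation: attempt to update a frozen policy")
  if (is.null(lr)) lr <- cfg$lr0
  N <- nrow(batch$obs)
  stopifnot(length(rewards) == N)
  # order rows by (body, episode, step) so segments are contiguous
  epi <- if (!is.null(batch$episode)) batch$episode else rep(1L, N)
  ord <- order(batch$body, epi, batch$t)
  batch$obs <- batch$obs[ord, , drop = FALSE]
  batch$act <- batch$act[ord, , drop = FALSE]
  batch$logp <- batch$logp[ord]
  batch$value <- batch$value[ord]
  batch$body <- batch$body[ord]
  batch$t <- batch$t[ord]
  epi <- epi[ord]
  rewards <- rewards[ord]
  seg_id <- cumsum(c(1L, (diff(batch$t) != 1L) | (diff(batch$body) != 0L) |
                          (diff(epi) != 0L)))
  adv <- numeric(N); ret <- numeric(N)
  for (sg in split(seq_len(N), seg_id)) {
    g <- gae_segment(rewards[sg], batch$value[sg], cfg$gamma, cfg$gae_lambda)
    adv[sg] <- g$adv; ret[sg] <- g$ret
  }
  adv_n <- (adv - mean(adv)) / max(sd(adv), 1e-8)
  diag <- NULL
  for (ep in seq_len(cfg$epochs)) {
    perm <- sample.int(N)
    splits <- split(perm, ceiling(seq_along(perm) / cfg$batch_size))
    for (mb in splits) {
      B <- length(mb)
      f <- policy_forward(brain, batch$obs[mb, , drop = FALSE], keep_cache = TRUE)
      p_loc <- softmax_rows(f$logits_loc)
      p_rot <- softmax_rows(f$logits_rot)
      i1 <- cbind(seq_len(B), batch$act[mb, 1])
      i2 <- cbind(seq_len(B), batch$act[mb, 2])
      logp_new <- log(pmax(p_loc[i1], 1e-12)) + log(pmax(p_rot[i2], 1e-12))
      ratio <- exp(logp_new - batch$logp[mb])
      a <- adv_n[mb]
      unclipped <- ratio * a
      clipped <- pmin(pmax(ratio, 1 - cfg$clip), 1 + cfg$clip) * a
      use <- unclipped <= clipped          # gradient flows where min = unclipped
      surr_coef <- ifelse(use, ratio * a, 0) # d surr / d logp_new
      # entropy gradients
      H_loc <- -rowSums(p_loc * log(pmax(p_loc, 1e-12)))
      H_rot <- -rowSums(p_rot * log(pmax(p_rot, 1e-12)))
      dH_loc <- -p_loc * (log(pmax(p_loc, 1e-12)) + H_loc)
      dH_rot <- -p_rot * (log(pmax(p_rot, 1e-12)) + H_rot)
      oh_loc <- matrix(0, B, 2); oh_loc[i1] <- 1
      oh_rot <- matrix(0, B, 3); oh_rot[i2] <- 1
      # minimize: -(surrogate + entropy) + value_coef * MSE
      dlog_loc <- oh_loc - p_loc
      dlog_rot <- oh_rot - p_rot
      dlogits_loc <- (-surr_coef * dlog_loc - cfg$entropy_coef * dH_loc) / B
      dlogits_rot <- (-surr_coef * dlog_rot - cfg$entropy_coef * dH_rot) / B
      dval <- matrix(cfg$value_coef * 2 * (f$value - ret[mb]) / B, B, 1)
      blo <- bwd_layer(brain$head_loc, f$caches$loc, dlogits_loc)
      bro <- bwd_layer(brain$head_rot, f$caches$rot, dlogits_rot)
      bva <- bwd_layer(brain$head_val, f$caches$val, dval)
      dfeat <- blo$dX + bro$dX + bva$dX
      bac <- bwd_layer(brain$act_lrelu, f$caches$act, dfeat)
      tb <- net_backward(brain$trunk, f$caches$trunk, bac$dX)
      net_apply_grads(brain$trunk, tb$grads, lr)
      brain$head_loc <- head_apply(brain, "head_loc", blo$grads, lr)
      brain$head_rot <- head_apply(brain, "head_rot", bro$grads, lr)
      brain$head_val <- head_apply(brain, "head_val", bva$grads, lr)
      diag <- list(surrogate = mean(pmin(unclipped, clipped)),
                   value_mse = mean((f$value - ret[mb])^2),
                   entropy = mean(H_loc + H_rot))
    }
  }
  invisible(diag)
}
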