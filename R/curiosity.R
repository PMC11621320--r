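#' Create an intrinsic-motivation (curiosity) module
#'
#' Four algorithms are available, each producing a nonnegative scalar
#' reward per transition from raw observations and co-trained online with
#' the policy:
#'
#' * `"icm"` — intrinsic curiosity module: a learned encoder, an inverse
#'   dynamics model predicting the action from consecutive encodings (one
#'   categorical head per sub-action factor), and a forward dynamics model
#'   predicting the next encoding; reward = squared forward prediction
#'   error. The encoder is trained by the inverse loss only.
#' * `"icm_random"` — as ICM but the encoder is randomly initialized and
#'   frozen; there is no inverse model and only the forward model trains.
#' * `"rnd"` — random network distillation: a frozen random target encoder
#'   and a trained predictor; reward = squared error between predictor and
#'   target embeddings.
#' * `"crl"` — temporal contrastive curiosity: encoder plus projection
#'   network trained so consecutive observations embed nearby and
#'   temporally distant ones far apart; reward = 1 - cosine similarity of
#'   consecutive projected representations (bounded in `[0, 2]`).
#'
#' Raw squared-error rewards are scale-dependent across algorithms, so a
#' running standardization (division by the running standard deviation) is
#' applied before the policy sees them (`normalize = TRUE`); the overall
#' `strength` multiplier is applied last.
#'
#' @param algorithm one of `"icm"`, `"icm_random"`, `"rnd"`, `"crl"`
#' @param n_rays retina length of the observations
#' @param strength reward strength multiplier (> 0; 1 in normal rearing,
#'   0.001 in the curiosity-reduced ablation)
#' @param beta ICM loss weighting: `beta * forward + (1 - beta) * inverse`
#' @param normalize apply running reward standardization
#' @param crl_margin hinge margin on negative-pair cosine similarity
#' @param crl_min_gap minimum temporal separation (steps) of negative pairs
#' @return a `curiosity_module` object (mutable environment)
#' @export
curiosity_module <- function(algorithm = c("icm", "icm_random", "rnd", "crl"),
                             n_rays, strength = 1.0, beta = 0.2,
                             normalize = TRUE, crl_margin = 0.5,
                             crl_min_gap = 5L) {
  algorithm <- match.arg(algorithm)
  if (strength <= 0) stop("`strength` must be > 0")
  m <- new.env(parent = emptyenv())
  m$algorithm <- algorithm
  m$n_rays <- n_rays
  m$strength <- strength
  m$beta <- beta
  m$normalize <- normalize
  m$crl_margin <- crl_margin
  m$crl_min_gap <- as.integer(crl_min_gap)
  m$rms <- list(n = 0, mean = 0, m2 = 0)   # running moments of discounted return
  m$ret_acc <- 0                           # discounted-return accumulator
  m$gamma <- 0.99
  if (algorithm == "icm") {
    m$encoder <- build_encoder(n_rays)
    m$inverse <- net_new(list(layer_dense(256, 256), layer_lrelu()))
    m$inv_head_loc <- layer_dense(256, 2)
    m$inv_head_rot <- layer_dense(256, 3)
    m$forward <- net_new(list(layer_dense(128 + 5, 128), layer_lrelu(),
                              layer_dense(128, 128)))
  } else if (algorithm == "icm_random") {
    m$encoder <- build_encoder(n_rays, frozen = TRUE)
    m$forward <- net_new(list(layer_dense(128 + 5, 128), layer_lrelu(),
                              layer_dense(128, 128)))
  } else if (algorithm == "rnd") {
    m$target <- build_encoder(n_rays, frozen = TRUE)
    m$predictor <- build_encoder(n_rays)
  } else {
    m$encoder <- build_encoder(n_rays)
    m$projection <- net_new(list(layer_lrelu(), layer_dense(128, 128),
                                 layer_lrelu(), layer_dense(128, 128)))
  }
  class(m) <- "curiosity_module"
  m
}

#' @export
print.curiosity_module <- function(x, ...) {
  cat(sprintf("<curiosity_module> %s, strength %g, normalize %s\n",
              x$algorithm, x$strength, x$normalize))
  invisible(x)
}

onehot_actions <- function(act) {
  B <- nrow(act)
  A <- matrix(0, B, 5)
  A[cbind(seq_len(B), act[, 1])] <- 1
  A[cbind(seq_len(B), 2L + act[, 2])] <- 1
  A
}

row_cosine <- function(A, B) {
  num <- rowSums(A * B)
  den <- sqrt(rowSums(A^2)) * sqrt(rowSums(B^2))
  num / pmax(den, 1e-12)
}

#' Compute intrinsic rewards for a batch of transitions
#'
#' Raw (unnormalized, unscaled) rewards; all four algorithms return
#' nonnegative values, and the computation never changes module state, so
#' repeated calls on the same batch give identical rewards.
#'
#' @param m a [curiosity_module()]
#' @param batch list with `obs` (B x D matrix), `obs_next` (B x D), and
#'   `act` (B x 2 sub-action indices; needed for ICM variants)
#' @return numeric vector of B rewards, >= 0
#' @export
curiosity_rewards <- function(m, batch) {
  switch(m$algorithm,
    icm = icm_reward(batch, m)$reward,
    icm_random = icm_random_reward(batch, m),
    rnd = rnd_reward(batch$obs_next, m),
    crl = crl_reward(batch, m))
}

#' ICM reward and losses
#'
#' Encodes both observations, predicts the action with the inverse model
#' and the next encoding with the forward model; the per-transition reward
#' is the squared norm of the forward prediction error.
#'
#' @param batch transition batch (see [curiosity_rewards()])
#' @param m an ICM [curiosity_module()]
#' @return list with `reward` (vector), `forward_loss`, `inverse_loss`
#' @export
icm_reward <- function(batch, m) {
  stopifnot(m$algorithm == "icm")
  x <- net_forward(m$encoder, batch$obs)$out
  x1 <- net_forward(m$encoder, batch$obs_next)$out
  A <- onehot_actions(batch$act)
  xhat <- net_forward(m$forward, cbind(x, A))$out
  reward <- rowSums((xhat - x1)^2)
  g <- net_forward(m$inverse, cbind(x, x1))$out
  p_loc <- softmax_rows(fwd_layer(m$inv_head_loc, g)$out)
  p_rot <- softmax_rows(fwd_layer(m$inv_head_rot, g)$out)
  B <- nrow(x)
  inv_loss <- -mean(log(pmax(p_loc[cbind(seq_len(B), batch$act[, 1])], 1e-12))) -
               mean(log(pmax(p_rot[cbind(seq_len(B), batch$act[, 2])], 1e-12)))
  list(reward = reward, forward_loss = mean(reward), inverse_loss = inv_loss)
}

#' @describeIn icm_reward random-feature ICM reward (frozen encoder, no
#'   inverse model); returns the reward vector
#' @export
icm_random_reward <- function(batch, m) {
  stopifnot(m$algorithm == "icm_random", isTRUE(m$encoder$frozen))
  x <- net_forward(m$encoder, batch$obs)$out
  x1 <- net_forward(m$encoder, batch$obs_next)$out
  xhat <- net_forward(m$forward, cbind(x, onehot_actions(batch$act)))$out
  rowSums((xhat - x1)^2)
}

#' @param obs_batch B x D matrix of observations
#' @describeIn icm_reward random network distillation reward: squared error
#'   between predictor and frozen-target embeddings
#' @export
rnd_reward <- function(obs_batch, m) {
  stopifnot(m$algorithm == "rnd", isTRUE(m$target$frozen))
  ft <- net_forward(m$target, obs_batch)$out
  fp <- net_forward(m$predictor, obs_batch)$out
  rowSums((fp - ft)^2)
}

#' @describeIn icm_reward contrastive curiosity reward: 1 - cosine
#'   similarity of consecutive projected representations (in `[0, 2]`)
#' @export
crl_reward <- function(batch, m) {
  stopifnot(m$algorithm == "crl")
  z <- net_forward(m$projection, net_forward(m$encoder, batch$obs)$out)$out
  z1 <- net_forward(m$projection, net_forward(m$encoder, batch$obs_next)$out)$out
  1 - row_cosine(z, z1)
}

#' Scale a reward batch
#'
#' Elementwise multiplication by a positive strength; preserves the
#' ordering of transitions by reward.
#'
#' @param r reward vector
#' @param strength positive scalar
#' @return scaled rewards
#' @export
scale_rewards <- function(r, strength) {
  if (strength <= 0) stop("`strength` must be > 0")
  r * strength
}

# Running standardization used before PPO: rewards are divided by the
# running standard deviation of the discounted return they induce, so that
# value-regression targets stay O(1) across algorithms with very different
# raw reward scales.
normalize_rewards <- function(m, r) {
  if (!m$normalize) return(r)
  s <- m$rms
  acc <- m$ret_acc
  for (v in r) {   # Welford on the streamed discounted return
    acc <- m$gamma * acc + v
    s$n <- s$n + 1
    d <- acc - s$mean
    s$mean <- s$mean + d / s$n
    s$m2 <- s$m2 + d * (acc - s$mean)
  }
  m$rms <- s
  m$ret_acc <- acc
  sd_run <- if (s$n > 1) sqrt(s$m2 / (s$n - 1)) else 1
  r / max(sd_run, 1e-8)
}

#' Rewards as seen by the policy (normalized and strength-scaled)
#'
#' @inheritParams curiosity_rewards
#' @return reward vector after running standardization (if enabled) and
#'   strength scaling
#' @export
shaped_rewards <- function(m, batch) {
  scale_rewards(normalize_rewards(m, curiosity_rewards(m, batch)), m$strength)
}

# gradient of 1 - cos(a, b) wrt a (rowwise)
dcos_da <- function(A, B) {
  na <- pmax(sqrt(rowSums(A^2)), 1e-12)
  nb <- pmax(sqrt(rowSums(B^2)), 1e-12)
  cs <- rowSums(A * B) / (na * nb)
  B / (na * nb) - cs * A / na^2
}

#' One gradient step on a curiosity module's own loss
#'
#' Dispatches on the algorithm: ICM minimizes the weighted sum of forward
#' and inverse losses (the encoder receives only inverse-loss gradients);
#' random-feature ICM trains the forward model alone; RND trains the
#' predictor toward the frozen target; CRL minimizes a margin-based
#' temporal contrastive loss with negatives drawn at least `crl_min_gap`
#' steps away in the batch. Frozen components are untouched.
#'
#' @param m a [curiosity_module()]
#' @param batch transition batch (rows in within-episode temporal order for
#'   CRL)
#' @param lr learning rate (0 makes the update a no-op)
#' @return invisibly, the scalar loss of the step
#' @export
update_module <- function(m, batch, lr = 1e-3) {
  B <- nrow(batch$obs)
  if (B < 1) stop("empty batch")
  loss <- switch(m$algorithm,
    icm = {
      ex <- net_forward(m$encoder, batch$obs, keep_cache = TRUE)
      ex1 <- net_forward(m$encoder, batch$obs_next, keep_cache = TRUE)
      A <- onehot_actions(batch$act)
      # forward model on detached features
      fin <- cbind(ex$out, A)
      ff <- net_forward(m$forward, fin, keep_cache = TRUE)
      diff <- ff$out - ex1$out
      fwd_loss <- mean(rowSums(diff^2))
      dfwd <- m$beta * 2 * diff / B
      fb <- net_backward(m$forward, ff$caches, dfwd)
      # inverse model trains encoder
      gin <- cbind(ex$out, ex1$out)
      gg <- net_forward(m$inverse, gin, keep_cache = TRUE)
      lo <- fwd_layer(m$inv_head_loc, gg$out)
      ro <- fwd_layer(m$inv_head_rot, gg$out)
      p_loc <- softmax_rows(lo$out)
      p_rot <- softmax_rows(ro$out)
      oh_loc <- matrix(0, B, 2); oh_loc[cbind(seq_len(B), batch$act[, 1])] <- 1
      oh_rot <- matrix(0, B, 3); oh_rot[cbind(seq_len(B), batch$act[, 2])] <- 1
      inv_loss <- -mean(log(pmax(p_loc[oh_loc == 1], 1e-12))) -
                   mean(log(pmax(p_rot[oh_rot == 1], 1e-12)))
      w <- (1 - m$beta)
      dlo <- w * (p_loc - oh_loc) / B
      dro <- w * (p_rot - oh_rot) / B
      blo <- bwd_layer(m$inv_head_loc, lo$cache, dlo)
      bro <- bwd_layer(m$inv_head_rot, ro$cache, dro)
      gb <- net_backward(m$inverse, gg$caches, blo$dX + bro$dX)
      denc <- gb$dX[, 1:128, drop = FALSE]
      denc1 <- gb$dX[, 129:256, drop = FALSE]
      eb <- net_backward(m$encoder, ex$caches, denc)
      eb1 <- net_backward(m$encoder, ex1$caches, denc1)
      net_apply_grads(m$forward, fb$grads, lr)
      net_apply_grads(m$inverse, gb$grads, lr)
      m$inv_head_loc <- head_apply(m, "inv_head_loc", blo$grads, lr)
      m$inv_head_rot <- head_apply(m, "inv_head_rot", bro$grads, lr)
      net_apply_grads(m$encoder, grads_add(eb$grads, eb1$grads), lr)
      m$beta * fwd_loss + (1 - m$beta) * inv_loss
    },
    icm_random = {
      x <- net_forward(m$encoder, batch$obs)$out
      x1 <- net_forward(m$encoder, batch$obs_next)$out
      ff <- net_forward(m$forward, cbind(x, onehot_actions(batch$act)),
                        keep_cache = TRUE)
      diff <- ff$out - x1
      fb <- net_backward(m$forward, ff$caches, 2 * diff / B)
      net_apply_grads(m$forward, fb$grads, lr)
      mean(rowSums(diff^2))
    },
    rnd = {
      ft <- net_forward(m$target, batch$obs_next)$out
      fp <- net_forward(m$predictor, batch$obs_next, keep_cache = TRUE)
      diff <- fp$out - ft
      pb <- net_backward(m$predictor, fp$caches, 2 * diff / B)
      net_apply_grads(m$predictor, pb$grads, lr)
      mean(rowSums(diff^2))
    },
    crl = {
      if (B <= m$crl_min_gap)
        stop("batch too small to draw temporally distant negatives")
      ex <- net_forward(m$encoder, batch$obs, keep_cache = TRUE)
      ex1 <- net_forward(m$encoder, batch$obs_next, keep_cache = TRUE)
      pz <- net_forward(m$projection, ex$out, keep_cache = TRUE)
      pz1 <- net_forward(m$projection, ex1$out, keep_cache = TRUE)
      z <- pz$out; z1 <- pz1$out
      # negatives: rows shifted by a random gap >= crl_min_gap (wrapped)
      gap <- sample(m$crl_min_gap:(B - 1), 1)
      jn <- ((seq_len(B) - 1 + gap) %% B) + 1
      zn <- z[jn, , drop = FALSE]
      cos_neg <- row_cosine(z, zn)
      act <- cos_neg > m$crl_margin
      pos_loss <- mean(1 - row_cosine(z, z1))
      neg_loss <- mean(pmax(cos_neg - m$crl_margin, 0))
      # d/dz of positive term
      dz <- -dcos_da(z, z1) / B
      dz1 <- -dcos_da(z1, z) / B
      # d/dz of hinge on negatives (both anchor and partner roles)
      if (any(act)) {
        dn_anchor <- dcos_da(z, zn); dn_anchor[!act, ] <- 0
        dn_partner <- dcos_da(zn, z); dn_partner[!act, ] <- 0
        dz <- dz + dn_anchor / B
        # scatter partner gradients back to their source rows
        dz_part <- matrix(0, B, ncol(z))
        dz_part[jn, ] <- dn_partner
        dz <- dz + dz_part / B
      }
      bz <- net_backward(m$projection, pz$caches, dz)
      bz1 <- net_backward(m$projection, pz1$caches, dz1)
      eb <- net_backward(m$encoder, ex$caches, bz$dX)
      eb1 <- net_backward(m$encoder, ex1$caches, bz1$dX)
      net_apply_grads(m$projection, grads_add(bz$grads, bz1$grads), lr)
      net_apply_grads(m$encoder, grads_add(eb$grads, eb1$grads), lr)
      pos_loss + neg_loss
    })
  invisible(loss)
}

# Adam update for a bare head layer stored in the module environment
head_apply <- function(m, name, grads, lr) {
  ly <- m[[name]]
  st_name <- paste0(name, "_adam")
  st <- m[[st_name]]
  if (is.null(st)) st <- list(mW = ly$W * 0, vW = ly$W * 0,
                              mb = ly$b * 0, vb = ly$b * 0, t = 0L)
  if (lr > 0) {
    st$t <- st$t + 1L
    b1 <- 0.9; b2 <- 0.999
    st$mW <- b1 * st$mW + (1 - b1) * grads$W
    st$vW <- b2 * st$vW + (1 - b2) * grads$W^2
    st$mb <- b1 * st$mb + (1 - b1) * grads$b
    st$vb <- b2 * st$vb + (1 - b2) * grads$b^2
    ly$W <- ly$W - lr * (st$mW / (1 - b1^st$t)) / (sqrt(st$vW / (1 - b2^st$t)) + 1e-8)
    ly$b <- ly$b - lr * (st$mb / (1 - b1^st$t)) / (sqrt(st$vb / (1 - b2^st$t)) + 1e-8)
  }
  m[[st_name]] <- st
  ly
}
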