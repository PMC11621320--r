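#' Create a policy network
#'
#' The policy maps a ray-retina observation to a distribution over action
#' pairs. It consists of the shared visual encoder ([build_encoder()])
#' followed by one categorical output head per sub-action factor
#' (locomotion: 2 options; rotation: 3 options) and a scalar value head.
#'
#' @param n_rays retina length
#' @param action_set `"exp1"` or `"exp2"` (recorded as metadata; both sets
#'   have 2 x 3 sub-actions)
#' @return a `fish_policy` object (mutable environment)
#' @export
make_policy <- function(n_rays, action_set = "exp1") {
  p <- new.env(parent = emptyenv())
  p$trunk <- build_encoder(n_rays)
  p$act_lrelu <- layer_lrelu()
  p$head_loc <- layer_dense(128, 2)
  p$head_rot <- layer_dense(128, 3)
  p$head_val <- layer_dense(128, 1)
  p$n_rays <- n_rays
  p$action_set <- action_set
  p$frozen <- FALSE
  p$adam <- NULL
  p$t <- 0L
  class(p) <- "fish_policy"
  p
}

#' @export
print.fish_policy <- function(x, ...) {
  cat(sprintf("<fish_policy> %d-ray retina, action set %s%s\n", x$n_rays,
              x$action_set, if (x$frozen) " (frozen)" else ""))
  invisible(x)
}

policy_forward <- function(p, X, keep_cache = FALSE) {
  tr <- net_forward(p$trunk, X, keep_cache)
  ac <- fwd_layer(p$act_lrelu, tr$out)
  lo <- fwd_layer(p$head_loc, ac$out)
  ro <- fwd_layer(p$head_rot, ac$out)
  va <- fwd_layer(p$head_val, ac$out)
  list(logits_loc = lo$out, logits_rot = ro$out, value = va$out[, 1],
       caches = if (keep_cache) list(trunk = tr$caches, act = ac$cache,
                                     loc = lo$cache, rot = ro$cache,
                                     val = va$cache, feat = ac$out) else NULL)
}

#' Sample actions from a policy
#'
#' @param p a [make_policy()] object
#' @param X batch of flattened observations (rows; see [obs_to_vec()])
#' @param deterministic if `TRUE`, take the arg-max action of each head
#' @return list with `actions` (B x 2 matrix: locomotion, rotation),
#'   `logp`, `value`, and the head probabilities
#' @export
policy_act <- function(p, X, deterministic = FALSE) {
  f <- policy_forward(p, rbind(X))
  p_loc <- softmax_rows(f$logits_loc)
  p_rot <- softmax_rows(f$logits_rot)
  if (deterministic) {
    a_loc <- max.col(p_loc, ties.method = "first")
    a_rot <- max.col(p_rot, ties.method = "first")
  } else {
    a_loc <- sample_categorical_rows(p_loc)
    a_rot <- sample_categorical_rows(p_rot)
  }
  B <- nrow(p_loc)
  logp <- log(pmax(p_loc[cbind(seq_len(B), a_loc)], 1e-12)) +
          log(pmax(p_rot[cbind(seq_len(B), a_rot)], 1e-12))
  list(actions = cbind(a_loc, a_rot), logp = logp, value = f$value,
       p_loc = p_loc, p_rot = p_rot)
}

#' Freeze a policy for inference-only use
#'
#' Frozen policies reproduce their saved behavior exactly; any attempt to
#' update their weights raises an error (the analogue of a closed critical
#' period).
#'
#' @param p a [make_policy()] object
#' @return the frozen policy (a deep copy; the original is untouched)
#' @export
freeze_policy <- function(p) {
  q <- policy_clone(p)
  q$frozen <- TRUE
  q$trunk$frozen <- TRUE
  q
}

policy_clone <- function(p) {
  q <- make_policy(p$n_rays, p$action_set)
  q$trunk <- net_clone(p$trunk)
  q$head_loc <- p$head_loc
  q$head_rot <- p$head_rot
  q$head_val <- p$head_val
  q$frozen <- p$frozen
  q$trunk$frozen <- p$frozen
  q$adam <- p$adam
  q$t <- p$t
  q
}

policy_params <- function(p) {
  list(trunk = net_params(p$trunk),
       head_loc = list(W = p$head_loc$W, b = p$head_loc$b),
       head_rot = list(W = p$head_rot$W, b = p$head_rot$b),
       head_val = list(W = p$head_val$W, b = p$head_val$b))
}

# Scripted oracle: turn toward the side with more fish pixels. A retina ray
# shows a fish iff its channels are unequal (walls and background are
# achromatic). Used to validate the probe protocol independently of any
# learned policy.
#' @param n_rays retina length of the observations the policy will see
#' @param locomotion fixed locomotion sub-action emitted with every turn
#' @describeIn make_policy scripted pixel-counting policy; returns a
#'   function mapping an observation matrix to an action pair
#' @export
scripted_pixel_policy <- function(n_rays, locomotion = 2L) {
  mid <- n_rays / 2
  function(obs) {
    chroma <- apply(obs, 1, max) - apply(obs, 1, min)
    fishy <- chroma > 1e-9
    right <- sum(fishy[seq_len(floor(mid))])         # negative offsets first
    left <- sum(fishy[(floor(mid) + 1):n_rays])
    rot <- if (left > right) 1L else if (right > left) 3L else 2L
    c(locomotion, rot)
  }
}

# Scripted oracle: approach a target pigment (used for preference-assay
# validation). Turns toward the side with more target-colored rays and
# always moves.
#' @param target `"orange"` or `"blue"`
#' @describeIn make_policy scripted color-approach policy
#' @export
scripted_color_policy <- function(n_rays, target = "orange") {
  rgb <- color_rgb(target)[1, ]
  mid <- floor(n_rays / 2)
  function(obs) {
    # chromatic rays whose hue matches the target (dominant channel agrees)
    chroma <- apply(obs, 1, max) - apply(obs, 1, min)
    dom <- max.col(obs, ties.method = "first")
    hit <- chroma > 1e-9 & dom == which.max(rgb)
    right <- sum(hit[seq_len(mid)])
    left <- sum(hit[(mid + 1):n_rays])
    rot <- if (left > right) 1L else if (right > left) 3L else 2L
    c(1L, rot)
  }
}
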