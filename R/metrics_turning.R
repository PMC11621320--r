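#' Turning probabilities by neighbor configuration (probe protocol)
#'
#' For each configuration, renders `n_images` probe scenes
#' ([place_configuration_probe()]; `n1` neighbors in the left half-field,
#' `n2` in the right), feeds each image to the policy, samples one action,
#' and counts rotation sub-actions toward each side. "No rotation" actions
#' are excluded from the denominator by default (`none_weight = 0`); with
#' `none_weight = 0.5` they contribute half a count to each side.
#'
#' @param policy a frozen [make_policy()] or a function mapping an
#'   observation matrix to `c(locomotion, rotation)`
#' @param cfgs list of configurations (length-2 vectors or
#'   [configuration()]s)
#' @param n_images probe images per configuration (default 600)
#' @param env probe environment template (see
#'   [place_configuration_probe()])
#' @param none_weight weight of "no rotation" responses (0 = excluded)
#' @param seed integer seed
#' @param deterministic take arg-max actions instead of sampling
#' @return a `data.table` (turning table): `n1`, `n2`, `toward_n1`,
#'   `toward_n2`, `n_turns`, `n_images`, `p_n1`
#' @export
turning_probability_by_configuration <- function(policy, cfgs,
                                                 n_images = 600, env = NULL,
                                                 none_weight = 0,
                                                 seed = NULL,
                                                 deterministic = FALSE, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", length(cfgs))
  for (i in seq_along(cfgs)) {
    cfg <- as_configuration(cfgs[[i]])
    probes <- place_configuration_probe(cfg, n_images, env = env, ...)
    rot <- integer(n_images)
    for (k in seq_len(n_images)) {
      obs <- probes$obs[[k]]
      if (is.function(policy)) {
        rot[k] <- policy(obs)[2]
      } else {
        a <- policy_act(policy, obs_to_vec(obs), deterministic = deterministic)
        rot[k] <- a$actions[1, 2]
      }
    }
    left <- sum(rot == 1L)          # toward the n1 side (left half-field)
    right <- sum(rot == 3L)
    none <- sum(rot == 2L)
    t1 <- left + none_weight * none
    t2 <- right + none_weight * none
    denom <- t1 + t2
    out[[i]] <- data.table::data.table(
      n1 = cfg$n1, n2 = cfg$n2, toward_n1 = t1, toward_n2 = t2,
      n_turns = denom, n_images = n_images,
      p_n1 = if (denom > 0) t1 / denom else NA_real_)
  }
  data.table::rbindlist(out)
}

#' Developmental attraction-parameter curve from probe tables
#'
#' Applies [fit_ps()] to the measured probabilities `P(2|2:1)`, `P(0|0:3)`
#' and `P(0|0:1)` of each age.
#'
#' @param turning_by_age `data.table` with columns `age`, `n1`, `n2` and
#'   `p_n1` (probe tables) or `p_hat` (decision samples), containing at
#'   least the 2:1, 0:3 and 0:1 configurations per age
#' @return `data.table` with `age`, `p_s`, `sem`
#' @export
attraction_fit_by_age <- function(turning_by_age) {
  tb <- data.table::as.data.table(turning_by_age)
  if (!"p_n1" %in% names(tb) && "p_hat" %in% names(tb))
    data.table::setnames(tb, "p_hat", "p_n1")
  need <- function(a, n1_, n2_) {
    v <- tb[age == a & n1 == n1_ & n2 == n2_, p_n1]
    if (length(v) != 1) stop("missing configuration ", n1_, ":", n2_,
                             " for age ", a)
    v
  }
  ages <- sort(unique(tb$age))
  data.table::rbindlist(lapply(ages, function(a) {
    f <- fit_ps(need(a, 2, 1), need(a, 0, 3), need(a, 0, 1))
    data.table::data.table(age = a, p_s = f$p_s, sem = f$sem)
  }))
}
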