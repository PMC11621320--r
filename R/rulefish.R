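#' Parameters of the rule-based attraction model
#'
#' The rule-based model describes shoaling with a single behavioral
#' parameter `p_s`, the fraction of time a fish spends in interaction. At
#' each decision epoch a focal fish either (with probability `p_s`) turns
#' toward one uniformly chosen neighbor, or (with probability `1 - p_s`)
#' turns to a uniformly random side. With `N1` neighbors on one side of the
#' focal axis and `N2` on the other, the probability of choosing the `N1`
#' side is therefore
#' \deqn{P(N_1 | N_1{:}N_2) = p_s \frac{N_1}{N_1+N_2} + (1-p_s)\frac{1}{2}.}
#'
#' Trajectory-level kinematics (speed, decision rate, turn magnitude) are
#' conventions of this implementation; only the decision-level probabilities
#' are fixed by the model.
#'
#' @param p_s attraction parameter in `[0, 1]`
#' @param decision_interval steps between turn decisions (>= 1)
#' @param speed swimming speed, tank units per step (> 0)
#' @param turn_step turn magnitude per decision, degrees
#' @param seed optional integer seed stored with the parameters
#' @return an object of class `rule_params`
#' @export
rule_params <- function(p_s, decision_interval = 5L, speed = 0.1,
                        turn_step = 30, seed = NULL) {
  if (!is.numeric(p_s) || length(p_s) != 1 || is.na(p_s) || p_s < 0 || p_s > 1)
    stop("`p_s` must be a single probability in [0, 1]")
  if (decision_interval < 1) stop("`decision_interval` must be >= 1")
  if (speed <= 0) stop("`speed` must be positive")
  structure(list(p_s = p_s, decision_interval = as.integer(decision_interval),
                 speed = speed, turn_step = turn_step, seed = seed),
            class = "rule_params")
}

#' @export
print.rule_params <- function(x, ...) {
  cat(sprintf("<rule_params> p_s = %.3f, decide every %d steps, speed %.3g u/step, turn %.3g deg\n",
              x$p_s, x$decision_interval, x$speed, x$turn_step))
  invisible(x)
}

#' Neighbor configuration N1:N2
#'
#' A configuration counts the neighbors visible on each side of a focal
#' fish's optical axis: `n1` on one side and `n2` on the other. At least one
#' neighbor must be present.
#'
#' @param n1,n2 nonnegative neighbor counts, `n1 + n2 >= 1`
#' @return an object of class `fish_configuration`
#' @export
configuration <- function(n1, n2) {
  if (n1 < 0 || n2 < 0 || n1 + n2 < 1)
    stop("invalid configuration: need n1 >= 0, n2 >= 0, n1 + n2 >= 1")
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2)),
            class = "fish_configuration")
}

as_configuration <- function(cfg) {
  if (inherits(cfg, "fish_configuration")) return(cfg)
  if (is.numeric(cfg) && length(cfg) == 2) return(configuration(cfg[1], cfg[2]))
  stop("cannot interpret object as a configuration")
}

#' Side-choice probability under the attraction rule
#'
#' Closed-form probability that a focal fish with `n1` neighbors on one side
#' and `n2` on the other chooses the `n1` side:
#' `p_s * n1/(n1+n2) + (1 - p_s)/2`. The complementary probability (choosing
#' the `n2` side) is one minus this value.
#'
#' @param cfg a [configuration()], or a length-2 vector `c(n1, n2)`
#' @param p_s attraction parameter in `[0, 1]` (may be a vector)
#' @return probability of choosing the `n1` side, vectorized over `p_s`
#' @examples
#' interaction_rule_probability(configuration(1, 2), 0.54)  # 0.41
#' interaction_rule_probability(c(0, 3), 0.47)              # 0.265
#' @export
interaction_rule_probability <- function(cfg, p_s) {
  cfg <- as_configuration(cfg)
  if (any(p_s < 0 | p_s > 1)) stop("`p_s` must lie in [0, 1]")
  p_s * cfg$n1 / (cfg$n1 + cfg$n2) + (1 - p_s) / 2
}

#' Parameter-free prediction linking the 0:3 and 1:2 configurations
#'
#' In groups of four fish the attraction rule implies a relation between the
#' turning probabilities of the two possible neighbor configurations that
#' does not depend on `p_s`:
#' `P(1 | 1:2) = 1/3 + P(0 | 0:3) / 3`.
#'
#' @param p003 probability of turning to the empty side in a 0:3
#'   configuration
#' @return predicted probability of turning to the 1-fish side in a 1:2
#'   configuration
#' @export
predicted_P112 <- function(p003) {
  if (any(p003 < 0 | p003 > 1)) stop("`p003` must lie in [0, 1]")
  1 / 3 + p003 / 3
}

#' Sample turn decisions under the attraction rule
#'
#' Draws `n` independent turn decisions per configuration using the
#' generative mechanism: with probability `p_s` a uniformly chosen neighbor
#' is approached (so its side is chosen), otherwise a fair coin picks the
#' side.
#'
#' @param cfgs a list of [configuration()]s (or length-2 vectors)
#' @param p_s attraction parameter
#' @param n decisions per configuration (>= 1)
#' @param seed optional integer seed
#' @return a `data.frame` with columns `n1`, `n2`, `toward_n1`, `toward_n2`,
#'   `n_samples`, `p_hat`
#' @export
sample_turn_decisions <- function(cfgs, p_s, n, seed = NULL) {
  if (length(cfgs) == 0) stop("`cfgs` must contain at least one configuration")
  if (n < 1) stop("`n` must be >= 1")
  if (p_s < 0 || p_s > 1) stop("`p_s` must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  cfgs <- lapply(cfgs, as_configuration)
  out <- lapply(cfgs, function(cfg) {
    interact <- runif(n) < p_s
    pick <- runif(n) < cfg$n1 / (cfg$n1 + cfg$n2)  # uniformly chosen neighbor
    coin <- runif(n) < 0.5
    toward1 <- ifelse(interact, pick, coin)
    data.frame(n1 = cfg$n1, n2 = cfg$n2,
               toward_n1 = sum(toward1), toward_n2 = sum(!toward1),
               n_samples = n, p_hat = mean(toward1))
  })
  do.call(rbind, out)
}

# Shared trajectory engine for the rule model and the independent-walker
# null. `p_s = 0` disables all interaction. Vectorized over fish; the step
# loop is the only serial part.
simulate_walkers_core <- function(n_fish, params, steps, arena,
                                  init_pos = NULL, init_heading = NULL,
                                  trial_id = 1L, age = 1L, color = "neutral") {
  stopifnot(is_arena(arena), steps >= 1)
  margin <- 0.5
  pos <- if (is.null(init_pos)) arena_sample_points(arena, n_fish, margin) else rbind(init_pos)
  heading <- if (is.null(init_heading)) runif(n_fish, 0, 360) else init_heading
  if (length(color) == 1) color <- rep(color, n_fish)
  di <- params$decision_interval
  ts <- params$turn_step
  xs <- matrix(NA_real_, steps, n_fish)
  ys <- matrix(NA_real_, steps, n_fish)
  hs <- matrix(NA_real_, steps, n_fish)
  for (s in seq_len(steps)) {
    if ((s - 1L) %% di == 0L) {
      if (params$p_s > 0 && n_fish >= 2) {
        interact <- runif(n_fish) < params$p_s
        # uniformly chosen neighbor (index among the other fish)
        j <- floor(runif(n_fish) * (n_fish - 1)) + 1L
        idx <- seq_len(n_fish)
        nb <- ifelse(j >= idx, j + 1L, j)
        bearing <- atan2(pos[nb, 2] - pos[, 2], pos[nb, 1] - pos[, 1]) * 180 / pi
        rel <- angle_diff(bearing, heading)
        side <- sign(rel)
        tie <- abs(rel) < 1 | abs(rel) > 179
        side[tie] <- sample(c(-1, 1), sum(tie), replace = TRUE)
        rand_side <- sample(c(-1, 1), n_fish, replace = TRUE)
        turn <- ifelse(interact, side, rand_side) * ts
      } else {
        turn <- sample(c(-1, 1), n_fish, replace = TRUE) * ts
      }
      heading <- wrap_heading(heading + turn)
    }
    th <- heading * pi / 180
    prop <- pos + params$speed * cbind(cos(th), sin(th))
    ref <- arena_reflect(arena, prop, heading, margin)
    pos <- ref$xy
    heading <- ref$heading_deg
    xs[s, ] <- pos[, 1]; ys[s, ] <- pos[, 2]; hs[s, ] <- heading
  }
  data.table::data.table(
    trial_id = trial_id, age = age,
    t_step = rep(seq_len(steps), times = n_fish),
    fish_id = rep(seq_len(n_fish), each = steps),
    color = rep(color, each = steps),
    x = as.vector(xs), y = as.vector(ys),
    heading_deg = as.vector(hs))
}

#' Simulate a group of rule-based fish
#'
#' Generates planar trajectories for `n_fish` fish following the attraction
#' rule: at each decision epoch each fish turns by `turn_step` degrees
#' toward the bearing of a uniformly chosen neighbor with probability
#' `p_s`, and otherwise turns by the same magnitude to a uniformly random
#' side. Fish move at constant speed and reflect off the arena walls.
#' Neighbors within 1 degree of dead ahead/behind are assigned a side
#' uniformly at random.
#'
#' @param n_fish number of fish (>= 2)
#' @param params a [rule_params()]
#' @param steps number of time steps (>= `decision_interval`)
#' @param arena an arena, default circular test arena of radius 16
#' @param trial_id,age identifiers stored in the output table
#' @param init_pos optional n x 2 matrix of starting positions
#' @return a trajectory `data.table` with columns `trial_id`, `age`,
#'   `t_step`, `fish_id`, `color`, `x`, `y`, `heading_deg`
#' @export
simulate_rule_group <- function(n_fish, params, steps, arena = arena_circle(16),
                                trial_id = 1L, age = 1L, init_pos = NULL) {
  if (n_fish < 2) stop("`n_fish` must be >= 2 for the rule model")
  if (steps < params$decision_interval)
    stop("`steps` must be >= `decision_interval`")
  if (!is.null(params$seed)) set.seed(params$seed)
  simulate_walkers_core(n_fish, params, steps, arena, init_pos = init_pos,
                        trial_id = trial_id, age = age)
}

#' Simulate independent random walkers (null model)
#'
#' Identical motion model to [simulate_rule_group()] with `p_s` forced to
#' zero: every decision is a uniformly random turn and fish never interact.
#' Used as the calibration null for the randomization significance test.
#'
#' @param n_fish number of walkers (>= 1)
#' @param steps number of time steps
#' @param arena an arena
#' @param seed optional integer seed
#' @param params optional [rule_params()] supplying kinematics (its `p_s`
#'   is ignored)
#' @param trial_id,age identifiers stored in the output table
#' @return a trajectory `data.table` (see [simulate_rule_group()])
#' @export
simulate_independent_walkers <- function(n_fish, steps, arena = arena_circle(16),
                                         seed = NULL, params = NULL,
                                         trial_id = 1L, age = 1L) {
  if (is.null(params)) params <- rule_params(0)
  params$p_s <- 0
  if (!is.null(seed)) set.seed(seed)
  simulate_walkers_core(n_fish, params, steps, arena,
                        trial_id = trial_id, age = age)
}
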