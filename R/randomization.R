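#' Randomized control trials for pair trajectories
#'
#' Destroys the temporal correlation between the two fish of a pair while
#' preserving each fish's marginal position distribution: the position of
#' the first fish at each time step of an episode is paired with the
#' position of the second fish at a randomly selected time step of a
#' different episode, and symmetrically for the second fish. Each seed
#' yields one randomized trial per original trial (both directions are
#' part of the same randomized trial), so `n_seeds` seeds produce
#' `n_seeds x` the original trial count.
#'
#' @param pair_traj trajectory table of one pair with at least two trials
#'   (episodes); exactly 2 fish per trial
#' @param n_seeds number of randomization seeds (default 20)
#' @param seed optional integer seed (`NULL` continues the current RNG
#'   stream)
#' @return a `data.table` of randomized trials with columns `control_id`,
#'   `source_trial`, `seed`, `direction`, `t_step`, `x1`, `y1`, `x2`, `y2`
#' @export
randomize_trials <- function(pair_traj, n_seeds = 20, seed = NULL) {
  traj <- data.table::as.data.table(pair_traj)
  trials <- sort(unique(traj$trial_id))
  if (length(trials) < 2)
    stop("randomization requires >= 2 episodes (no 'different episode' exists)")
  fish <- sort(unique(traj$fish_id))
  stopifnot(length(fish) == 2)
  if (!is.null(seed)) set.seed(seed)
  data.table::setorder(traj, trial_id, fish_id, t_step)
  xy <- lapply(trials, function(tr) lapply(fish, function(f) {
    s <- traj[trial_id == tr & fish_id == f]
    cbind(s$x, s$y)
  }))
  names(xy) <- as.character(trials)
  cid <- 0L
  n_ctl <- n_seeds * length(trials)
  res <- vector("list", n_ctl)
  for (sd_i in seq_len(n_seeds)) {
    for (ti in seq_along(trials)) {
      cid <- cid + 1L
      tr <- trials[ti]
      pool <- setdiff(seq_along(trials), ti)
      oth1 <- pool[sample.int(length(pool), 1)]
      oth2 <- pool[sample.int(length(pool), 1)]
      a1 <- xy[[ti]][[1]]; b1 <- xy[[oth1]][[2]]
      a2 <- xy[[ti]][[2]]; b2 <- xy[[oth2]][[1]]
      n1 <- nrow(a1); n2 <- nrow(a2)
      j1 <- sample.int(nrow(b1), n1, replace = TRUE)
      j2 <- sample.int(nrow(b2), n2, replace = TRUE)
      res[[cid]] <- list(
        control_id = rep(cid, n1 + n2), source_trial = rep(tr, n1 + n2),
        seed = rep(sd_i, n1 + n2), direction = rep(1:2, c(n1, n2)),
        t_step = c(seq_len(n1), seq_len(n2)),
        x1 = c(a1[, 1], a2[, 1]), y1 = c(a1[, 2], a2[, 2]),
        x2 = c(b1[j1, 1], b2[j2, 1]), y2 = c(b1[j1, 2], b2[j2, 2]))
    }
  }
  data.table::data.table(
    control_id = unlist(lapply(res, `[[`, "control_id")),
    source_trial = unlist(lapply(res, `[[`, "source_trial")),
    seed = unlist(lapply(res, `[[`, "seed")),
    direction = unlist(lapply(res, `[[`, "direction")),
    t_step = unlist(lapply(res, `[[`, "t_step")),
    x1 = unlist(lapply(res, `[[`, "x1")),
    y1 = unlist(lapply(res, `[[`, "y1")),
    x2 = unlist(lapply(res, `[[`, "x2")),
    y2 = unlist(lapply(res, `[[`, "y2")))
}

#' Mean distance of each randomized control trial
#'
#' @param controls output of [randomize_trials()]
#' @return numeric vector, one mean distance per control trial
#' @export
control_mean_distances <- function(controls) {
  controls <- data.table::as.data.table(controls)
  controls[, .(d = mean(sqrt((x1 - x2)^2 + (y1 - y2)^2))),
           by = control_id][order(control_id), d]
}

#' Randomization p-value for grouping
#'
#' Resampling significance of an experimental mean pair distance against
#' randomized controls: `draw` control values are drawn (with
#' replacement) and averaged, `resamples` times; the p-value is the
#' proportion of resampled means less than or equal to the experimental
#' value (ties count as <=).
#'
#' @param d_exp experimental mean distance (mean over pairs)
#' @param controls vector of control mean distances (protocol default: 200
#'   values = 20 seeds x 10 pairs)
#' @param resamples number of resampled means (default 10000)
#' @param draw values per resample (default 10, the number of pairs)
#' @param seed optional integer seed (`NULL` continues the current RNG
#'   stream)
#' @return p-value in `[0, 1]`
#' @export
randomization_pvalue <- function(d_exp, controls, resamples = 10000,
                                 draw = 10, seed = NULL) {
  if (length(controls) < draw)
    stop("need at least `draw` control values")
  if (!is.null(seed)) set.seed(seed)
  d <- colMeans(matrix(sample(controls, draw * resamples, replace = TRUE),
                       nrow = draw))
  mean(d <= d_exp)
}
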