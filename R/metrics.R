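#' Pairwise-distance development curve
#'
#' For each trial the mean over timesteps of the mean distance over all
#' unordered fish pairs is computed, expressed in body lengths; trials are
#' then averaged within each age (checkpoint), with the standard error of
#' the mean across trials.
#'
#' @param traj trajectory table (`trial_id, age, t_step, fish_id, color, x,
#'   y, heading_deg`)
#' @param body_length body length used as the distance unit (default 2
#'   tank units)
#' @return `data.table` with columns `age`, `mean_bl`, `sem`, `n_trials`
#' @export
pairwise_distance_curve <- function(traj, body_length = 2) {
  traj <- data.table::as.data.table(traj)
  if (traj[, data.table::uniqueN(fish_id)] < 2)
    stop("pairwise distances need at least 2 fish per trial")
  per_trial <- traj[, .(d = mean_pair_dist_by_step(x, y, fish_id, t_step)),
                    by = .(age, trial_id)]
  per_trial[, d := d / body_length]
  per_trial[, .(mean_bl = mean(d), sem = sd(d) / sqrt(.N), n_trials = .N),
            by = age][order(age)]
}

# mean over timesteps of mean pairwise distance for one trial
mean_pair_dist_by_step <- function(x, y, fish_id, t_step) {
  dt <- data.table::data.table(x = x, y = y, fish_id = fish_id, t = t_step)
  per_step <- dt[, {
    if (.N < 2) stop("pairwise distances need >= 2 fish per timestep")
    list(d = mean(dist(cbind(x, y))))
  }, by = t]
  mean(per_step$d)
}

#' Transform a neighbor position into the focal-fish frame
#'
#' Rigid transform placing the focal fish at the origin with the positive
#' y axis along its velocity vector; distances are preserved. Undefined
#' when the focal speed is zero.
#'
#' @param focal_xy focal position (length 2, or n x 2)
#' @param focal_vel focal velocity vector(s)
#' @param neighbor_xy neighbor position(s)
#' @return n x 2 matrix of relative positions (`NA` rows where the focal
#'   speed is zero)
#' @export
to_focal_frame <- function(focal_xy, focal_vel, neighbor_xy) {
  focal_xy <- rbind(focal_xy); focal_vel <- rbind(focal_vel)
  neighbor_xy <- rbind(neighbor_xy)
  sp <- sqrt(rowSums(focal_vel^2))
  ux <- focal_vel[, 1] / sp; uy <- focal_vel[, 2] / sp
  dx <- neighbor_xy[, 1] - focal_xy[, 1]
  dy <- neighbor_xy[, 2] - focal_xy[, 2]
  # +y along velocity, +x to the right of the velocity vector
  out <- cbind(dx * uy - dy * ux, dx * ux + dy * uy)
  out[sp == 0, ] <- NA_real_
  out
}

# long table of focal-frame rows for all ordered pairs: focal velocity from
# forward displacement; zero-speed rows excluded. Also carries the focal
# heading change at the decision step (for turning maps).
focal_frame_rows <- function(traj) {
  traj <- data.table::as.data.table(traj)[order(trial_id, fish_id, t_step)]
  traj[, `:=`(vx = data.table::shift(x, type = "lead") - x,
              vy = data.table::shift(y, type = "lead") - y,
              dhead = angle_diff(data.table::shift(heading_deg, type = "lead"),
                                 heading_deg)),
       by = .(trial_id, fish_id)]
  ids <- unique(traj$fish_id)
  out <- vector("list", 0)
  for (f in ids) {
    focal <- traj[fish_id == f]
    nb <- traj[fish_id != f, .(trial_id, t_step, nb_id = fish_id,
                               nx = x, ny = y)]
    j <- merge(nb, focal[, .(trial_id, age, t_step, x, y, vx, vy, dhead)],
               by = c("trial_id", "t_step"))
    rel <- to_focal_frame(cbind(j$x, j$y), cbind(j$vx, j$vy),
                          cbind(j$nx, j$ny))
    j[, `:=`(rel_x = rel[, 1], rel_y = rel[, 2], focal_id = f)]
    out[[length(out) + 1]] <- j[!is.na(rel_x)]
  }
  data.table::rbindlist(out)
}

#' Relative-position density map
#'
#' Normalized 2D histogram of neighbor positions in the focal-fish frame
#' (origin at the focal fish, +y along its velocity). Cells with fewer
#' than `min_count` observations are masked (`NA`) rather than zero
#' filled, and the density is normalized over unmasked cells.
#'
#' @param traj trajectory table
#' @param grid half-width of the square map, tank units
#' @param nbin bins per axis
#' @param min_count minimum observations per cell
#' @return list with `density` (nbin x nbin matrix, sums to 1 over
#'   unmasked cells), `counts`, `breaks`
#' @export
relative_position_histogram <- function(traj, grid = 10, nbin = 21,
                                        min_count = 20) {
  ff <- focal_frame_rows(traj)
  breaks <- seq(-grid, grid, length.out = nbin + 1)
  ix <- findInterval(ff$rel_x, breaks, rightmost.closed = TRUE)
  iy <- findInterval(ff$rel_y, breaks, rightmost.closed = TRUE)
  ok <- ix >= 1 & ix <= nbin & iy >= 1 & iy <= nbin
  counts <- matrix(0, nbin, nbin)
  tab <- table(factor(ix[ok], levels = 1:nbin), factor(iy[ok], levels = 1:nbin))
  counts[] <- as.numeric(tab)
  dens <- counts
  dens[counts < min_count] <- NA
  dens <- dens / sum(dens, na.rm = TRUE)
  list(density = dens, counts = counts, breaks = breaks)
}

#' @describeIn relative_position_histogram per-cell probability of turning
#'   right given the neighbor position; cells under `min_count` masked
#' @param turn_threshold heading-change magnitude (degrees/step) that
#'   counts as a turn
#' @export
turn_probability_map <- function(traj, grid = 10, nbin = 21, min_count = 20,
                                 turn_threshold = 0.5) {
  ff <- focal_frame_rows(traj)
  ff <- ff[!is.na(dhead) & abs(dhead) > turn_threshold]
  breaks <- seq(-grid, grid, length.out = nbin + 1)
  ix <- findInterval(ff$rel_x, breaks, rightmost.closed = TRUE)
  iy <- findInterval(ff$rel_y, breaks, rightmost.closed = TRUE)
  ok <- ix >= 1 & ix <= nbin & iy >= 1 & iy <= nbin
  right <- ff$dhead < 0   # negative heading change = clockwise = right
  cnt <- matrix(0, nbin, nbin); rgt <- matrix(0, nbin, nbin)
  tab_all <- table(factor(ix[ok], levels = 1:nbin), factor(iy[ok], levels = 1:nbin))
  tab_r <- table(factor(ix[ok & right], levels = 1:nbin),
                 factor(iy[ok & right], levels = 1:nbin))
  cnt[] <- as.numeric(tab_all); rgt[] <- as.numeric(tab_r)
  p <- rgt / cnt
  p[cnt < min_count] <- NA
  list(p_right = p, counts = cnt, breaks = breaks)
}

#' Probability of turning toward the neighbor's side
#'
#' For every decision step with a detected turn (heading-change magnitude
#' above `turn_threshold`), the neighbor's side is the sign of its bearing
#' in the focal frame and the turn side is the sign of the heading change;
#' the statistic is P(turn side = neighbor side | turn occurred), by age,
#' with the SEM over trials.
#'
#' @param traj trajectory table of pair trials
#' @param turn_threshold heading-change magnitude (degrees/step) counting
#'   as a turn
#' @return `data.table` with `age`, `p_toward`, `sem`, `n_trials` (ages
#'   with no detected turns are reported as `NA`)
#' @export
prob_turn_toward_neighbor <- function(traj, turn_threshold = 0.5) {
  ff <- focal_frame_rows(traj)
  ff <- ff[!is.na(dhead)]
  ff[, turned := abs(dhead) > turn_threshold]
  ff[, toward := (dhead > 0 & rel_x < 0) | (dhead < 0 & rel_x > 0)]
  # rel_x > 0 is the focal's right; dhead < 0 is a right turn
  per_trial <- ff[turned == TRUE & rel_x != 0,
                  .(p = mean(toward)), by = .(age, trial_id)]
  if (nrow(per_trial) == 0)
    return(data.table::data.table(age = integer(), p_toward = numeric(),
                                  sem = numeric(), n_trials = integer()))
  per_trial[, .(p_toward = mean(p), sem = sd(p) / sqrt(.N), n_trials = .N),
            by = age][order(age)]
}

#' Invert the attraction rule for one developmental age
#'
#' Closed-form inversions of the side-choice probability for the three
#' probe probabilities used in the developmental fit: from
#' `P(2|2:1) = 1/2 + p_s/6` follows `p_s = 6 (P(2|2:1) - 1/2)`; from
#' `P(0|0:3) = (1 - p_s)/2` and `P(0|0:1) = (1 - p_s)/2` follow
#' `p_s = 1 - 2 P`. Each inversion is clipped to `[0, 1]`; the estimate is
#' their mean with the SEM over the three values.
#'
#' @param P21 measured `P(2 | 2:1)`
#' @param P003 measured `P(0 | 0:3)`
#' @param P001 measured `P(0 | 0:1)`
#' @return list with `p_s` (mean), `sem`, `values` (the three clipped
#'   inversions)
#' @examples
#' fit_ps(0.59, 0.23, 0.23)$p_s  # 0.54
#' @export
fit_ps <- function(P21, P003, P001) {
  stopifnot(P21 >= 0, P21 <= 1, P003 >= 0, P003 <= 1, P001 >= 0, P001 <= 1)
  v <- c(6 * (P21 - 0.5), 1 - 2 * P003, 1 - 2 * P001)
  v <- pmin(pmax(v, 0), 1)
  list(p_s = mean(v), sem = sd(v) / sqrt(3), values = v)
}

#' Least-squares attraction-parameter fit
#'
#' Alternative to the closed-form inversion of [fit_ps()]: minimizes the
#' summed squared deviation of the measured probabilities from the rule's
#' predictions over `p_s` in `[0, 1]`.
#'
#' @inheritParams fit_ps
#' @return the least-squares `p_s`
#' @export
fit_ps_lsq <- function(P21, P003, P001) {
  obj <- function(p)
    (interaction_rule_probability(c(2, 1), p) - P21)^2 +
    (interaction_rule_probability(c(0, 3), p) - P003)^2 +
    (interaction_rule_probability(c(0, 1), p) - P001)^2
  stats::optimize(obj, c(0, 1))$minimum
}

#' Parameter-free scatter check of the four-fish prediction
#'
#' Residuals of measured `(P(0|0:3), P(1|1:2))` points from the
#' theoretical line `P(1|1:2) = 1/3 + P(0|0:3)/3`.
#'
#' @param turning `data.frame` with columns `age`, `P003`, `P112`
#' @return `data.table` with per-age residuals plus an `rms_residual`
#'   attribute
#' @export
eq2_scatter <- function(turning) {
  turning <- data.table::as.data.table(turning)
  stopifnot(all(c("P003", "P112") %in% names(turning)))
  turning[, residual := P112 - predicted_P112(P003)]
  data.table::setattr(turning, "rms_residual",
                      sqrt(mean(turning$residual^2)))
  turning[]
}
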