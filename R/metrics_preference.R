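#' Two-alternative forced-choice preference score
#'
#' Proportion of time the test fish spends strictly nearer the familiar
#' shoal center than the novel one (distance to the center of each shoal);
#' equidistant steps contribute half a count.
#'
#' @param traj trajectory table of the test fish (single fish)
#' @param familiar_center,novel_center shoal centers (length-2)
#' @return proportion in `[0, 1]`
#' @export
two_afc_score <- function(traj, familiar_center, novel_center) {
  traj <- data.table::as.data.table(traj)
  df <- sqrt((traj$x - familiar_center[1])^2 + (traj$y - familiar_center[2])^2)
  dn <- sqrt((traj$x - novel_center[1])^2 + (traj$y - novel_center[2])^2)
  mean((df < dn) + 0.5 * (df == dn))
}

#' Self-segregation scores
#'
#' For every fish and timestep, the mean distance to same-colored others
#' (in-group) and to differently colored others (out-group), averaged over
#' time and trials. A fish whose color has no other member gets `NA`
#' in-group distance.
#'
#' @param traj trajectory table with a `color` column and >= 2 colors
#' @return `data.table` with `fish_id`, `color`, `in_group`, `out_group`
#' @export
self_segregation_scores <- function(traj) {
  traj <- data.table::as.data.table(traj)
  if (traj[, data.table::uniqueN(color)] < 2)
    stop("self-segregation requires at least 2 colors")
  fish <- unique(traj[, .(fish_id, color)])
  out <- vector("list", nrow(fish))
  for (i in seq_len(nrow(fish))) {
    f <- fish$fish_id[i]; col <- fish$color[i]
    focal <- traj[fish_id == f, .(trial_id, t_step, fx = x, fy = y)]
    others <- traj[fish_id != f, .(trial_id, t_step, color, x, y)]
    j <- merge(others, focal, by = c("trial_id", "t_step"))
    j[, d := sqrt((x - fx)^2 + (y - fy)^2)]
    ing <- j[color == col, mean(d)]
    outg <- j[color != col, mean(d)]
    out[[i]] <- data.table::data.table(
      fish_id = f, color = col,
      in_group = if (is.nan(ing)) NA_real_ else ing,
      out_group = if (is.nan(outg)) NA_real_ else outg)
  }
  data.table::rbindlist(out)[order(fish_id)]
}

#' Preference significance tests
#'
#' One-sample t-test of per-trial 2AFC scores against chance (0.5) for
#' each fish, or a paired two-tailed t-test of in-group versus out-group
#' distances. P-values are uncorrected. With zero variance the test
#' statistic is degenerate; the p-value is then reported as the limit
#' case (0 if the mean differs from the null, 1 otherwise).
#'
#' @param scores for `type = "2afc"`: `data.frame` with `fish_id` and
#'   per-trial `score`; for `type = "segregation"`: `data.frame` with
#'   `fish_id` and per-trial `in_group`, `out_group`
#' @param type `"2afc"` or `"segregation"`
#' @param mu null value for the 2AFC test (default 0.5)
#' @return `data.table` with `fish_id`, `statistic`, `df`, `p_value`,
#'   `mean_score` (or mean paired difference)
#' @export
preference_tests <- function(scores, type = c("2afc", "segregation"),
                             mu = 0.5) {
  type <- match.arg(type)
  scores <- data.table::as.data.table(scores)
  test_one <- function(x, y = NULL) {
    if (length(x) < 2) stop("need at least 2 samples per fish")
    delta <- if (is.null(y)) x - mu else x - y
    if (sd(delta) == 0) {
      return(list(statistic = if (mean(delta) == 0) 0 else sign(mean(delta)) * Inf,
                  df = length(delta) - 1,
                  p_value = if (mean(delta) == 0) 1 else 0))
    }
    tt <- if (is.null(y)) t.test(x, mu = mu) else t.test(x, y, paired = TRUE)
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value)
  }
  if (type == "2afc") {
    scores[, {
      r <- test_one(score)
      list(statistic = r$statistic, df = r$df, p_value = r$p_value,
           mean_score = mean(score))
    }, by = fish_id]
  } else {
    scores[, {
      r <- test_one(out_group, in_group)  # positive statistic = in < out
      list(statistic = r$statistic, df = r$df, p_value = r$p_value,
           mean_score = mean(out_group - in_group))
    }, by = fish_id]
  }
}
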