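#' End-to-end collective-behavior pipeline
#'
#' Trains a population with the chosen curiosity algorithm, deploys frozen
#' checkpoint pairs in the circular test arena, and runs the analysis
#' suite: pairwise-distance development, turn-toward-neighbor probability,
#' probe-based turning tables for the 2-, 4- and 7-fish configurations,
#' the parameter-free 0:3 vs 1:2 scatter, the attraction-parameter fit per
#' age, and the randomization significance test at the final age.
#'
#' @param cfg a `run_config` from [preset()] (experiment 1)
#' @param algorithm curiosity algorithm
#' @param out_dir optional directory; when given, all tables are written
#'   as CSV and the resolved configuration as YAML
#' @param probe_ages checkpoint indices probed for turning tables
#'   (default: first, middle, last)
#' @param verbose print progress
#' @return list with `training`, `pair_traj`, `distance_curve`,
#'   `turn_toward`, `turning_tables`, `eq2`, `ps_fit`, `randomization`
#' @export
run_pipeline_exp1 <- function(cfg = preset("desk-exp1"), algorithm = "icm",
                              out_dir = NULL, probe_ages = NULL,
                              verbose = FALSE) {
  stopifnot(cfg$experiment == 1)
  env <- env_from_config(cfg$env)
  training <- train_population(env, algorithm, cfg$ppo, verbose = verbose)
  test_arena <- arena_circle(cfg$test$radius)
  pair_traj <- evaluate_checkpoint_pairs(
    training$checkpoints, arena = test_arena, n_pairs = cfg$test$n_pairs,
    trials = cfg$test$trials, steps_per_trial = cfg$test$steps_per_trial,
    env_args = list(action_set = cfg$env$action_set, n_rays = cfg$env$n_rays,
                    fov = cfg$env$fov),
    seed = cfg$seed + 1000L)
  dist_curve <- pairwise_distance_curve(pair_traj)
  turn_toward <- prob_turn_toward_neighbor(pair_traj)
  if (is.null(probe_ages))
    probe_ages <- unique(c(1, ceiling(cfg$ppo$n_checkpoints / 2),
                           cfg$ppo$n_checkpoints))
  probe_env <- tank_env(test_arena, n_fish = 1, colors = "orange",
                        action_set = cfg$env$action_set,
                        n_rays = cfg$env$n_rays, fov = cfg$env$fov)
  probe_cfgs <- list(c(1, 0), c(2, 1), c(0, 1), c(0, 3), c(1, 2),
                     c(3, 0), c(3, 3), c(4, 2), c(5, 1), c(6, 0))
  tt <- vector("list", 0)
  for (k in probe_ages) {
    cp <- training$checkpoints$checkpoints[[k]]
    pol <- freeze_policy(cp$policies[[1]])
    tb <- turning_probability_by_configuration(
      pol, probe_cfgs, n_images = cfg$analysis$n_probe_images,
      env = probe_env, seed = cfg$seed + 2000L + k)
    tb$age <- k
    tt[[length(tt) + 1]] <- tb
  }
  turning_tables <- data.table::rbindlist(tt)
  eq2 <- eq2_scatter(data.table::dcast(
    turning_tables[(n1 == 0 & n2 == 3) | (n1 == 1 & n2 == 2)],
    age ~ paste0("c", n1, n2), value.var = "p_n1")[,
      .(age, P003 = c03, P112 = c12)])
  ps_fit <- attraction_fit_by_age(turning_tables)
  # randomization test at the final age
  final_age <- max(pair_traj$age)
  fin <- pair_traj[age == final_age]
  pair_ids <- unique(fin$pair_id)
  d_pairs <- numeric(0)
  ctl <- numeric(0)
  for (pr in pair_ids) {
    pt <- fin[pair_id == pr]
    d_pairs <- c(d_pairs, pt[, mean_pair_dist_by_step(x, y, fish_id, t_step)])
    ctl <- c(ctl, control_mean_distances(
      randomize_trials(pt, n_seeds = cfg$analysis$rand_seeds,
                       seed = cfg$seed + 3000L + pr)))
  }
  d_exp <- mean(d_pairs)
  pval <- randomization_pvalue(d_exp, ctl, resamples = cfg$analysis$resamples,
                               draw = min(cfg$analysis$draw, length(ctl)),
                               seed = cfg$seed + 4000L)
  res <- list(training = training, pair_traj = pair_traj,
              distance_curve = dist_curve, turn_toward = turn_toward,
              turning_tables = turning_tables, eq2 = eq2, ps_fit = ps_fit,
              randomization = list(d_exp = d_exp, controls = ctl,
                                   p_value = pval))
  if (!is.null(out_dir)) write_exp1_outputs(res, cfg, out_dir)
  res
}

write_exp1_outputs <- function(res, cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_trajectories(res$pair_traj, file.path(out_dir, "pair_trajectories.csv"))
  data.table::fwrite(res$distance_curve, file.path(out_dir, "distance_curve.csv"))
  data.table::fwrite(res$turn_toward, file.path(out_dir, "turn_toward.csv"))
  data.table::fwrite(res$turning_tables, file.path(out_dir, "turning_tables.csv"))
  data.table::fwrite(res$eq2, file.path(out_dir, "eq2_scatter.csv"))
  data.table::fwrite(res$ps_fit, file.path(out_dir, "ps_fit.csv"))
  data.table::fwrite(res$training$log, file.path(out_dir, "training_log.csv"))
  yaml::write_yaml(list(preset = cfg$name, seed = cfg$seed,
                        p_value = res$randomization$p_value,
                        d_exp = res$randomization$d_exp),
                   file.path(out_dir, "summary.yaml"))
  invisible(out_dir)
}

#' Run 2AFC preference trials for a set of reared policies
#'
#' @param policies list of frozen policies (one per fish)
#' @param metadata rearing metadata (from [run_experiment3()])
#' @param trials test trials per fish
#' @param steps steps per trial
#' @param chamber_size side of the square test chamber
#' @param shoal_size fish per shoal
#' @param n_rays retina length (must match the policies)
#' @param seed integer seed
#' @return `data.table` with `fish_id`, `trial`, `score`
#' @export
run_2afc_trials <- function(policies, metadata, trials = 30, steps = 200,
                            chamber_size = 24, shoal_size = 11, n_rays = 32,
                            seed = 1L) {
  set.seed(seed)
  out <- vector("list", 0)
  for (i in seq_along(policies)) {
    fam <- metadata$familiar_color[i]
    nov <- setdiff(c("orange", "blue"), fam)
    for (tr in seq_len(trials)) {
      scene <- build_2afc_scene(fam, nov, shoal_size = shoal_size,
                                arena = arena_square(chamber_size),
                                test_color = metadata$color[i],
                                n_rays = n_rays)
      traj <- run_policy_episode(scene, policies[i], steps,
                                 trial_id = tr, reset = FALSE)
      out[[length(out) + 1]] <- data.table::data.table(
        fish_id = metadata$fish[i], trial = tr,
        score = two_afc_score(traj, attr(scene, "familiar_center"),
                              attr(scene, "novel_center")))
    }
  }
  data.table::rbindlist(out)
}

#' Run self-segregation trials
#'
#' All fish are spawned together near the chamber center with random
#' orientations and left to move freely; per trial and fish the mean
#' distance to in-group (same color) and out-group members is recorded.
#'
#' @inheritParams run_2afc_trials
#' @param trials number of trials
#' @param steps steps per trial
#' @param chamber_size side of the square chamber
#' @return `data.table` with `fish_id`, `color`, `trial`, `in_group`,
#'   `out_group`
#' @export
run_segregation_trials <- function(policies, metadata, trials = 30,
                                   steps = 200, chamber_size = 24,
                                   n_rays = 32, seed = 1L) {
  set.seed(seed)
  n <- length(policies)
  out <- vector("list", 0)
  for (tr in seq_len(trials)) {
    env <- tank_env(arena_square(chamber_size), n_fish = n,
                    colors = metadata$color, action_set = "exp2",
                    n_rays = n_rays)
    # spawn clustered at the center, random orientation, no overlap
    center <- arena_center(env$arena)
    repeat {
      ang <- runif(n, 0, 2 * pi)
      rad <- 4 * sqrt(runif(n))
      pos <- cbind(center[1] + rad * cos(ang), center[2] + rad * sin(ang))
      hd <- runif(n, 0, 360)
      dd <- capsule_pair_dists_cpp(pos, hd, env$body$half_len)
      if (min(dd[upper.tri(dd)]) >= 2 * env$body$radius) break
    }
    env$pos <- pos; env$heading <- hd; env$t <- 0L
    traj <- run_policy_episode(env, policies, steps, trial_id = tr,
                               reset = FALSE)
    sc <- self_segregation_scores(traj)
    sc[, `:=`(trial = tr)]
    data.table::setnames(sc, "fish_id", "body_id")
    sc[, fish_id := metadata$fish[body_id]]
    out[[length(out) + 1]] <- sc[, .(fish_id, color, trial, in_group, out_group)]
  }
  data.table::rbindlist(out)
}

#' End-to-end social-preference pipeline
#'
#' Rears fish (group mode and, when requested, the reared-separately and
#' curiosity-reduced arms), then runs the 2AFC and self-segregation tasks
#' with frozen policies and the preference significance tests.
#'
#' @param cfg a `run_config` from [preset()] (experiment 3)
#' @param algorithm curiosity algorithm
#' @param arms character subset of `c("group", "separate", "reduced")`
#' @param out_dir optional output directory for CSV tables
#' @param verbose print progress
#' @return named list per arm, each with `metadata`, `afc_scores`,
#'   `afc_tests`, `segregation`, `seg_tests`
#' @export
run_pipeline_exp3 <- function(cfg = preset("desk-exp3"), algorithm = "icm",
                              arms = c("group"), out_dir = NULL,
                              verbose = FALSE) {
  stopifnot(cfg$experiment == 3)
  cup <- arena_circle(cfg$env$radius)
  run_arm <- function(mode, strength) {
    reared <- run_experiment3(mode, strength = strength, cfg = cfg$ppo,
                              algorithm = algorithm,
                              fish_per_color = cfg$fish_per_color,
                              cup = cup, n_rays = cfg$env$n_rays)
    afc <- run_2afc_trials(reared$policies, reared$metadata,
                           trials = cfg$test$trials,
                           steps = cfg$test$steps_per_trial,
                           chamber_size = cfg$test$chamber_size,
                           shoal_size = cfg$test$shoal_size,
                           n_rays = cfg$env$n_rays, seed = cfg$seed + 7000L)
    seg <- run_segregation_trials(reared$policies, reared$metadata,
                                  trials = cfg$test$trials,
                                  steps = cfg$test$steps_per_trial,
                                  chamber_size = cfg$test$chamber_size,
                                  n_rays = cfg$env$n_rays,
                                  seed = cfg$seed + 8000L)
    list(metadata = reared$metadata, afc_scores = afc,
         afc_tests = preference_tests(afc, "2afc"),
         segregation = seg,
         seg_tests = preference_tests(seg, "segregation"))
  }
  res <- list()
  if ("group" %in% arms) res$group <- run_arm("group_reared", 1.0)
  if ("separate" %in% arms) res$separate <- run_arm("reared_separately", 1.0)
  if ("reduced" %in% arms) res$reduced <- run_arm("group_reared", 0.001)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (arm in names(res)) {
      data.table::fwrite(res[[arm]]$afc_scores,
                         file.path(out_dir, paste0(arm, "_2afc_scores.csv")))
      data.table::fwrite(res[[arm]]$segregation,
                         file.path(out_dir, paste0(arm, "_segregation.csv")))
    }
  }
  res
}
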