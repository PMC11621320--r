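#' Named run presets
#'
#' Presets bundle the environment, curiosity, PPO and analysis settings of
#' the three experiments at two scales. `full-*` presets use the original
#' protocol sizes (20 fish, 2000 episodes of 1000 steps, 10 pairs x 2
#' trials x 5000 steps of testing, 600 probe images, 20 x 10 = 200
#' randomized controls with 10,000 resamples). `desk-*` presets preserve
#' every protocol ratio — 20 checkpoints, paired testing, probe protocol,
#' both rearing modes — at sizes that run on a single CPU in minutes:
#' fewer fish, shorter episodes, a 32-ray retina, and proportionally
#' scaled control counts.
#'
#' @param name one of `"desk-exp1"`, `"desk-exp2"`, `"desk-exp3"`,
#'   `"full-exp1"`, `"full-exp2"`, `"full-exp3"`
#' @param seed integer seed stored in the preset
#' @return a run-configuration list (class `run_config`)
#' @export
preset <- function(name = c("desk-exp1", "desk-exp2", "desk-exp3",
                            "full-exp1", "full-exp2", "full-exp3"),
                   seed = 1L) {
  name <- match.arg(name)
  desk <- startsWith(name, "desk")
  expn <- sub(".*-exp", "", name)
  cfg <- list(name = name, experiment = as.integer(expn), seed = seed)
  if (expn == "1") {
    # the desk rearing tank shrinks with the population to preserve fish
    # density (20 fish / 1600 sq units vs 4 fish / 324 sq units)
    cfg$env <- list(arena = "square", size = if (desk) 18 else 40,
                    wall = "white",
                    n_fish = if (desk) 4 else 20, colors = "neutral",
                    action_set = "exp1", n_rays = if (desk) 32 else 64,
                    fov = 160)
    cfg$ppo <- ppo_config(
      episodes = if (desk) 300 else 2000,
      steps_per_episode = if (desk) 75 else 1000,
      epochs = if (desk) 6 else 3,
      seed = seed)
    cfg$test <- list(arena = "circle", radius = 16,
                     n_pairs = if (desk) 2 else 10,
                     trials = 2,
                     steps_per_trial = if (desk) 600 else 5000)
    cfg$analysis <- list(n_probe_images = if (desk) 200 else 600,
                         rand_seeds = 20,
                         resamples = if (desk) 2000 else 10000,
                         draw = if (desk) 4 else 10)
  } else if (expn == "2") {
    cfg$env <- list(arena = "square", size = if (desk) 28 else 40,
                    wall = "textured",
                    n_fish = if (desk) 8 else 16,
                    colors = c("orange", "blue"),
                    action_set = "exp2", n_rays = if (desk) 32 else 64,
                    fov = 160)
    cfg$ppo <- ppo_config(
      episodes = if (desk) 100 else 1000,
      steps_per_episode = if (desk) 75 else 1000,
      epochs = if (desk) 6 else 3,
      seed = seed)
    cfg$brains_per_group <- 4   # one brain controls 4 bodies
  } else {
    # rearing cup: ~6 body lengths radius (a 100 mL cup is a few
    # centimeters across; one body length is 2 tank units)
    cfg$env <- list(arena = "circle", radius = 12, wall = "white",
                    action_set = "exp2", n_rays = if (desk) 32 else 64,
                    fov = 160)
    cfg$fish_per_color <- if (desk) 2 else 4
    cfg$ppo <- ppo_config(
      episodes = if (desk) 200 else 2000,
      steps_per_episode = if (desk) 75 else 1000,
      epochs = if (desk) 6 else 3,
      seed = seed)
    cfg$test <- list(chamber_size = if (desk) 24 else 40,
                     shoal_size = 11,
                     trials = if (desk) 20 else 1000,
                     steps_per_trial = if (desk) 300 else 3000)
  }
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> %s (experiment %d, seed %d)\n", x$name,
              x$experiment, x$seed))
  invisible(x)
}

#' Load a run configuration from a YAML file
#'
#' The file must contain at least `preset:`; any further top-level keys
#' override the preset's entries (shallow merge per block).
#'
#' @param path YAML file
#' @return a `run_config`
#' @export
config_load <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$preset)) stop("config must name a `preset:`")
  cfg <- preset(y$preset, seed = if (is.null(y$seed)) 1L else as.integer(y$seed))
  for (key in setdiff(names(y), c("preset", "seed"))) {
    if (is.list(y[[key]]) && is.list(cfg[[key]]))
      cfg[[key]] <- utils::modifyList(cfg[[key]], y[[key]])
    else cfg[[key]] <- y[[key]]
  }
  cfg
}

env_from_config <- function(ecfg, n_fish = NULL, colors = NULL) {
  arena <- if (ecfg$arena == "square")
    arena_square(ecfg$size, ecfg$wall) else arena_circle(ecfg$radius, ecfg$wall)
  tank_env(arena,
           n_fish = if (is.null(n_fish)) ecfg$n_fish else n_fish,
           colors = if (is.null(colors)) ecfg$colors else colors,
           action_set = ecfg$action_set, n_rays = ecfg$n_rays,
           fov = ecfg$fov)
}
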