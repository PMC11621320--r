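#' Fish body geometry
#'
#' Bodies are stadium (2D capsule) colliders: a segment of total length 2
#' units inflated by radius 0.5, height 0.7 units (metadata only in the
#' plane). A fish's position is the center of its collider.
#'
#' @param color one of `"blue"`, `"orange"`, `"neutral"`
#' @return a list with fields `length`, `height`, `radius`, `half_len`,
#'   `color`
#' @export
fish_body <- function(color = "neutral") {
  list(length = 2, height = 0.7, radius = 0.5,
       half_len = 0.5,  # segment half-length: (length - 2*radius)/2
       color = match.arg(color, c("blue", "orange", "neutral")))
}

color_rgb <- function(color) {
  tab <- rbind(orange = c(1.0, 0.55, 0.10),
               blue = c(0.15, 0.35, 1.0),
               neutral = c(0.5, 0.5, 0.5))
  unname(tab[color, , drop = FALSE])
}

#' Create a planar multi-agent fish tank
#'
#' The tank holds `n_fish` controllable fish (capsule colliders, egocentric
#' vision) plus optional static scenery fish. Observations are panoramic ray
#' retinas: `n_rays` equal-angle rays spanning `fov` degrees, each carrying
#' an RGB intensity in `[0, 1]` (nearest object per ray; fish occlude each
#' other; walls close every ray; mild depth attenuation provides distance
#' cues). The renderer is exactly mirror-equivariant.
#'
#' Two discrete action sets are available, each a pair of sub-actions:
#' `"exp1"` = \{fast, slow\} x \{left, none, right\} and `"exp2"` =
#' \{forward, stay\} x \{left, none, right\}. Each rotation changes heading
#' by `turn_deg` (default 2 degrees); `"left"` is counterclockwise.
#'
#' @param arena an [arena_square()] or [arena_circle()]
#' @param n_fish number of controllable fish
#' @param colors color name(s), recycled to `n_fish`
#' @param action_set `"exp1"` (fast/slow) or `"exp2"` (forward/stay)
#' @param n_rays number of retina rays
#' @param fov field of view, degrees
#' @param speed_fast,speed_slow locomotion speeds, units/step (`"forward"`
#'   uses `speed_slow`; `"stay"` is 0)
#' @param turn_deg rotation per step, degrees
#' @param shade depth-attenuation coefficient of the renderer
#' @return a `tank_env` object (a mutable environment)
#' @export
tank_env <- function(arena = arena_square(40), n_fish = 4, colors = "neutral",
                     action_set = c("exp1", "exp2"), n_rays = 32, fov = 160,
                     speed_fast = 0.14, speed_slow = 0.07, turn_deg = 2,
                     shade = 0.05) {
  stopifnot(is_arena(arena), n_fish >= 1, n_rays >= 1, fov > 0)
  action_set <- match.arg(action_set)
  e <- new.env(parent = emptyenv())
  e$arena <- arena
  e$n_fish <- n_fish
  e$colors <- rep(colors, length.out = n_fish)
  e$action_set <- action_set
  e$n_rays <- as.integer(n_rays)
  e$fov <- fov
  # symmetric equal-angle ray offsets (degrees, positive = left/CCW)
  e$offsets <- fov * ((seq_len(n_rays) - 0.5) / n_rays - 0.5)
  e$speed_fast <- speed_fast
  e$speed_slow <- speed_slow
  e$turn_deg <- turn_deg
  e$shade <- shade
  e$body <- fish_body()
  e$pos <- matrix(NA_real_, n_fish, 2)
  e$heading <- rep(0, n_fish)
  e$t <- 0L
  e$scenery <- NULL   # data.frame(x, y, heading_deg, color) of static fish
  class(e) <- "tank_env"
  e
}

#' @export
print.tank_env <- function(x, ...) {
  cat(sprintf("<tank_env> %d fish, %s arena, action set %s, %d rays / %g deg fov\n",
              x$n_fish, x$arena$shape, x$action_set, x$n_rays, x$fov))
  invisible(x)
}

arena_code <- function(arena) {
  if (arena$shape == "square") list(type = 0L, par = arena$size)
  else list(type = 1L, par = arena$radius)
}

scenery_caps <- function(env) {
  if (is.null(env$scenery) || nrow(env$scenery) == 0)
    return(matrix(numeric(0), 0, 5))
  b <- env$body
  cbind(env$scenery$x, env$scenery$y, env$scenery$heading_deg,
        b$half_len, b$radius)
}

#' Reset a tank environment
#'
#' Randomizes positions and orientations of all fish: poses are sampled
#' i.i.d. uniformly over the arena interior (headings uniform over
#' `[0, 360)`) and re-sampled until no colliders overlap. The same seed
#' always reproduces the same initial poses.
#'
#' @param env a [tank_env()]
#' @param seed optional integer seed
#' @param max_tries placement attempts before giving up
#' @return invisibly, the list of initial observations (one `n_rays x 3`
#'   matrix per fish)
#' @export
env_reset <- function(env, seed = NULL, max_tries = 400) {
  if (!is.null(seed)) set.seed(seed)
  b <- env$body
  n <- env$n_fish
  sc <- scenery_caps(env)
  for (try in seq_len(max_tries)) {
    pos <- arena_sample_points(env$arena, n, margin = b$half_len + b$radius)
    heading <- runif(n, 0, 360)
    ok <- TRUE
    if (n > 1) {
      dd <- capsule_pair_dists_cpp(pos, heading, b$half_len)
      ok <- min(dd[upper.tri(dd)]) >= 2 * b$radius
    }
    if (ok && nrow(sc) > 0) {
      # against scenery: reuse pairwise kernel by stacking
      all_pos <- rbind(pos, sc[, 1:2, drop = FALSE])
      all_h <- c(heading, sc[, 3])
      dd <- capsule_pair_dists_cpp(all_pos, all_h, b$half_len)
      ok <- min(dd[seq_len(n), n + seq_len(nrow(sc)), drop = FALSE]) >= 2 * b$radius
    }
    if (ok) {
      env$pos <- pos
      env$heading <- heading
      env$t <- 0L
      return(invisible(env_observe(env)))
    }
  }
  stop("placement error: could not place ", n, " fish without collider overlap")
}

action_speeds <- function(env) {
  if (env$action_set == "exp1") c(env$speed_fast, env$speed_slow)
  else c(env$speed_slow, 0)
}

#' Apply a single action to an agent state
#'
#' The rotation sub-action changes the heading by `+turn_deg` (left,
#' counterclockwise), `-turn_deg` (right) or 0; the position then advances
#' by the locomotion speed along the new heading. Functional: returns the
#' new state without touching any environment.
#'
#' @param state list with fields `pos` (length-2) and `heading_deg`
#' @param locomotion 1 = fast/forward, 2 = slow/stay (meaning depends on
#'   `action_set`)
#' @param rotation 1 = left, 2 = none, 3 = right
#' @param action_set `"exp1"` or `"exp2"`
#' @param speed_fast,speed_slow,turn_deg kinematic constants
#' @return updated state list
#' @export
apply_action <- function(state, locomotion, rotation,
                         action_set = "exp1", speed_fast = 0.14,
                         speed_slow = 0.07, turn_deg = 2) {
  stopifnot(locomotion %in% 1:2, rotation %in% 1:3)
  dh <- c(turn_deg, 0, -turn_deg)[rotation]
  sp <- if (action_set == "exp1") c(speed_fast, speed_slow)[locomotion]
        else c(speed_slow, 0)[locomotion]
  h <- wrap_heading(state$heading_deg + dh)
  th <- h * pi / 180
  list(pos = state$pos + sp * c(cos(th), sin(th)), heading_deg = h)
}

#' Step a tank environment
#'
#' Applies one action pair per fish (rotation first, then translation along
#' the new heading), then resolves collisions: overlapping moves are cut
#' back along the rejected motion vector so that no two colliders overlap
#' and no collider crosses a wall. Headings are never altered by collision
#' resolution.
#'
#' @param env a [tank_env()]
#' @param actions n x 2 matrix (or data.frame) of sub-action indices:
#'   column 1 locomotion (1 = fast/forward, 2 = slow/stay), column 2
#'   rotation (1 = left, 2 = none, 3 = right)
#' @param observe if `TRUE` (default) return the new observations
#' @return list of observations per fish, or `NULL` if `observe = FALSE`
#' @export
env_step <- function(env, actions, observe = TRUE) {
  actions <- as.matrix(actions)
  stopifnot(nrow(actions) == env$n_fish)
  dh <- c(env$turn_deg, 0, -env$turn_deg)[actions[, 2]]
  sp <- action_speeds(env)[actions[, 1]]
  heading <- wrap_heading(env$heading + dh)
  th <- heading * pi / 180
  prop <- env$pos + sp * cbind(cos(th), sin(th))
  ac <- arena_code(env$arena)
  b <- env$body
  env$pos <- resolve_collisions_cpp(env$pos, prop, heading, b$half_len,
                                    b$radius, ac$type, ac$par, scenery_caps(env))
  env$heading <- heading
  env$t <- env$t + 1L
  if (observe) env_observe(env) else invisible(NULL)
}

all_caps <- function(env, exclude = 0L) {
  b <- env$body
  idx <- setdiff(seq_len(env$n_fish), exclude)
  caps <- if (length(idx) == 0) matrix(numeric(0), 0, 8) else
    cbind(env$pos[idx, 1], env$pos[idx, 2], env$heading[idx],
          b$half_len, b$radius, color_rgb(env$colors[idx]))
  if (!is.null(env$scenery) && nrow(env$scenery) > 0) {
    sc <- cbind(env$scenery$x, env$scenery$y, env$scenery$heading_deg,
                b$half_len, b$radius, color_rgb(env$scenery$color))
    caps <- rbind(caps, sc)
  }
  caps
}

#' Render the egocentric view of one fish
#'
#' Equal-angle ray casting over the field of view: each ray returns the
#' color of the nearest intersected object (another fish's body in its
#' color, otherwise the wall), attenuated with distance. The focal fish's
#' own body is not rendered.
#'
#' @param env a [tank_env()]
#' @param focal_id index of the focal fish
#' @return an `n_rays x 3` matrix of intensities in `[0, 1]`; row `i`
#'   corresponds to ray offset `env$offsets[i]` (positive offsets = left of
#'   the optical axis)
#' @export
render_egocentric <- function(env, focal_id = 1L) {
  stopifnot(focal_id >= 1, focal_id <= env$n_fish)
  ac <- arena_code(env$arena)
  wall <- c(1, 1, 1)
  render_rays_cpp(env$pos[focal_id, ], env$heading[focal_id], env$offsets,
                  all_caps(env, exclude = focal_id), ac$type, ac$par, wall,
                  as.integer(env$arena$wall_appearance == "textured"),
                  env$shade)
}

#' @rdname render_egocentric
#' @return `env_observe`: a list with one observation matrix per fish
#' @export
env_observe <- function(env) {
  lapply(seq_len(env$n_fish), function(i) render_egocentric(env, i))
}

#' Flatten an observation to a feature vector
#'
#' Rays are interleaved with channels (`ray1 R,G,B, ray2 R,G,B, ...`), the
#' layout expected by the network encoders.
#'
#' @param obs an `n_rays x 3` observation matrix
#' @return numeric vector of length `3 * n_rays`
#' @export
obs_to_vec <- function(obs) as.vector(t(obs))

#' Render a batch of configuration probe images
#'
#' Probe scenes implement the turning-probability protocol: the focal fish
#' is fixed at the arena center with a fixed heading, and `n1` neighbors
#' are placed uniformly in the left half-field, `n2` in the right
#' half-field (within the field of view and the probe view distance, no
#' collider overlap). Each scene is rendered from the focal camera. The
#' left side (positive ray offsets) is the `n1` side.
#'
#' @param cfg a [configuration()] or length-2 vector `c(n1, n2)`
#' @param n_images number of probe images (default 600)
#' @param env a [tank_env()] template supplying arena/retina parameters;
#'   default circular test arena of radius 16
#' @param view_dist maximum neighbor placement distance, units
#' @param min_dist minimum neighbor placement distance, units
#' @param seed optional integer seed
#' @param mirror if `TRUE`, reflect every scene about the optical axis
#'   (swaps the sides)
#' @param neighbor_color pigment of the placed neighbors
#' @return list with `obs` (list of `n_rays x 3` matrices), `cfg`, `side`
#'   (a character note that the n1 side is the left half-field)
#' @export
place_configuration_probe <- function(cfg, n_images = 600, env = NULL,
                                      view_dist = 12, min_dist = 2.5,
                                      seed = NULL, mirror = FALSE,
                                      neighbor_color = "orange") {
  cfg <- as_configuration(cfg)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(env)) env <- tank_env(arena_circle(16), n_fish = 1, colors = "orange")
  b <- env$body
  n_nb <- cfg$n1 + cfg$n2
  half_fov <- env$fov / 2
  center <- arena_center(env$arena)
  obs <- vector("list", n_images)
  # a mirrored probe draws the swapped configuration with the same random
  # stream, then reflects the whole scene about the optical axis, so it is
  # the exact mirror image of the unmirrored probe of the swapped
  # configuration under the same seed
  cfg_eff <- if (mirror) configuration(cfg$n2, cfg$n1) else cfg
  for (k in seq_len(n_images)) {
    for (try in 1:200) {
      # bearings: n1 in the left half-field (positive), n2 right (negative)
      bear <- c(runif(cfg_eff$n1, 2, half_fov - 2),
                -runif(cfg_eff$n2, 2, half_fov - 2))
      dist <- runif(n_nb, min_dist, view_dist)
      hd <- runif(n_nb, 0, 360)
      if (mirror) {
        bear <- -bear
        hd <- wrap_heading(-hd)
      }
      th <- bear * pi / 180
      xy <- cbind(center[1] + dist * cos(th), center[2] + dist * sin(th))
      all_pos <- rbind(center, xy)
      all_h <- c(0, hd)
      dd <- capsule_pair_dists_cpp(all_pos, all_h, b$half_len)
      if (n_nb == 0 || min(dd[upper.tri(dd)]) >= 2 * b$radius) break
      if (try == 200) stop("impossible probe placement for configuration ",
                           cfg$n1, ":", cfg$n2)
    }
    caps <- cbind(xy[, 1], xy[, 2], hd, b$half_len, b$radius,
                  color_rgb(rep(neighbor_color, n_nb)))
    ac <- arena_code(env$arena)
    obs[[k]] <- render_rays_cpp(center, 0, env$offsets, caps, ac$type, ac$par,
                                c(1, 1, 1),
                                as.integer(env$arena$wall_appearance == "textured"),
                                env$shade)
  }
  list(obs = obs, cfg = cfg, n1_side = "left")
}

#' Build a two-alternative forced-choice (2AFC) scene
#'
#' Constructs the social-preference test chamber: two static shoaling
#' groups of `shoal_size` fish each (one in the familiar pigment, one in
#' the novel pigment) at opposite ends of the chamber, with the test fish
#' spawned at the center facing a random direction. Which end holds the
#' familiar shoal is randomized per call.
#'
#' @param familiar_color,novel_color two distinct fish colors
#' @param shoal_size fish per shoal (default 11)
#' @param arena chamber arena (default 24 x 24 square)
#' @param test_color color of the test fish (defaults to the familiar
#'   pigment, i.e. the test fish's own group color)
#' @param n_rays,fov retina parameters of the test fish
#' @param seed optional integer seed
#' @return a [tank_env()] with one controllable fish and attributes
#'   `familiar_center` and `novel_center` (chamber coordinates)
#' @export
build_2afc_scene <- function(familiar_color, novel_color, shoal_size = 11,
                             arena = arena_square(24), test_color = familiar_color,
                             n_rays = 32, fov = 160, seed = NULL) {
  if (identical(familiar_color, novel_color))
    stop("familiar and novel pigments must differ")
  if (!is.null(seed)) set.seed(seed)
  env <- tank_env(arena, n_fish = 1, colors = test_color, action_set = "exp2",
                  n_rays = n_rays, fov = fov)
  center <- arena_center(arena)
  span <- if (arena$shape == "square") arena$size else 2 * arena$radius
  ends <- rbind(c(center[1] - 0.33 * span, center[2]),
                c(center[1] + 0.33 * span, center[2]))
  familiar_end <- sample(1:2, 1)
  # dense static shoal: one fish at the center surrounded by jittered rings
  # (shoal members may touch; they are render/collision scenery, not agents)
  place_shoal <- function(at, color) {
    n <- shoal_size
    ring_r <- c(0, rep(1.8, min(4, max(0, n - 1))),
                rep(3.2, max(0, n - 5)))[seq_len(n)]
    ring_a <- c(0, seq(0, 2 * pi, length.out = min(4, max(0, n - 1)) + 1)[-1],
                seq(pi / 6, 2 * pi + pi / 6,
                    length.out = max(0, n - 5) + 1)[-1])[seq_len(n)]
    xy <- cbind(at[1] + ring_r * cos(ring_a), at[2] + ring_r * sin(ring_a))
    xy <- xy + matrix(runif(2 * n, -0.3, 0.3), n, 2)
    # clamp inside the arena with a one-unit margin
    if (arena$shape == "square") {
      xy <- pmin(pmax(xy, 1), arena$size - 1)
    } else {
      r <- sqrt(rowSums(xy^2))
      out <- r > arena$radius - 1
      xy[out, ] <- xy[out, , drop = FALSE] * ((arena$radius - 1) / r[out])
    }
    data.frame(x = xy[, 1], y = xy[, 2], heading_deg = runif(n, 0, 360),
               color = color)
  }
  env$scenery <- rbind(place_shoal(ends[familiar_end, ], familiar_color),
                       place_shoal(ends[3 - familiar_end, ], novel_color))
  env$pos <- matrix(center, 1, 2)
  env$heading <- runif(1, 0, 360)
  env$t <- 0L
  attr(env, "familiar_center") <- ends[familiar_end, ]
  attr(env, "novel_center") <- ends[3 - familiar_end, ]
  env
}
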