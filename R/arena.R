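#' Arena specifications
#'
#' Arenas are flat (2D) tanks. Two shapes are supported: a square rearing
#' tank (side `size`, default 40 units) and a circular test arena (default
#' radius 16 units). The square arena spans `[0, size] x [0, size]`; the
#' circular arena is centered at the origin. A "cup" rearing environment is
#' simply a small circular arena.
#'
#' @param size side length of the square arena, tank units
#' @param radius radius of the circular arena, tank units
#' @param wall_appearance `"white"` or `"textured"` (procedurally textured
#'   walls used for the naturalistic variant)
#' @return an object of class `arena`
#' @export
arena_square <- function(size = 40, wall_appearance = "white") {
  stopifnot(size > 0)
  structure(list(shape = "square", size = size,
                 wall_appearance = match.arg(wall_appearance, c("white", "textured"))),
            class = "arena")
}

#' @rdname arena_square
#' @export
arena_circle <- function(radius = 16, wall_appearance = "white") {
  stopifnot(radius > 0)
  structure(list(shape = "circle", radius = radius,
                 wall_appearance = match.arg(wall_appearance, c("white", "textured"))),
            class = "arena")
}

#' @export
print.arena <- function(x, ...) {
  dim <- if (x$shape == "square") paste0(x$size, " x ", x$size) else paste0("radius ", x$radius)
  cat("<arena> ", x$shape, " (", dim, " units), ", x$wall_appearance, " walls\n", sep = "")
  invisible(x)
}

is_arena <- function(x) inherits(x, "arena")

#' Test whether points lie inside an arena
#'
#' @param arena an [arena_square()] or [arena_circle()]
#' @param xy n x 2 matrix of positions
#' @param margin required clearance from the wall (e.g. a collider radius)
#' @return logical vector of length n
#' @export
arena_contains <- function(arena, xy, margin = 0) {
  xy <- rbind(xy)
  if (arena$shape == "square") {
    lo <- margin; hi <- arena$size - margin
    xy[, 1] >= lo & xy[, 1] <= hi & xy[, 2] >= lo & xy[, 2] <= hi
  } else {
    sqrt(rowSums(xy^2)) <= arena$radius - margin
  }
}

#' Sample uniform positions in the arena interior
#'
#' @inheritParams arena_contains
#' @param n number of points
#' @return n x 2 matrix
#' @export
arena_sample_points <- function(arena, n, margin = 0) {
  if (arena$shape == "square") {
    lo <- margin; hi <- arena$size - margin
    stopifnot(hi > lo)
    cbind(runif(n, lo, hi), runif(n, lo, hi))
  } else {
    r <- (arena$radius - margin) * sqrt(runif(n))
    a <- runif(n, 0, 2 * pi)
    cbind(r * cos(a), r * sin(a))
  }
}

arena_center <- function(arena) {
  if (arena$shape == "square") c(arena$size / 2, arena$size / 2) else c(0, 0)
}

# Reflect proposed positions (and headings, degrees) back inside the arena.
# Square: mirror fold of position, heading mirrored about the crossed wall.
# Circle: position clamped to the boundary, velocity reflected about the
# inward normal. Vectorized over rows.
arena_reflect <- function(arena, xy, heading_deg, margin = 0) {
  xy <- rbind(xy)
  h <- heading_deg
  if (arena$shape == "square") {
    lo <- margin; hi <- arena$size - margin
    x <- xy[, 1]; y <- xy[, 2]
    bx <- x < lo | x > hi
    by <- y < lo | y > hi
    # single reflection suffices for per-step displacements << arena size
    x[x < lo] <- 2 * lo - x[x < lo]; x[x > hi] <- 2 * hi - x[x > hi]
    y[y < lo] <- 2 * lo - y[y < lo]; y[y > hi] <- 2 * hi - y[y > hi]
    h[bx] <- 180 - h[bx]
    h[by] <- -h[by]
    xy <- cbind(pmin(pmax(x, lo), hi), pmin(pmax(y, lo), hi))
  } else {
    rmax <- arena$radius - margin
    r <- sqrt(rowSums(xy^2))
    out <- r > rmax
    if (any(out)) {
      n_hat <- xy[out, , drop = FALSE] / r[out]         # wall normal
      th <- h[out] * pi / 180
      v <- cbind(cos(th), sin(th))
      v2 <- v - 2 * rowSums(v * n_hat) * n_hat          # specular reflection
      h[out] <- atan2(v2[, 2], v2[, 1]) * 180 / pi
      xy[out, ] <- xy[out, , drop = FALSE] * (rmax / r[out])
    }
  }
  list(xy = xy, heading_deg = wrap_heading(h))
}

#' Normalize headings to [0, 360)
#' @param h headings in degrees
#' @return headings wrapped to `[0, 360)`
#' @export
wrap_heading <- function(h) ((h %% 360) + 360) %% 360

# signed smallest angular difference a - b in (-180, 180]; NA-safe
angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  big <- which(d > 180)
  d[big] <- d[big] - 360
  d
}
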