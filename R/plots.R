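#' Plot helpers for the analysis tables
#'
#' All plots are built from the tabular outputs of the analysis functions
#' (never from in-memory simulation state), so figures are replayable from
#' saved CSVs.
#'
#' @param curve output of [pairwise_distance_curve()]
#' @return a ggplot object
#' @export
plot_distance_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = age, y = mean_bl)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = mean_bl - sem,
                                          ymax = mean_bl + sem)) +
    ggplot2::labs(x = "age (checkpoint)", y = "mean pair distance (BL)") +
    ggplot2::theme_classic()
}

#' @param eq2 output of [eq2_scatter()]
#' @describeIn plot_distance_curve measured (P(0|0:3), P(1|1:2)) points
#'   with the parameter-free theoretical line `y = 1/3 + x/3`
#' @export
plot_eq2_scatter <- function(eq2) {
  ggplot2::ggplot(eq2, ggplot2::aes(x = P003, y = P112, color = factor(age))) +
    ggplot2::geom_abline(slope = 1 / 3, intercept = 1 / 3, linetype = "dashed") +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "P(0 | 0:3)", y = "P(1 | 1:2)", color = "age") +
    ggplot2::theme_classic()
}

#' @param fit output of [attraction_fit_by_age()]
#' @describeIn plot_distance_curve attraction parameter p_s versus age
#' @export
plot_ps_curve <- function(fit) {
  ggplot2::ggplot(fit, ggplot2::aes(x = age, y = p_s)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = p_s - sem, ymax = p_s + sem)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "age (checkpoint)", y = expression(p[s])) +
    ggplot2::theme_classic()
}

#' @param hist output of [relative_position_histogram()]
#' @describeIn plot_distance_curve focal-frame neighbor density map
#' @export
plot_relative_density <- function(hist) {
  nb <- nrow(hist$density)
  mids <- (hist$breaks[-1] + hist$breaks[-(nb + 1)]) / 2
  df <- data.frame(x = rep(mids, times = nb), y = rep(mids, each = nb),
                   density = as.vector(hist$density))
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, fill = density)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "right of focal (units)", y = "ahead of focal (units)") +
    ggplot2::theme_classic()
}

#' @param tests output of [preference_tests()]
#' @describeIn plot_distance_curve per-fish preference bars
#' @export
plot_preference_bars <- function(tests) {
  ggplot2::ggplot(tests, ggplot2::aes(x = factor(fish_id), y = mean_score)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "fish", y = "preference score") +
    ggplot2::theme_classic()
}

utils::globalVariables(c("mean_bl", "sem", "P003", "P112", "p_s", "density",
                         "mean_score", "residual", "p_n1", "n1", "n2",
                         "dhead", "turned", "toward", "rel_x", "score",
                         "in_group", "out_group", "body_id", "c03", "c12",
                         "control_id", "vx", "vy", "nx", "ny", "t"))
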