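circle_points <- function(x0, y0, r, n = 120) {
  a <- seq(0, 2 * pi, length.out = n + 1)
  tibble::tibble(x = x0 + r * cos(a), y = y0 + r * sin(a))
}

#' Plot a litter snapshot
#'
#' Draws the arena boundary and each pup's body circle, coloured by body
#' temperature, with heading arrows.
#'
#' @param litter A [litter_state()].
#' @param r Pup radius; defaults to the litter's.
#' @param arena_radius Arena radius; defaults to the litter's.
#' @return A ggplot object.
#' @export
plot_litter <- function(litter, r = NULL, arena_radius = NULL) {
  if (is.null(r)) r <- litter_r(litter)
  if (is.null(arena_radius)) {
    arena_radius <- attr(litter, "arena_radius")
    if (is.null(arena_radius)) arena_radius <- 10 * r
  }
  bodies <- purrr::map_dfr(seq_len(nrow(litter)), function(i) {
    dplyr::mutate(circle_points(litter$x[i], litter$y[i], r),
                  pup = litter$pup[i], tb = litter$tb[i])
  })
  arrows <- dplyr::mutate(litter,
                          xend = .data$x + r * cos(.data$theta),
                          yend = .data$y + r * sin(.data$theta))
  ggplot2::ggplot() +
    ggplot2::geom_path(data = circle_points(0, 0, arena_radius),
                       ggplot2::aes(.data$x, .data$y), colour = "grey40") +
    ggplot2::geom_polygon(data = bodies,
                          ggplot2::aes(.data$x, .data$y,
                                       group = .data$pup, fill = .data$tb),
                          colour = "grey20", alpha = 0.8) +
    ggplot2::geom_segment(data = arrows,
                          ggplot2::aes(.data$x, .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          arrow = ggplot2::arrow(
                            length = ggplot2::unit(2, "mm"))) +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "Tb (°C)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (pup radii)", y = "y (pup radii)") +
    ggplot2::theme_minimal()
}

#' Plot a simulation
#'
#' `type = "snapshot"` draws the final litter configuration;
#' `type = "metrics"` shows the litter-mean exposed fraction and body
#' temperature over time.
#'
#' @param object A `"huddle_sim"`.
#' @param type `"snapshot"` or `"metrics"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.huddle_sim <- function(object, type = c("snapshot", "metrics"),
                                ...) {
  type <- match.arg(type)
  traj <- object$trajectory
  cfg <- object$config
  if (type == "snapshot") {
    last <- dplyr::filter(traj, .data$step == max(.data$step))
    litter <- litter_state(last$x, last$y, theta = last$theta, tb = last$tb,
                           r = cfg$r, arena_radius = cfg$arena_radius)
    return(plot_litter(litter) +
             ggplot2::ggtitle(sprintf("%s, t_a = %g, step %d",
                                      cfg$variant, cfg$t_a, max(traj$step))))
  }
  series <- traj |>
    dplyr::group_by(.data$step) |>
    dplyr::summarise(`huddling (1 - eta)` = mean(1 - .data$eta),
                     `mean Tb` = mean(.data$tb), .groups = "drop") |>
    tidyr::pivot_longer(-"step")
  ggplot2::ggplot(series,
                  ggplot2::aes(.data$step, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~name, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "simulation step", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a sweep summary
#'
#' Mean huddling (or another metric) against the swept parameter with
#' pup-level standard-error bars, optionally overlaying the analytic
#' super-organism prediction.
#'
#' @param object A `"huddle_sweep"`.
#' @param metric One of `"huddling"`, `"mean_tb"`, `"pup_flow"`,
#'   `"mean_subgroups"`.
#' @param superorg Optional [superorganism_params()]; when supplied (and the
#'   sweep is over `t_a`), the matching analytic curve is overlaid.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.huddle_sweep <- function(object, metric = c("huddling", "mean_tb",
                                                     "pup_flow",
                                                     "mean_subgroups"),
                                  superorg = NULL, ...) {
  metric <- match.arg(metric)
  s <- summarise_sweep(object)
  se_col <- paste0(metric, "_se")
  p <- ggplot2::ggplot(s, ggplot2::aes(.data$value, .data[[metric]])) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = attr(object, "param"), y = metric) +
    ggplot2::theme_minimal()
  if (se_col %in% names(s)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data[[metric]] - .data[[se_col]],
                   ymax = .data[[metric]] + .data[[se_col]]),
      width = 0
    )
  }
  if (!is.null(superorg) && identical(attr(object, "param"), "t_a") &&
      metric %in% c("huddling", "mean_tb")) {
    grid <- seq(min(s$value), max(s$value), length.out = 200)
    curves <- superorg_curves(grid, superorg)
    ycol <- if (metric == "huddling") "huddling" else "b"
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(value = curves$t_a, y = curves[[ycol]]),
      ggplot2::aes(.data$value, .data$y), colour = "firebrick"
    )
  }
  p
}
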