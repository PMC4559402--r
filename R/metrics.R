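# Accept either a huddle_sim or a bare trajectory tibble.
as_trajectory <- function(x) {
  if (inherits(x, "huddle_sim")) return(x$trajectory)
  stopifnot(is.data.frame(x),
            all(c("step", "pup", "eta") %in% names(x)))
  x
}

traj_r <- function(x, r = NULL) {
  if (!is.null(r)) return(r)
  cfg <- if (inherits(x, "huddle_sim")) x$config else attr(x, "config")
  if (is.null(cfg)) 1 else cfg$r
}

#' Huddling metric
#'
#' One minus the proportion of exposed thermometers, `1 - eta`, averaged
#' across pups and recorded (post-settle) time-steps. 0 means fully
#' dispersed; dense aggregation at low ambient temperatures gives values
#' around 0.5-0.6.
#'
#' @param x A `"huddle_sim"` or a trajectory tibble with columns `step`,
#'   `pup`, `eta`.
#' @param per_pup If `TRUE`, return the time-averaged value for each pup.
#' @return A scalar, or one value per pup.
#' @export
huddling_metric <- function(x, per_pup = FALSE) {
  traj <- as_trajectory(x)
  if (per_pup) {
    traj |>
      dplyr::group_by(.data$pup) |>
      dplyr::summarise(h = mean(1 - .data$eta), .groups = "drop") |>
      dplyr::pull("h")
  } else {
    mean(1 - traj$eta)
  }
}

#' Pup-flow metric
#'
#' The mean absolute rate of change of each pup's exposed fraction -- the
#' time-averaged `|d eta / d t|`, estimated per pup as
#' `(1 / (n_t - 1)) * sum_t |eta(t) - eta(t - 1)|` over consecutive recorded
#' steps and divided by the timestep `dt` -- averaged over pups. Pups that
#' stay put at the huddle centre or periphery (or stay isolated) contribute
#' zero; continual exchange of positions between the warm centre and cool
#' periphery raises the value. A huddling litter at low ambient temperature
#' holds a baseline around 0.013 per unit time under default parameters.
#'
#' `scale = "step"` returns the raw mean absolute per-step difference
#' (the per-time value multiplied by `dt`).
#'
#' @inheritParams huddling_metric
#' @param scale `"time"` (default; per unit simulation time) or `"step"`
#'   (per recorded step).
#' @param dt Timestep used for `scale = "time"`; defaults to the
#'   simulation's.
#' @return A scalar, or one value per pup.
#' @export
pup_flow <- function(x, per_pup = FALSE, scale = c("time", "step"),
                     dt = NULL) {
  scale <- match.arg(scale)
  traj <- as_trajectory(x)
  per <- traj |>
    dplyr::arrange(.data$pup, .data$step) |>
    dplyr::group_by(.data$pup) |>
    dplyr::summarise(flow = mean(abs(diff(.data$eta))), .groups = "drop")
  if (any(is.na(per$flow))) {
    stop("pup_flow needs at least 2 recorded steps", call. = FALSE)
  }
  if (scale == "time") {
    if (is.null(dt)) {
      cfg <- if (inherits(x, "huddle_sim")) x$config else attr(traj, "config")
      dt <- if (is.null(cfg)) 0.05 else cfg$dt
    }
    per$flow <- per$flow / dt
  }
  if (per_pup) per$flow else mean(per$flow)
}

#' Mean body temperature
#'
#' Mean of `tb` over pups and recorded time-steps.
#'
#' @inheritParams huddling_metric
#' @return Degrees C.
#' @export
mean_body_temperature <- function(x, per_pup = FALSE) {
  traj <- as_trajectory(x)
  if (per_pup) {
    traj |>
      dplyr::group_by(.data$pup) |>
      dplyr::summarise(tb = mean(.data$tb), .groups = "drop") |>
      dplyr::pull("tb")
  } else {
    mean(traj$tb)
  }
}

#' Count contact subgroups of a litter
#'
#' Number of connected components of the contact graph, with an edge between
#' pups whose centre distance is at most `2 r` (touching or overlapping
#' bodies, the same gate as the contact field).
#'
#' @param litter A [litter_state()].
#' @param r Pup radius; defaults to the litter's.
#' @return Integer component count.
#' @examples
#' count_subgroups(fixture_litter("two_clusters")) # 2
#' @export
count_subgroups <- function(litter, r = NULL) {
  if (is.null(r)) r <- litter_r(litter)
  d <- as.matrix(stats::dist(cbind(litter$x, litter$y)))
  adj <- d <= 2 * r
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$no
}

#' Per-step subgroup statistics of a trajectory
#'
#' @inheritParams huddling_metric
#' @param r Pup radius; defaults to the simulation's.
#' @return A tibble with one row per recorded step: `step`, `n_subgroups`
#'   (connected contact-graph components) and `largest` (largest component
#'   size, in pups).
#' @export
subgroup_series <- function(x, r = NULL) {
  traj <- as_trajectory(x)
  r <- traj_r(x, r)
  xm <- traj_matrix(traj, "x")
  ym <- traj_matrix(traj, "y")
  res <- cpp_component_stats(xm, ym, r)
  tibble::tibble(step = sort(unique(traj$step)),
                 n_subgroups = res$n_subgroups,
                 largest = res$largest)
}

traj_matrix <- function(traj, var) {
  traj <- dplyr::arrange(traj, .data$pup, .data$step)
  matrix(traj[[var]], nrow = length(unique(traj$step)),
         ncol = length(unique(traj$pup)))
}

#' Time-averaged subgroup count
#'
#' @inheritParams subgroup_series
#' @return Mean number of contact subgroups over recorded steps.
#' @export
mean_subgroups <- function(x, r = NULL) {
  mean(subgroup_series(x, r = r)$n_subgroups)
}

#' Largest contact aggregate
#'
#' Size of the largest connected component of the contact graph, either
#' time-averaged (`stat = "mean"`, the typical aggregate the litter
#' sustains) or the maximum observed over recorded steps (`stat = "max"`).
#'
#' @inheritParams subgroup_series
#' @param stat `"mean"` or `"max"`.
#' @return Aggregate size in pups.
#' @export
largest_aggregate <- function(x, stat = c("mean", "max"), r = NULL) {
  stat <- match.arg(stat)
  s <- subgroup_series(x, r = r)$largest
  if (stat == "mean") mean(s) else max(s)
}

#' One-row summary of a simulation
#'
#' @inheritParams subgroup_series
#' @return A tibble with `huddling`, `mean_tb`, `pup_flow`,
#'   `mean_subgroups`, `mean_largest` and `max_aggregate`.
#' @export
summary_metrics <- function(x, r = NULL) {
  sub <- subgroup_series(x, r = r)
  tibble::tibble(
    huddling = huddling_metric(x),
    mean_tb = mean_body_temperature(x),
    pup_flow = pup_flow(x),
    mean_subgroups = mean(sub$n_subgroups),
    mean_largest = mean(sub$largest),
    max_aggregate = max(sub$largest)
  )
}
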