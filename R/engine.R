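#' Initialise a litter
#'
#' Pup centres are drawn i.i.d. uniform in the disc of radius `r` about the
#' arena centre (a pre-formed macro-huddle: the model studies huddle
#' maintenance, not formation across a large arena), headings uniform on
#' `[0, 2 pi)`, and all body temperatures at `config$tb_init`. Draws come
#' from the current RNG stream; call `set.seed()` (or use
#' [run_simulation()]'s `seed`) for reproducibility.
#'
#' @param config A [sim_config()].
#' @return A [litter_state()] at time 0.
#' @export
initialize_litter <- function(config) {
  p <- config$n_pups
  rad <- config$r * sqrt(runif(p))
  ang <- runif(p, 0, 2 * pi)
  theta <- runif(p, 0, 2 * pi)
  litter_state(rad * cos(ang), rad * sin(ang), theta = theta,
               tb = config$tb_init, r = config$r,
               arena_radius = config$arena_radius, time = 0)
}

#' Settle body temperatures with kinematics frozen
#'
#' Applies `config$settle_steps` body-temperature updates while positions and
#' headings are held fixed, letting the initial temperatures relax before
#' movement is enabled. The contact geometry is constant during the settle,
#' but contact temperatures are refreshed each step as littermates' body
#' temperatures evolve.
#'
#' @param litter A [litter_state()].
#' @param config A [sim_config()].
#' @return The litter with settled body temperatures.
#' @export
settle <- function(litter, config) {
  for (s in seq_len(config$settle_steps)) {
    field <- compute_contact_field(litter, n = config$n_thermometers)
    litter$tb <- body_temperature_step(litter$tb, field$eta, field$tc, config)
  }
  litter
}

#' One synchronous simulation step (reference implementation)
#'
#' Applies the five-step update to every pup simultaneously from the
#' start-of-step state: (i) contact field and left/right sensor values,
#' (ii) contralateral motor drives, (iii) heading update, (iv) position
#' update with boundary and collision forces, (v) body-temperature update.
#' This pure-R path defines the model semantics; [run_simulation()] runs the
#' same update in compiled code.
#'
#' @param litter A [litter_state()].
#' @param config A [sim_config()].
#' @return A list with the updated `litter` and the start-of-step `field`.
#' @export
sim_step <- function(litter, config) {
  field <- compute_contact_field(litter, n = config$n_thermometers)
  sens <- surface_temperatures(field, config)
  f_l <- transfer(sens$t_left, litter$tb, config)
  f_r <- transfer(sens$t_right, litter$tb, config)
  drives <- motor_speeds(f_l, f_r)
  new_theta <- litter$theta + heading_increment(drives$m_left,
                                                drives$m_right, config)
  out <- position_update(litter, config) # uses start-of-step headings
  out$theta <- new_theta
  out$tb <- body_temperature_step(litter$tb, field$eta, field$tc, config)
  attr(out, "time") <- attr(litter, "time") + config$dt
  if (any(!is.finite(out$x) | !is.finite(out$y) | !is.finite(out$tb))) {
    stop("non-finite state: check dt and parameters", call. = FALSE)
  }
  list(litter = out, field = field)
}

#' Run a huddling simulation
#'
#' Initialises a litter, settles body temperatures for
#' `config$settle_steps`, then iterates the five-step update for
#' `config$steps` recorded steps. With the same seed and configuration the
#' trajectory is exactly reproducible.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for all randomness (initial placement, sensor
#'   noise, degenerate tie-breaks); `NULL` uses the current RNG state.
#' @param engine `"cpp"` (compiled, default) or `"r"` (pure-R reference
#'   path; identical dynamics, used for cross-validation).
#' @return An object of class `"huddle_sim"`: a list with `trajectory` (a
#'   tibble with one row per recorded step and pup: `step`, `pup`, `x`, `y`,
#'   `theta`, `tb`, `eta`), `config`, `seed` and `engine`. `eta` is the
#'   exposed fraction from the contact field that drove the recorded step.
#' @examples
#' sim <- run_simulation(sim_config("endothermic", t_a = 45, n_pups = 3,
#'                                  n_thermometers = 100, steps = 50),
#'                       seed = 1)
#' glance(sim)
#' @export
run_simulation <- function(config, seed = NULL, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  validate_config(config)
  if (!is.null(seed)) set.seed(seed)
  litter <- initialize_litter(config)

  if (config$steps == 0) { # settled initial state only
    litter <- settle(litter, config)
    field <- compute_contact_field(litter, n = config$n_thermometers)
    traj <- tibble::tibble(
      step = 0L, pup = litter$pup, x = litter$x, y = litter$y,
      theta = litter$theta, tb = litter$tb, eta = field$eta
    )
    attr(traj, "config") <- config
    return(structure(list(trajectory = traj, config = config, seed = seed,
                          engine = engine),
                     class = "huddle_sim"))
  }

  if (engine == "cpp") {
    res <- cpp_simulate(litter$x, litter$y, litter$theta, litter$tb,
                        cfg_for_cpp(config))
    traj <- tibble::tibble(
      step = rep(seq_len(config$steps), times = config$n_pups),
      pup = rep(seq_len(config$n_pups), each = config$steps),
      x = as.vector(res$x),
      y = as.vector(res$y),
      theta = as.vector(res$theta),
      tb = as.vector(res$tb),
      eta = as.vector(res$eta)
    )
  } else {
    litter <- settle(litter, config)
    p <- config$n_pups
    rows <- vector("list", config$steps)
    for (s in seq_len(config$steps)) {
      stepped <- sim_step(litter, config)
      litter <- stepped$litter
      rows[[s]] <- tibble::tibble(
        step = s, pup = seq_len(p),
        x = litter$x, y = litter$y, theta = litter$theta, tb = litter$tb,
        eta = stepped$field$eta
      )
    }
    traj <- dplyr::bind_rows(rows)
  }
  traj <- dplyr::arrange(traj, .data$step, .data$pup)
  attr(traj, "config") <- config
  structure(
    list(trajectory = traj, config = config, seed = seed, engine = engine),
    class = "huddle_sim"
  )
}

#' @export
print.huddle_sim <- function(x, ...) {
  cat("<huddle_sim>", x$config$variant, "variant, t_a =", x$config$t_a,
      "|", x$config$n_pups, "pups,", x$config$steps, "steps",
      if (!is.null(x$seed)) paste("| seed", x$seed), "\n")
  if (length(unique(x$trajectory$step)) >= 2) {
    g <- glance(x)
    cat(sprintf(
      "  huddling %.3f | mean Tb %.2f | pup flow %.4f | subgroups %.2f\n",
      g$huddling, g$mean_tb, g$pup_flow, g$mean_subgroups))
  }
  invisible(x)
}

#' Parameter sweep over replicated simulations
#'
#' Runs replicated simulations across a grid of one parameter (ambient
#' temperature `t_a`, thermogenesis `g`, `contact_scaling`, or
#' `noise_variance`) and summarises each run. Each (value, replicate) pair
#' gets its own RNG stream seeded from `seed + 1009 * value_index +
#' replicate_index`, recorded in the output.
#'
#' @param config Base [sim_config()]; the swept field is overwritten.
#' @param param One of `"t_a"`, `"g"`, `"contact_scaling"`,
#'   `"noise_variance"`.
#' @param values Numeric grid of parameter values. For the standard
#'   ambient-temperature protocol use `seq(5, 50, length.out = 20)`.
#' @param replicates Replicates per value (default 10).
#' @param seed Master seed.
#' @param engine Passed to [run_simulation()].
#' @return A tibble of class `"huddle_sweep"`, one row per (value,
#'   replicate): the run-level metrics `huddling`, `mean_tb`, `pup_flow`,
#'   `mean_subgroups`, `mean_largest`, `max_aggregate`, plus a `per_pup`
#'   list-column of per-pup metrics for pup-level standard errors
#'   (see [summarise_sweep()]).
#' @examples
#' cfg <- sim_config("endothermic", n_pups = 4, n_thermometers = 40,
#'                   steps = 40, settle_steps = 5)
#' run_sweep(cfg, "t_a", c(20, 45), replicates = 2, seed = 1)
#' @export
run_sweep <- function(config, param = c("t_a", "g", "contact_scaling",
                                        "noise_variance"),
                      values, replicates = 10, seed = 1,
                      engine = c("cpp", "r")) {
  param <- match.arg(param)
  engine <- match.arg(engine)
  grid <- tidyr::expand_grid(.value_idx = seq_along(values),
                             replicate = seq_len(replicates))
  rows <- purrr::pmap(grid, function(.value_idx, replicate) {
    value <- values[.value_idx]
    cfg <- config
    cfg[[param]] <- value
    run_seed <- as.integer(seed + 1009L * (.value_idx - 1L) + replicate - 1L)
    sim <- run_simulation(cfg, seed = run_seed, engine = engine)
    sub <- subgroup_series(sim)
    per_pup <- tibble::tibble(
      pup = seq_len(cfg$n_pups),
      huddling = huddling_metric(sim, per_pup = TRUE),
      mean_tb = mean_body_temperature(sim, per_pup = TRUE),
      pup_flow = pup_flow(sim, per_pup = TRUE),
      mean_eta = 1 - huddling_metric(sim, per_pup = TRUE)
    )
    tibble::tibble(
      param = param, value = value, replicate = replicate, seed = run_seed,
      huddling = mean(per_pup$huddling),
      mean_tb = mean(per_pup$mean_tb),
      pup_flow = mean(per_pup$pup_flow),
      mean_subgroups = mean(sub$n_subgroups),
      mean_largest = mean(sub$largest),
      max_aggregate = max(sub$largest),
      per_pup = list(per_pup)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- config
  attr(out, "param") <- param
  class(out) <- c("huddle_sweep", class(out))
  out
}

#' Summarise a sweep with pup-level standard errors
#'
#' Pup-level metrics (huddling, mean body temperature, pup flow) are averaged
#' over all pups x replicates at each parameter value, with standard errors
#' over those observations (e.g. 120 observations for 10 replicates of 12
#' pups); subgroup statistics are averaged over replicates.
#'
#' @param sweep A [run_sweep()] result.
#' @return A tibble with one row per parameter value.
#' @export
summarise_sweep <- function(sweep) {
  se <- function(v) sd(v) / sqrt(length(v))
  pup_level <- sweep |>
    dplyr::select("value", "replicate", "per_pup") |>
    tidyr::unnest("per_pup") |>
    dplyr::group_by(.data$value) |>
    dplyr::summarise(
      huddling_se = se(.data$huddling),
      mean_tb_se = se(.data$mean_tb),
      pup_flow_se = se(.data$pup_flow),
      n_obs = dplyr::n(),
      .groups = "drop"
    )
  run_level <- sweep |>
    dplyr::group_by(.data$value) |>
    dplyr::summarise(
      huddling = mean(.data$huddling),
      mean_tb = mean(.data$mean_tb),
      pup_flow = mean(.data$pup_flow),
      mean_subgroups = mean(.data$mean_subgroups),
      mean_subgroups_se = se(.data$mean_subgroups),
      mean_largest = mean(.data$mean_largest),
      .groups = "drop"
    )
  dplyr::left_join(run_level, pup_level, by = "value")
}
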