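#' Super-organism parameters
#'
#' Parameters of the closed-form group-level model, which treats the whole
#' litter as one body that adapts its total exposed surface-area fraction
#' `A` to hold its temperature at the preferred `t_p`. Setting the settled
#' heat balance `0 = k1 * A * (t_a - t_b) + g` with `t_b = t_p` gives the
#' optimal area `A = g / (k1 * (t_p - t_a))`, clipped to the bounds
#' `[a_min, a_max]` measured from agent-based simulations (defaults 0.36 and
#' 1.0; [estimate_area_bounds()] recomputes them from any sweep).
#'
#' @param g Thermogenesis rate (degrees C / time).
#' @param k1 Thermal rate constant (1/time), same convention as
#'   [sim_config()].
#' @param t_p Preferred body temperature (degrees C).
#' @param a_min,a_max Exposed-area bounds in (0, 1].
#' @return A list of class `"superorganism_params"`.
#' @export
superorganism_params <- function(g = 6.32, k1 = 1, t_p = 37,
                                 a_min = 0.36, a_max = 1) {
  stopifnot(g >= 0, k1 > 0, a_min > 0, a_min <= a_max, a_max <= 1)
  structure(list(g = g, k1 = k1, t_p = t_p, a_min = a_min, a_max = a_max),
            class = "superorganism_params")
}

#' Optimal exposed area of the super-organism
#'
#' Piecewise in the ambient temperature: `a_min` below the lower breakpoint
#' `t_p - g / (k1 * a_min)`, `a_max` above the upper breakpoint
#' `t_p - g / (k1 * a_max)`, and `g / (k1 * (t_p - t_a))` between; the
#' interior branch meets the bounds continuously at both breakpoints. The
#' corresponding huddling prediction is `1 - A(t_a)`.
#'
#' @param t_a Ambient temperature(s), degrees C.
#' @param p A [superorganism_params()].
#' @return Exposed-area fraction(s) in `[a_min, a_max]`.
#' @examples
#' exposed_area(25, superorganism_params()) # 6.32 / 12
#' @export
exposed_area <- function(t_a, p = superorganism_params()) {
  if (p$g == 0) {
    warning("g = 0: the super-organism model degenerates to a sharp step ",
            "at t_p (a transition the agent-based model does not show: ",
            "without thermogenesis simulated litters disperse at every ",
            "ambient temperature)")
    return(ifelse(t_a < p$t_p, p$a_min, p$a_max))
  }
  lower <- p$t_p - p$g / (p$k1 * p$a_min)
  upper <- p$t_p - p$g / (p$k1 * p$a_max)
  interior <- p$g / (p$k1 * (p$t_p - t_a))
  dplyr::case_when(
    t_a <= lower ~ p$a_min,
    t_a >= upper ~ p$a_max,
    TRUE ~ interior
  )
}

#' Super-organism mean body temperature
#'
#' `t_a + g / (k1 * a_min)` below the plateau, `t_a + g / (k1 * a_max)`
#' above it, and exactly `t_p` on the plateau (the same breakpoints as
#' [exposed_area()]): over the transition slope the litter regulates its
#' mean temperature at the preferred value.
#'
#' @inheritParams exposed_area
#' @return Body temperature(s), degrees C.
#' @export
superorg_body_temperature <- function(t_a, p = superorganism_params()) {
  if (p$g == 0) {
    return(t_a)
  }
  lower <- p$t_p - p$g / (p$k1 * p$a_min)
  upper <- p$t_p - p$g / (p$k1 * p$a_max)
  dplyr::case_when(
    t_a <= lower ~ t_a + p$g / (p$k1 * p$a_min),
    t_a >= upper ~ t_a + p$g / (p$k1 * p$a_max),
    TRUE ~ p$t_p
  )
}

#' Thermoregulatory plateau range
#'
#' The plateau over which the super-organism holds its temperature at `t_p`
#' spans `delta = (g / k1) * (1 / a_min - 1 / a_max)` degrees, centred on
#' `t_p - (g / (2 * k1)) * (1 / a_min + 1 / a_max)`. The model's central
#' testable prediction is that the width grows with thermogenesis `g` and
#' with insulation (decreasing `k1`). With the area bounds held fixed, both
#' breakpoints shift downward as `g / k1` grows, so the regulated range
#' widens toward colder ambient temperatures.
#'
#' @param p A [superorganism_params()].
#' @return A one-row tibble: `width`, `centre`, `lower`, `upper` (degrees C).
#' @examples
#' plateau_range(superorganism_params()) # width 6.32 * (1/0.36 - 1)
#' @export
plateau_range <- function(p = superorganism_params()) {
  stopifnot(p$g > 0)
  tibble::tibble(
    width = (p$g / p$k1) * (1 / p$a_min - 1 / p$a_max),
    centre = p$t_p - (p$g / (2 * p$k1)) * (1 / p$a_min + 1 / p$a_max),
    lower = p$t_p - p$g / (p$k1 * p$a_min),
    upper = p$t_p - p$g / (p$k1 * p$a_max)
  )
}

#' Analytic curves over an ambient-temperature grid
#'
#' @param t_a Numeric grid of ambient temperatures.
#' @param p A [superorganism_params()].
#' @return A tibble with `t_a`, `a` (exposed area), `huddling` (`1 - a`)
#'   and `b` (mean body temperature), for overlaying on sweep summaries.
#' @export
superorg_curves <- function(t_a, p = superorganism_params()) {
  tibble::tibble(
    t_a = t_a,
    a = exposed_area(t_a, p),
    huddling = 1 - exposed_area(t_a, p),
    b = superorg_body_temperature(t_a, p)
  )
}

#' Measure exposed-area bounds from a sweep
#'
#' Recomputes `a_min` and `a_max` as the minimum and maximum, over the
#' sweep's parameter values, of the litter-mean exposed fraction
#' `eta = 1 - huddling`; the normative path for comparing the analytic
#' curves against simulation.
#'
#' @param sweep A [run_sweep()] result (or its [summarise_sweep()] summary).
#' @return A list with `a_min` and `a_max`.
#' @export
estimate_area_bounds <- function(sweep) {
  if (!"huddling" %in% names(sweep)) {
    stop("expected a sweep table with a 'huddling' column", call. = FALSE)
  }
  by_value <- sweep |>
    dplyr::group_by(.data$value) |>
    dplyr::summarise(eta = mean(1 - .data$huddling), .groups = "drop")
  list(a_min = min(by_value$eta), a_max = max(by_value$eta))
}
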