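#' Simulation configuration
#'
#' Builds the full parameter set for a huddling simulation. Defaults are the
#' standard model parameterisation: a litter of 12 pups of unit radius in a
#' circular arena of radius `10 * r`, 1000 surface thermometers per pup,
#' forward-Euler integration at `dt = 0.05` for 8000 steps after a 100-step
#' temperature settle, thermogenesis `g = 6.32`, preferred body temperature
#' `t_p = 37` and transfer steepness `sigma = 100`.
#'
#' The thermal rate constants `k1` (exposed surface) and `k2` (contact
#' surface) are expressed per unit time for a fully exposed / fully contacted
#' pup: they equal the circumference `2 * pi * r` times a conductance of
#' `1 / (2 * pi * r)` (respectively `2.5 / (2 * pi * r)`) per unit arc length,
#' so the defaults are `k1 = 1` and `k2 = 2.5` under the unit-radius
#' convention. This scale-free convention places the steady state of an
#' isolated pup at `t_a + g / k1` and the litter's thermoregulatory plateau in
#' the ambient range 19--31 degrees C at defaults.
#'
#' @param variant Model variant: `"homeothermotaxic"` (full model: dynamic
#'   body temperature plus the sigmoidal homeostatic transfer),
#'   `"endothermic"` (body temperature clamped at `tb_endo`), or
#'   `"ectothermic"` (dynamic body temperature, identity transfer).
#' @param t_a Ambient temperature (degrees C).
#' @param n_pups Number of pups in the litter.
#' @param n_thermometers Even number of thermometers tiling each pup's
#'   circumference (first half left of the heading, second half right).
#' @param steps Number of recorded simulation steps after the settle phase.
#' @param settle_steps Temperature-only settle steps with kinematics frozen.
#' @param dt Integration timestep (time units).
#' @param k1,k2 Thermal rate constants (1/time) for exposed and contact
#'   surface; see Details.
#' @param g Thermogenesis rate (degrees C / time) per pup.
#' @param t_p Preferred body temperature (degrees C; homeothermotaxic only).
#' @param sigma Transfer-function steepness (degrees C squared).
#' @param v1 Rotation gain (unitless).
#' @param v2 Forward speed (length/time).
#' @param r Pup radius (the unit of length).
#' @param arena_radius Arena radius; default `10 * r`.
#' @param contact_scaling Fraction in (0, 1] scaling the temperature
#'   registered at thermometers in contact with a littermate. Lowering it
#'   below 1 shifts the endothermic critical temperature to
#'   `contact_scaling * tb_endo`.
#' @param noise_variance Variance (degrees C squared) of zero-mean Gaussian
#'   sensor noise added independently to every thermometer at every step;
#'   0 disables noise.
#' @param boundary Logical; apply the inward boundary force at the arena wall.
#'   Disabling it leaves pups unconfined.
#' @param tb_init Initial body temperature (degrees C) of every pup.
#' @param tb_endo Clamped body temperature of the endothermic variant.
#'
#' @return A list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(variant = "endothermic", t_a = 20, steps = 100)
#' cfg$k2 / cfg$k1 # contact conductance is 2.5x the exposed conductance
#' @export
sim_config <- function(variant = c("homeothermotaxic", "endothermic",
                                   "ectothermic"),
                       t_a = 20,
                       n_pups = 12L,
                       n_thermometers = 1000L,
                       steps = 8000L,
                       settle_steps = 100L,
                       dt = 0.05,
                       k1 = 1,
                       k2 = 2.5,
                       g = 6.32,
                       t_p = 37,
                       sigma = 100,
                       v1 = 200,
                       v2 = 0.3,
                       r = 1,
                       arena_radius = 10 * r,
                       contact_scaling = 1,
                       noise_variance = 0,
                       boundary = TRUE,
                       tb_init = 30,
                       tb_endo = 37) {
  variant <- match.arg(variant)
  cfg <- list(
    variant = variant,
    t_a = t_a,
    n_pups = as.integer(n_pups),
    n_thermometers = as.integer(n_thermometers),
    steps = as.integer(steps),
    settle_steps = as.integer(settle_steps),
    dt = dt, k1 = k1, k2 = k2, g = g, t_p = t_p, sigma = sigma,
    v1 = v1, v2 = v2, r = r, arena_radius = arena_radius,
    contact_scaling = contact_scaling, noise_variance = noise_variance,
    boundary = isTRUE(boundary), tb_init = tb_init, tb_endo = tb_endo
  )
  class(cfg) <- "sim_config"
  validate_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks ranges and consistency; called by [sim_config()] and
#' [load_config()].
#'
#' @param cfg A `"sim_config"` list.
#' @return `cfg`, invisibly unchanged, or an error describing the first
#'   out-of-range value.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!cfg$variant %in% c("homeothermotaxic", "endothermic", "ectothermic")) {
    stop("unknown variant '", cfg$variant, "'; valid variants are ",
         "'endothermic', 'ectothermic', 'homeothermotaxic'", call. = FALSE)
  }
  chk <- function(ok, msg) if (!ok) stop("out-of-range value: ", msg,
                                         call. = FALSE)
  chk(cfg$n_pups >= 1, "n_pups must be >= 1")
  chk(cfg$n_thermometers >= 2, "n_thermometers must be >= 2")
  chk(cfg$n_thermometers %% 2 == 0,
      "n_thermometers must be even (left/right split)")
  chk(cfg$steps >= 0, "steps must be >= 0")
  chk(cfg$settle_steps >= 0, "settle_steps must be >= 0")
  chk(cfg$dt > 0, "dt must be > 0")
  chk(cfg$k1 > 0 && cfg$k2 > 0, "k1 and k2 must be > 0")
  chk(cfg$g >= 0, "g must be >= 0")
  chk(cfg$sigma > 0, "sigma must be > 0")
  chk(cfg$v1 > 0 && cfg$v2 > 0, "v1 and v2 must be > 0")
  chk(cfg$r > 0, "r must be > 0")
  chk(cfg$arena_radius > cfg$r, "arena_radius must exceed r")
  chk(cfg$contact_scaling > 0 && cfg$contact_scaling <= 1,
      "contact_scaling must be in (0, 1]")
  chk(cfg$noise_variance >= 0, "noise_variance must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> variant =", x$variant,
      "| t_a =", x$t_a, "| pups =", x$n_pups,
      "| steps =", x$steps, "(+", x$settle_steps, "settle)\n")
  cat("  k1 =", x$k1, "k2 =", x$k2, "g =", x$g, "t_p =", x$t_p,
      "sigma =", x$sigma, "\n")
  cat("  v1 =", x$v1, "v2 =", x$v2, "dt =", x$dt,
      "| r =", x$r, "arena =", x$arena_radius,
      "| n_therm =", x$n_thermometers, "\n")
  if (x$contact_scaling != 1 || x$noise_variance > 0 || !x$boundary) {
    cat("  contact_scaling =", x$contact_scaling,
        "noise_variance =", x$noise_variance,
        "boundary =", x$boundary, "\n")
  }
  invisible(x)
}

variant_code <- function(variant) {
  match(variant, c("endothermic", "ectothermic", "homeothermotaxic")) - 1L
}

# config as the flat list the C++ kernel expects
cfg_for_cpp <- function(cfg) {
  c(cfg, list(variant_code = variant_code(cfg$variant)))
}
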