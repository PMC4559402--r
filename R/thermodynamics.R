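#' Surface temperatures sensed by each pup
#'
#' The temperature at thermometer `k` of pup `i` is
#' `tau[i, k] = t_a * epsilon[i, k] + s * chi[i, k]` (ambient where exposed,
#' the scaled body temperature of the nearest contacting littermate where
#' covered), plus optional i.i.d. zero-mean Gaussian sensor noise drawn fresh
#' from the current RNG stream. The left (right) sensor value is the mean of
#' `tau` over the first (second) half of the thermometers.
#'
#' @param field A [compute_contact_field()] result.
#' @param config A [sim_config()]; uses `t_a`, `contact_scaling` and
#'   `noise_variance`.
#' @return A tibble with columns `pup`, `t_left`, `t_right`; the full
#'   `tau` matrix is attached as attribute `"tau"`.
#' @examples
#' f <- compute_contact_field(fixture_litter("isolated"), n = 100)
#' surface_temperatures(f, sim_config(t_a = 20)) # t_left = t_right = 20
#' @export
surface_temperatures <- function(field, config) {
  tau <- config$t_a * field$epsilon + config$contact_scaling * field$chi
  if (config$noise_variance > 0) {
    tau <- tau + matrix(rnorm(length(tau), 0, sqrt(config$noise_variance)),
                        nrow(tau), ncol(tau))
  }
  n <- field$n
  left <- seq_len(n / 2)
  out <- tibble::tibble(
    pup = seq_len(nrow(tau)),
    t_left = rowMeans(tau[, left, drop = FALSE]),
    t_right = rowMeans(tau[, -left, drop = FALSE])
  )
  attr(out, "tau") <- tau
  out
}

#' Contact-mediated mean surface temperature
#'
#' The mean of the contact temperatures `chi` over the thermometers that are
#' in contact with a littermate. A fully exposed pup has no contacted
#' thermometers; its value is reported as its own body temperature so that
#' the exchange term `-k2 * (1 - eta) * (tb - tc)` is exactly zero.
#'
#' @param field A [compute_contact_field()] result.
#' @param tb Body temperatures used for the fully exposed fallback; defaults
#'   to the values already recorded in `field`.
#' @return Numeric vector of per-pup contact temperatures (degrees C).
#' @export
contact_mean_temperature <- function(field, tb = NULL) {
  n_contact <- field$n - rowSums(field$epsilon)
  tc <- rowSums(field$chi) / pmax(n_contact, 1)
  if (is.null(tb)) tb <- field$tc # fallback recorded at field construction
  ifelse(n_contact > 0, tc, tb)
}

#' One forward-Euler body-temperature update
#'
#' Integrates `d tb / dt = -k1 * eta * (tb - t_a) - k2 * (1 - eta) *
#' (tb - tc) + g` for one step of length `dt`: heat decay through the exposed
#' surface, heat exchange through the contact surface, and constant internal
#' thermogenesis. The endothermic variant clamps every body temperature at
#' `tb_endo` instead. An isolated pup (`eta = 1`) relaxes to the steady state
#' `t_a + g / k1`.
#'
#' @param tb Body temperatures (degrees C).
#' @param eta Exposed fractions in `[0, 1]`.
#' @param tc Contact-mediated surface temperatures (degrees C).
#' @param config A [sim_config()].
#' @return Updated body temperatures.
#' @examples
#' cfg <- sim_config(variant = "ectothermic", t_a = 20, g = 0)
#' body_temperature_step(30, eta = 1, tc = 30, cfg) # decays toward 20
#' @export
body_temperature_step <- function(tb, eta, tc, config) {
  stopifnot(all(eta >= 0 & eta <= 1))
  if (config$variant == "endothermic") {
    return(rep(config$tb_endo, length(tb)))
  }
  tb + config$dt * (-config$k1 * eta * (tb - config$t_a) -
                      config$k2 * (1 - eta) * (tb - tc) + config$g)
}
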