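#' Sensor-to-drive transfer function
#'
#' The homeothermotaxic variant squashes each side's surface temperature
#' through `F(T) = 1 / (1 + exp(-(t_p - tb) * T / sigma))`: when the pup is
#' cooler than its preferred temperature the drive increases with `T`
#' (heat-seeking), when warmer it decreases (heat-avoiding), and at
#' `tb = t_p` it is exactly 1/2 regardless of `T`. The endothermic and
#' ectothermic variants use the identity `F(T) = T`.
#'
#' @param temp Surface temperature(s) of one side (degrees C).
#' @param tb Body temperature(s) (degrees C); recycled against `temp`.
#' @param config A [sim_config()].
#' @return Drives: in (0, 1) for the homeothermotaxic variant, `temp`
#'   unchanged otherwise.
#' @examples
#' cfg <- sim_config("homeothermotaxic")
#' transfer(10, tb = 27, cfg) # 1 / (1 + exp(-1)) ~ 0.731
#' @export
transfer <- function(temp, tb, config) {
  if (config$variant == "homeothermotaxic") {
    1 / (1 + exp(-(config$t_p - tb) * temp / config$sigma))
  } else {
    temp
  }
}

#' Contralateral motor drives
#'
#' The left motor is driven by the right sensor and vice versa:
#' `m_left = F(T_right) / (F(T_left) + F(T_right))`, so the drives sum to one
#' by construction. When both transferred drives are zero (possible only for
#' the identity transfer at zero temperatures) both motors are set to 1/2,
#' continuous with the symmetric case.
#'
#' @param f_left,f_right Transferred drives for the left and right sensors.
#' @return A tibble with columns `m_left`, `m_right` summing to 1 rowwise.
#' @examples
#' motor_speeds(f_left = 0.2, f_right = 0.6) # m_left = 0.75
#' @export
motor_speeds <- function(f_left, f_right) {
  s <- f_left + f_right
  ok <- s > 0
  tibble::tibble(
    m_left = ifelse(ok, f_right / s, 0.5),
    m_right = ifelse(ok, f_left / s, 0.5)
  )
}

#' Heading increment from the motor drives
#'
#' A pup whose left motor is driven harder (`m_left > m_right`, i.e. the
#' right side senses more heat under contralateral wiring) turns clockwise,
#' toward its warmer right side: the heading change per step is
#' `dt * atan(v1 * (m_right - m_left))`, bounded in magnitude by
#' `dt * pi / 2`.
#'
#' @param m_left,m_right Motor drives.
#' @param config A [sim_config()]; uses `v1` and `dt`.
#' @return Heading increments in radians.
#' @examples
#' cfg <- sim_config()
#' heading_increment(0.4975, 0.5025, cfg) / cfg$dt # atan(1) = pi/4
#' @export
heading_increment <- function(m_left, m_right, config) {
  config$dt * atan(config$v1 * (m_right - m_left))
}

#' Position update with boundary and collision forces
#'
#' Each pup translates at constant speed `v2` along its heading, receives an
#' inward radial push `beta * x / |x|` with
#' `beta = arena_radius - |x| - r <= 0` whenever its body touches the arena
#' wall (suppressed when `config$boundary` is `FALSE`), and springs away from
#' every overlapping littermate with force `(r - d/2)` directed from the
#' littermate's centre toward its own. All forces are evaluated at the
#' start-of-step state and applied as one forward-Euler increment; transient
#' overlaps are permitted.
#'
#' @param litter A [litter_state()].
#' @param config A [sim_config()].
#' @return The litter with updated `x`, `y`.
#' @export
position_update <- function(litter, config) {
  p <- nrow(litter)
  r <- config$r
  fx <- config$v2 * cos(litter$theta)
  fy <- config$v2 * sin(litter$theta)

  if (config$boundary) {
    nrm <- sqrt(litter$x^2 + litter$y^2)
    hit <- nrm + r >= config$arena_radius & nrm > 0
    beta <- ifelse(hit, config$arena_radius - nrm - r, 0)
    fx <- fx + ifelse(hit, beta * litter$x / pmax(nrm, 1e-300), 0)
    fy <- fy + ifelse(hit, beta * litter$y / pmax(nrm, 1e-300), 0)
  }

  if (p > 1) {
    dx <- outer(litter$x, litter$x, "-") # dx[i, j] = x_i - x_j
    dy <- outer(litter$y, litter$y, "-")
    d <- sqrt(dx^2 + dy^2)
    touching <- d <= 2 * r & upper.tri(d, diag = FALSE)
    touching <- touching | t(touching)
    mag <- ifelse(touching, r - d / 2, 0) # push grows with overlap
    ux <- dx / pmax(d, 1e-300)
    uy <- dy / pmax(d, 1e-300)
    coincident <- which(touching & d < 1e-12 & upper.tri(d), arr.ind = TRUE)
    for (idx in seq_len(nrow(coincident))) {
      i <- coincident[idx, 1]; j <- coincident[idx, 2]
      ph <- runif(1, 0, 2 * pi) # one seeded draw per unordered pair
      ux[i, j] <- -cos(ph); uy[i, j] <- -sin(ph)
      ux[j, i] <- cos(ph); uy[j, i] <- sin(ph)
    }
    fx <- fx + rowSums(mag * ux)
    fy <- fy + rowSums(mag * uy)
  }

  litter$x <- litter$x + config$dt * fx
  litter$y <- litter$y + config$dt * fy
  litter
}
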