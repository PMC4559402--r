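#' Construct a litter state
#'
#' A litter state is a tibble with one row per pup and columns `pup`, `x`,
#' `y` (arena coordinates, in units of the pup radius), `theta` (heading,
#' radians) and `tb` (body temperature, degrees C), carrying the common pup
#' radius, the arena radius and the simulation time as attributes.
#'
#' @param x,y Numeric vectors of pup centre coordinates.
#' @param theta Headings in radians (recycled).
#' @param tb Body temperatures in degrees C (recycled).
#' @param r Common pup radius (> 0).
#' @param arena_radius Arena radius; defaults to `10 * r`.
#' @param time Simulation time.
#' @return A tibble of class `"litter_state"`.
#' @examples
#' litter_state(x = c(0, 1.5), y = c(0, 0), theta = c(0, pi), tb = 37)
#' @export
litter_state <- function(x, y, theta = 0, tb = 37, r = 1,
                         arena_radius = 10 * r, time = 0) {
  p <- length(x)
  stopifnot(length(y) == p, p >= 1, r > 0, arena_radius > 0)
  out <- tibble::tibble(
    pup = seq_len(p),
    x = as.numeric(x),
    y = as.numeric(y),
    theta = rep_len(as.numeric(theta), p),
    tb = rep_len(as.numeric(tb), p)
  )
  if (any(!is.finite(out$theta))) stop("headings must be finite")
  attr(out, "r") <- r
  attr(out, "arena_radius") <- arena_radius
  attr(out, "time") <- time
  class(out) <- c("litter_state", class(out))
  out
}

litter_r <- function(litter) {
  r <- attr(litter, "r")
  if (is.null(r)) 1 else r
}

#' Deterministic fixture litters
#'
#' Hand-constructed litter configurations used throughout the geometry,
#' behaviour and metrics examples and tests.
#'
#' @param case One of `"isolated"` (single pup at the origin),
#'   `"touching_pair"` (two pups at centre distance `2 r`, touching without
#'   overlap), `"lens_pair_d_eq_r"` (two pups at distance `r`, the analytic
#'   lens-overlap case), `"chain12"` (12 pups in a touching line),
#'   `"two_clusters"` (two well-separated clusters of 6), or
#'   `"coincident_pair"` (two pups with coincident centres, the degenerate
#'   bearing case).
#' @param r Pup radius.
#' @return A [litter_state()].
#' @examples
#' fixture_litter("lens_pair_d_eq_r")
#' @export
fixture_litter <- function(case = c("isolated", "touching_pair",
                                    "lens_pair_d_eq_r", "chain12",
                                    "two_clusters", "coincident_pair"),
                           r = 1) {
  case <- match.arg(case)
  switch(case,
    isolated = litter_state(0, 0, theta = 0, tb = 37, r = r),
    touching_pair = litter_state(c(0, 2 * r), c(0, 0), theta = 0, tb = 37,
                                 r = r),
    lens_pair_d_eq_r = litter_state(c(0, r), c(0, 0), theta = 0, tb = 37,
                                    r = r),
    chain12 = litter_state(1.5 * r * (seq_len(12) - 6.5), rep(0, 12),
                           theta = 0, tb = 37, r = r,
                           arena_radius = 20 * r),
    two_clusters = {
      hex <- cbind(c(0, 1.8 * r, 0.9 * r, -0.9 * r, -1.8 * r, 0.9 * r),
                   c(0, 0, 1.5 * r, 1.5 * r, 0, -1.5 * r))
      litter_state(c(hex[, 1] - 6 * r, hex[, 1] + 6 * r),
                   c(hex[, 2], hex[, 2]), theta = 0, tb = 37, r = r,
                   arena_radius = 12 * r)
    },
    coincident_pair = litter_state(c(0, 0), c(0, 0), theta = 0, tb = 37,
                                   r = r)
  )
}
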