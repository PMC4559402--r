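#' Tidy a simulation into its trajectory
#'
#' @param x A `"huddle_sim"`.
#' @param ... Unused.
#' @return The trajectory tibble: one row per recorded step and pup with
#'   `step`, `pup`, `x`, `y`, `theta`, `tb`, `eta`.
#' @export
tidy.huddle_sim <- function(x, ...) {
  x$trajectory
}

#' One-row summary of a simulation
#'
#' @param x A `"huddle_sim"`.
#' @param ... Unused.
#' @return A one-row tibble: variant, ambient temperature, seed, and the
#'   group-level metrics from [summary_metrics()].
#' @export
glance.huddle_sim <- function(x, ...) {
  cfg <- x$config
  dplyr::bind_cols(
    tibble::tibble(
      variant = if (is.null(cfg)) NA_character_ else cfg$variant,
      t_a = if (is.null(cfg)) NA_real_ else cfg$t_a,
      seed = if (is.null(x$seed)) NA_integer_ else x$seed
    ),
    summary_metrics(x)
  )
}

#' Summarise a sweep
#'
#' @param x A `"huddle_sweep"`.
#' @param ... Unused.
#' @return [summarise_sweep()] of the sweep: one row per parameter value
#'   with means and pup-level standard errors.
#' @export
glance.huddle_sweep <- function(x, ...) {
  summarise_sweep(x)
}
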