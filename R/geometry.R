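#' Angular offsets of the surface thermometers
#'
#' Thermometer `k` of `n` sits at angular offset `(k - 1/2) * 2 * pi / n`
#' from the pup's heading, so the first `n/2` thermometers lie on the pup's
#' left and the second `n/2` on its right.
#'
#' @param n Even thermometer count.
#' @return Numeric vector of `n` offsets in radians.
#' @export
thermometer_offsets <- function(n) {
  check_even_n(n)
  (seq_len(n) - 0.5) * 2 * pi / n
}

check_even_n <- function(n) {
  if (length(n) != 1 || n < 2 || n %% 2 != 0) {
    stop("n must be a single even count >= 2 (the left/right split is ",
         "undefined for odd n)", call. = FALSE)
  }
  invisible(as.integer(n))
}

# circular (wrap-around) angular distance: pi - |pi - (|a| mod 2pi)|
circ_dist <- function(a) {
  pi - abs(pi - (abs(a) %% (2 * pi)))
}

#' Thermometer positions for one pup
#'
#' @param litter A [litter_state()].
#' @param pup Index of the focal pup.
#' @param n Even thermometer count (default 1000).
#' @return A tibble with columns `k`, `offset` (radians from heading), `x`,
#'   `y` (arena coordinates on the pup's circumference) and `side`
#'   (`"left"` for the first `n/2`, `"right"` otherwise).
#' @examples
#' thermometer_positions(fixture_litter("isolated"), n = 4)
#' @export
thermometer_positions <- function(litter, pup = 1, n = 1000) {
  n <- check_even_n(n)
  r <- litter_r(litter)
  off <- thermometer_offsets(n)
  ang <- litter$theta[pup] + off
  tibble::tibble(
    k = seq_len(n),
    offset = off,
    x = litter$x[pup] + r * cos(ang),
    y = litter$y[pup] + r * sin(ang),
    side = rep(c("left", "right"), each = n / 2)
  )
}

#' Contact indicator between a thermometer and a littermate
#'
#' Thermometer `k` of pup `i` registers contact with pup `j` when the two
#' discs overlap (centre distance `d <= 2 r`) and the thermometer's angular
#' position lies within `acos(d / (2 r))` (circular distance) of the bearing
#' of `j` from `i`. For equal radii this is exactly the point-in-disc test
#' "thermometer inside the body of `j`".
#'
#' @inheritParams thermometer_positions
#' @param i,j Distinct pup indices.
#' @param k Thermometer indices (default all `n`).
#' @param n Even thermometer count.
#' @return Integer vector of 0/1 indicators, one per element of `k`.
#' @examples
#' contact_indicator(fixture_litter("lens_pair_d_eq_r"), i = 1, j = 2, n = 8)
#' @export
contact_indicator <- function(litter, i, j, k = NULL, n = 1000) {
  n <- check_even_n(n)
  stopifnot(i != j)
  if (is.null(k)) k <- seq_len(n)
  r <- litter_r(litter)
  dx <- litter$x[j] - litter$x[i]
  dy <- litter$y[j] - litter$y[i]
  d <- sqrt(dx^2 + dy^2)
  if (d > 2 * r) return(integer(length(k)))
  if (d == 0) {
    stop("coincident pup centres: the bearing is undefined; ",
         "compute_contact_field() resolves this with a seeded random bearing",
         call. = FALSE)
  }
  phi <- atan2(dy, dx)
  ang <- litter$theta[i] + (k - 0.5) * 2 * pi / n
  as.integer(circ_dist(ang - phi) < acos(d / (2 * r)))
}

#' Contact field of a litter
#'
#' Computes, for every pup and thermometer, the exposure flag
#' `epsilon[i, k] = prod_j (1 - alpha[i, j, k])`, the exposed fraction
#' `eta[i] = mean_k epsilon[i, k]`, the contact temperature
#' `chi[i, k]` (the body temperature of the littermate whose centre is
#' nearest to the thermometer, zero where exposed), and the contact-mediated
#' surface temperature `tc[i]` (mean of `chi` over contacted thermometers;
#' reported as the pup's own body temperature when fully exposed so that the
#' contact-exchange term of the temperature update is exactly zero).
#'
#' Coincident pup centres (an unstable, measure-zero configuration that the
#' collision spring immediately separates) are handled by drawing the
#' undefined bearing uniformly from the current RNG stream.
#'
#' @inheritParams thermometer_positions
#' @param n Even thermometer count per pup.
#' @return An object of class `"contact_field"`: a list with matrices
#'   `epsilon` (pups x n, 0/1), `chi`, `nearest` (littermate index, `NA`
#'   where exposed), vectors `eta` and `tc`, and the thermometer count `n`.
#' @examples
#' f <- compute_contact_field(fixture_litter("lens_pair_d_eq_r"), n = 300)
#' f$eta # about 2/3 exposed each
#' @export
compute_contact_field <- function(litter, n = 1000) {
  n <- check_even_n(n)
  p <- nrow(litter)
  stopifnot(p >= 1)
  r <- litter_r(litter)
  off <- thermometer_offsets(n)

  eps <- matrix(1L, p, n)
  chi <- matrix(0, p, n)
  nearest <- matrix(NA_integer_, p, n)

  # pairwise distances and bearings; undefined bearings drawn once per pair
  dx <- outer(litter$x, litter$x, function(a, b) b - a)
  dy <- outer(litter$y, litter$y, function(a, b) b - a)
  d <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx)
  if (p > 1) {
    coin <- which(upper.tri(d) & d < 1e-12, arr.ind = TRUE)
    for (idx in seq_len(nrow(coin))) {
      i <- coin[idx, 1]; j <- coin[idx, 2]
      ph <- runif(1, 0, 2 * pi)
      phi[i, j] <- ph
      phi[j, i] <- ph + pi
    }
  }

  for (i in seq_len(p)) {
    ang <- litter$theta[i] + off
    tx <- litter$x[i] + r * cos(ang)
    ty <- litter$y[i] + r * sin(ang)
    best <- rep(Inf, n)
    for (j in seq_len(p)) {
      if (j == i || d[i, j] > 2 * r) next
      halfw <- acos(min(d[i, j] / (2 * r), 1))
      covered <- circ_dist(ang - phi[i, j]) < halfw
      if (!any(covered)) next
      eps[i, covered] <- 0L
      d2 <- (litter$x[j] - tx[covered])^2 + (litter$y[j] - ty[covered])^2
      better <- d2 < best[covered] # ties keep the lowest pup index
      upd <- which(covered)[better]
      best[upd] <- d2[better]
      chi[i, upd] <- litter$tb[j]
      nearest[i, upd] <- j
    }
  }

  eta <- rowMeans(eps)
  n_contact <- n - rowSums(eps)
  tc <- ifelse(n_contact > 0, rowSums(chi) / pmax(n_contact, 1), litter$tb)
  structure(
    list(epsilon = eps, chi = chi, nearest = nearest, eta = eta, tc = tc,
         n = n, r = r),
    class = "contact_field"
  )
}

#' @export
print.contact_field <- function(x, ...) {
  cat("<contact_field>", nrow(x$epsilon), "pups x", x$n, "thermometers\n")
  cat("  eta:", paste(signif(x$eta, 3), collapse = " "), "\n")
  invisible(x)
}

#' Tidy a contact field
#'
#' @param x A `"contact_field"` object.
#' @param ... Unused.
#' @return A tibble with one row per pup: `pup`, `eta`, `tc` and
#'   `n_contacted` (number of thermometers in contact).
#' @export
tidy.contact_field <- function(x, ...) {
  tibble::tibble(
    pup = seq_along(x$eta),
    eta = x$eta,
    tc = x$tc,
    n_contacted = x$n - rowSums(x$epsilon)
  )
}
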