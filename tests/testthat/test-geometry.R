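test_that("thermometer positions follow the half-offset layout", {
  litter <- fixture_litter("isolated")
  tp <- thermometer_positions(litter, n = 4)
  expect_equal(tp$offset, c(pi / 4, 3 * pi / 4, 5 * pi / 4, 7 * pi / 4))
  expect_equal(tp$side, c("left", "left", "right", "right"))
  expect_equal(tp$x, cos(tp$offset))
  expect_equal(tp$y, sin(tp$offset))

  # all points sit on the body circle, for any n
  tp1000 <- thermometer_positions(litter, n = 1000)
  expect_equal(sqrt(tp1000$x^2 + tp1000$y^2), rep(1, 1000))

  expect_error(thermometer_positions(litter, n = 5), "even")
})

test_that("rotating the heading rotates every thermometer with it", {
  delta <- 0.7
  l0 <- litter_state(2, 1, theta = 0.3)
  l1 <- litter_state(2, 1, theta = 0.3 + delta)
  t0 <- thermometer_positions(l0, n = 16)
  t1 <- thermometer_positions(l1, n = 16)
  rot <- cbind(
    2 + cos(delta) * (t0$x - 2) - sin(delta) * (t0$y - 1),
    1 + sin(delta) * (t0$x - 2) + cos(delta) * (t0$y - 1)
  )
  expect_equal(cbind(t1$x, t1$y), rot)
})

test_that("contact indicator matches the stated angular criterion", {
  # disjoint circles: no contact for any thermometer
  far <- litter_state(c(0, 3), c(0, 0))
  expect_equal(contact_indicator(far, 1, 2, n = 100), integer(100))

  # d = r, thermometer facing the littermate head on: covered
  lens <- fixture_litter("lens_pair_d_eq_r")
  n <- 1000
  facing <- which.min(abs(thermometer_offsets(n))) # offset closest to 0
  expect_equal(contact_indicator(lens, 1, 2, k = facing, n = n), 1L)

  expect_error(contact_indicator(fixture_litter("coincident_pair"), 1, 2,
                                 n = 10), "coincident")
})

test_that("angular contact criterion equals the point-in-disc oracle", {
  # oracle: Euclidean distance from the thermometer to centre j <= r
  set.seed(42)
  n <- 64
  for (rep in 1:200) {
    r <- runif(1, 0.5, 2)
    d <- runif(1, 0.05, 2.5) * r
    phi <- runif(1, 0, 2 * pi)
    th <- runif(1, 0, 2 * pi)
    litter <- litter_state(c(0, d * cos(phi)), c(0, d * sin(phi)),
                           theta = th, r = r, arena_radius = 10 * r)
    got <- contact_indicator(litter, 1, 2, n = n)
    tp <- thermometer_positions(litter, pup = 1, n = n)
    oracle <- as.integer(
      sqrt((tp$x - litter$x[2])^2 + (tp$y - litter$y[2])^2) <= r
    )
    # the two tests may only disagree where the thermometer sits exactly on
    # the boundary circle (measure zero; none generated here)
    expect_equal(got, oracle)
  }
})

test_that("contact field of a lone pup is fully exposed", {
  f <- compute_contact_field(fixture_litter("isolated"), n = 100)
  expect_equal(f$eta, 1)
  expect_equal(f$epsilon, matrix(1L, 1, 100))
  expect_equal(f$chi, matrix(0, 1, 100))
  expect_equal(f$tc, 37) # own body temperature: exchange term is zero
})

test_that("pair at d = r exposes 1 - 1/3 of each pup", {
  # lens half-angle acos(1/2) = pi/3 covers a third of the circumference
  f <- compute_contact_field(fixture_litter("lens_pair_d_eq_r"), n = 1200)
  expect_equal(f$eta, c(2 / 3, 2 / 3), tolerance = 0.002)
  # oracle: count thermometers passing the point-in-disc test
  lens <- fixture_litter("lens_pair_d_eq_r")
  tp <- thermometer_positions(lens, pup = 1, n = 1200)
  inside <- sqrt((tp$x - 1)^2 + tp$y^2) <= 1
  expect_equal(f$eta[1], 1 - mean(inside))
})

test_that("three overlapping pups: coverage and nearest-centre assignment", {
  litter <- litter_state(c(0, 1.2, -1.2), c(0, 0, 0), tb = c(30, 35, 40))
  n <- 400
  f <- compute_contact_field(litter, n = n)
  # brute-force oracle for pup 1
  tp <- thermometer_positions(litter, pup = 1, n = n)
  d2 <- sapply(2:3, function(j) (tp$x - litter$x[j])^2 +
                                 (tp$y - litter$y[j])^2)
  covered <- d2 <= 1
  eps_oracle <- as.integer(!(covered[, 1] | covered[, 2]))
  expect_equal(f$epsilon[1, ], eps_oracle)
  nearer <- ifelse(d2[, 1] <= d2[, 2], 2L, 3L) # ties to the lower index
  chi_oracle <- ifelse(eps_oracle == 1, 0,
                       litter$tb[ifelse(covered[, 1] & covered[, 2], nearer,
                                        ifelse(covered[, 1], 2L, 3L))])
  expect_equal(f$chi[1, ], chi_oracle)
})

test_that("eta is invariant under rigid motions of the litter", {
  set.seed(7)
  base <- litter_state(runif(5, -2, 2), runif(5, -2, 2),
                       theta = runif(5, 0, 2 * pi))
  f0 <- compute_contact_field(base, n = 200)
  a <- 1.1
  moved <- litter_state(
    3 + cos(a) * base$x - sin(a) * base$y,
    -2 + sin(a) * base$x + cos(a) * base$y,
    theta = base$theta + a
  )
  f1 <- compute_contact_field(moved, n = 200)
  expect_equal(f1$eta, f0$eta)
})

test_that("moving pups apart never creates contact", {
  n <- 100
  prev <- Inf
  for (d in seq(0.2, 2.6, by = 0.2)) {
    litter <- litter_state(c(0, d), c(0, 0))
    cov <- sum(contact_indicator(litter, 1, 2, n = n))
    expect_lte(cov, prev)
    prev <- cov
  }
})

test_that("exposure flags are binary and exhaustive", {
  set.seed(11)
  litter <- litter_state(runif(6, -1.5, 1.5), runif(6, -1.5, 1.5))
  f <- compute_contact_field(litter, n = 120)
  expect_true(all(f$epsilon %in% c(0L, 1L)))
  expect_equal(rowSums(f$epsilon) + rowSums(1 - f$epsilon),
               rep(120, 6))
  expect_true(all(f$chi[f$epsilon == 1L] == 0))
  expect_true(all(f$eta >= 0 & f$eta <= 1))
})

test_that("eta estimates at n = 200 converge to n = 1000 within 0.01", {
  set.seed(3)
  for (rep in 1:5) {
    litter <- litter_state(runif(6, -1.5, 1.5), runif(6, -1.5, 1.5),
                           theta = runif(6, 0, 2 * pi))
    e200 <- compute_contact_field(litter, n = 200)$eta
    e1000 <- compute_contact_field(litter, n = 1000)$eta
    expect_lt(max(abs(e200 - e1000)), 0.01)
  }
})

test_that("coincident centres resolve to full mutual contact", {
  set.seed(5)
  f <- compute_contact_field(fixture_litter("coincident_pair"), n = 100)
  # each pup half-covered by the drawn bearing (half-angle pi/2)
  expect_equal(f$eta, c(0.5, 0.5))
  expect_equal(f$tc, c(37, 37))
})

test_that("tidy() summarises a contact field per pup", {
  f <- compute_contact_field(fixture_litter("lens_pair_d_eq_r"), n = 300)
  td <- tidy(f)
  expect_equal(nrow(td), 2)
  expect_equal(td$n_contacted, 300 - 300 * td$eta)
})
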