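test_that("transfer function gates drives by the body-temperature error", {
  homeo <- sim_config("homeothermotaxic")
  # at the preferred temperature the output is exactly 1/2 for any input
  expect_equal(transfer(c(0, 10, 40), tb = 37, homeo), rep(0.5, 3))
  # direct evaluation: (Tp - Tb) * T / sigma = 1
  expect_equal(transfer(10, tb = 27, homeo), 1 / (1 + exp(-1)))
  # cold pup: increasing in T; warm pup: decreasing in T
  expect_true(all(diff(transfer(seq(5, 40, 5), tb = 30, homeo)) > 0))
  expect_true(all(diff(transfer(seq(5, 40, 5), tb = 40, homeo)) < 0))
  expect_true(all(transfer(seq(-50, 50, 10), tb = 20, homeo) > 0 &
                    transfer(seq(-50, 50, 10), tb = 20, homeo) < 1))
  # identity for the other variants
  ecto <- sim_config("ectothermic")
  expect_equal(transfer(25, tb = 30, ecto), 25)
})

test_that("motor drives are contralateral and sum to one", {
  expect_equal(motor_speeds(0.2, 0.6),
               tibble::tibble(m_left = 0.75, m_right = 0.25))
  m <- motor_speeds(0.3, 0.3)
  expect_equal(m$m_left, 0.5)
  # degenerate zero drive: continuous with the symmetric case
  z <- motor_speeds(0, 0)
  expect_equal(c(z$m_left, z$m_right), c(0.5, 0.5))
  # property: sums are exactly 1 across random drives
  set.seed(2)
  fl <- runif(100); fr <- runif(100)
  ms <- motor_speeds(fl, fr)
  expect_equal(ms$m_left + ms$m_right, rep(1, 100))
})

test_that("heading increments are bounded and steer toward the warm side", {
  cfg <- sim_config()
  expect_equal(heading_increment(0.5, 0.5, cfg), 0)
  # direct evaluation at the arctan unit point: |v1 * dM| = 1
  expect_equal(abs(heading_increment(0.5025, 0.4975, cfg)),
               cfg$dt * pi / 4, tolerance = 1e-10)
  # saturation from below at dt * pi / 2
  expect_lt(abs(heading_increment(1, 0, cfg)), cfg$dt * pi / 2)
  expect_equal(abs(heading_increment(1, 0, cfg)), cfg$dt * pi / 2,
               tolerance = 0.01)
  # warmer right side: F(T_R) > F(T_L) means m_left > m_right, and the pup
  # must turn clockwise (negative increment) toward the warm side
  m <- motor_speeds(f_left = 0.2, f_right = 0.8)
  expect_gt(m$m_left, m$m_right)
  expect_lt(heading_increment(m$m_left, m$m_right, cfg), 0)
})

test_that("endothermic pups orient toward contact when cold, away when hot", {
  # littermate on the left (+y) of a pup heading +x
  litter <- litter_state(c(0, 0), c(0, 1.2), theta = c(0, 0), tb = 37)
  turn_at <- function(t_a) {
    cfg <- sim_config("endothermic", t_a = t_a, n_thermometers = 200L)
    f <- compute_contact_field(litter, n = 200)
    st <- surface_temperatures(f, cfg)
    m <- motor_speeds(transfer(st$t_left[1], 37, cfg),
                      transfer(st$t_right[1], 37, cfg))
    heading_increment(m$m_left, m$m_right, cfg)
  }
  expect_gt(turn_at(20), 0) # toward the contact on the left
  expect_lt(turn_at(45), 0) # away from it
})

test_that("mirror reflection negates heading increments", {
  set.seed(4)
  cfg <- sim_config("homeothermotaxic", t_a = 15, n_thermometers = 100L)
  litter <- litter_state(runif(4, -2, 2), runif(4, -2, 2),
                         theta = runif(4, 0, 2 * pi), tb = runif(4, 25, 40))
  inc <- function(l) {
    f <- compute_contact_field(l, n = 100)
    st <- surface_temperatures(f, cfg)
    m <- motor_speeds(transfer(st$t_left, l$tb, cfg),
                      transfer(st$t_right, l$tb, cfg))
    heading_increment(m$m_left, m$m_right, cfg)
  }
  mirrored <- litter_state(litter$x, -litter$y, theta = -litter$theta,
                           tb = litter$tb)
  expect_equal(inc(mirrored), -inc(litter), tolerance = 1e-12)
})

test_that("position update combines forward, boundary and collision terms", {
  cfg <- sim_config()
  # unobstructed pup moves at speed v2 along its heading
  iso <- fixture_litter("isolated")
  up <- position_update(iso, cfg)
  expect_equal(c(up$x, up$y), c(cfg$dt * cfg$v2, 0))

  # pup intruding on the wall is pushed back proportionally to incursion
  wall <- litter_state(9.5, 0, theta = pi / 2)
  upw <- position_update(wall, cfg)
  expect_equal(upw$x, 9.5 + cfg$dt * (10 - 9.5 - 1)) # beta = -0.5, inward
  # toggle off: no boundary force
  cfg_nb <- sim_config(boundary = FALSE)
  upn <- position_update(wall, cfg_nb)
  expect_equal(upn$x, 9.5)

  # overlapping pair springs apart with magnitude r - d/2 = 1/2 each
  lens <- fixture_litter("lens_pair_d_eq_r")
  upl <- position_update(litter_state(c(0, 1), c(0, 0), theta = pi / 2), cfg)
  expect_equal(upl$x, c(0 - cfg$dt * 0.5, 1 + cfg$dt * 0.5))
  expect_equal(upl$y, c(cfg$dt * cfg$v2, cfg$dt * cfg$v2))
})

test_that("unobstructed pups always advance at speed v2", {
  cfg <- sim_config()
  set.seed(6)
  for (i in 1:20) {
    l <- litter_state(runif(1, -5, 5), runif(1, -5, 5),
                      theta = runif(1, 0, 2 * pi))
    up <- position_update(l, cfg)
    speed <- sqrt((up$x - l$x)^2 + (up$y - l$y)^2) / cfg$dt
    expect_equal(speed, cfg$v2)
  }
})
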