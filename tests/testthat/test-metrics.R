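hand_traj <- function(eta_by_pup, x = NULL, y = NULL) {
  # build a minimal trajectory from per-pup eta series
  p <- length(eta_by_pup)
  nt <- length(eta_by_pup[[1]])
  tibble::tibble(
    step = rep(seq_len(nt), times = p),
    pup = rep(seq_len(p), each = nt),
    x = if (is.null(x)) 0 else x,
    y = if (is.null(y)) 0 else y,
    theta = 0,
    tb = 37,
    eta = unlist(eta_by_pup)
  )
}

test_that("huddling metric averages 1 - eta over pups and steps", {
  tr <- hand_traj(list(c(1, 0.5, 0.5)))
  expect_equal(huddling_metric(tr), 1 / 3)
  # all pups isolated at every step
  expect_equal(huddling_metric(hand_traj(list(c(1, 1), c(1, 1)))), 0)
  # equals the unweighted mean of the per-step series
  tr2 <- hand_traj(list(c(0.2, 0.6, 1), c(0.4, 0.8, 1)))
  per_step <- sapply(1:3, function(s) mean(1 - tr2$eta[tr2$step == s]))
  expect_equal(huddling_metric(tr2), mean(per_step))
  expect_equal(huddling_metric(tr2, per_pup = TRUE),
               c(1 - mean(c(0.2, 0.6, 1)), 1 - mean(c(0.4, 0.8, 1))))
})

test_that("pup flow measures the mean absolute change in exposure", {
  # alternating 0.4/0.6 over 5 steps: |diff| = 0.2 at each of 4 transitions
  tr <- hand_traj(list(c(0.4, 0.6, 0.4, 0.6, 0.4)))
  expect_equal(pup_flow(tr, scale = "step"), 0.2)
  expect_equal(pup_flow(tr, scale = "time", dt = 0.05), 4)
  # constant exposure contributes nothing
  tr2 <- hand_traj(list(rep(0.7, 5), c(0.4, 0.6, 0.4, 0.6, 0.4)))
  expect_equal(pup_flow(tr2, scale = "step"), 0.1)
  expect_equal(pup_flow(tr2, scale = "step", per_pup = TRUE), c(0, 0.2))
  expect_error(pup_flow(hand_traj(list(0.5)), scale = "step"), "2 recorded")
})

test_that("pup flow equals a brute-force recomputation from stored eta", {
  cfg <- test_config("homeothermotaxic", t_a = 16)
  cfg$steps <- 300L
  sim <- run_simulation(cfg, seed = 14)
  tr <- tidy(sim)
  brute <- mean(sapply(split(tr$eta, tr$pup),
                       function(e) mean(abs(diff(e)))))
  expect_equal(pup_flow(sim, scale = "step"), brute)
  expect_equal(pup_flow(sim), brute / cfg$dt)
})

test_that("subgroup counts come from contact-graph components", {
  expect_equal(count_subgroups(fixture_litter("chain12")), 1)
  expect_equal(count_subgroups(fixture_litter("two_clusters")), 2)
  far <- litter_state(10 * (1:12), rep(0, 12), arena_radius = 200)
  expect_equal(count_subgroups(far), 12)
  # touching (d = 2r) counts as connected
  expect_equal(count_subgroups(fixture_litter("touching_pair")), 1)
})

test_that("per-step component statistics agree with the igraph oracle", {
  set.seed(31)
  cfg <- sim_config("endothermic", t_a = 20, n_pups = 8L,
                    n_thermometers = 60L, steps = 40L, settle_steps = 5L)
  sim <- run_simulation(cfg, seed = 31)
  ser <- subgroup_series(sim)
  tr <- tidy(sim)
  for (s in c(1, 17, 40)) {
    snap <- tr[tr$step == s, ]
    litter <- litter_state(snap$x, snap$y)
    d <- as.matrix(stats::dist(cbind(snap$x, snap$y)))
    adj <- d <= 2; diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)
    expect_equal(ser$n_subgroups[ser$step == s], comp$no)
    expect_equal(ser$largest[ser$step == s], max(comp$csize))
  }
})

test_that("aggregate-size statistics respect litter bounds", {
  cfg <- sim_config("ectothermic", t_a = 10, n_pups = 6L,
                    n_thermometers = 60L, steps = 100L, settle_steps = 10L)
  sim <- run_simulation(cfg, seed = 1)
  mx <- largest_aggregate(sim, "max")
  mn <- largest_aggregate(sim, "mean")
  expect_lte(mx, 6)
  expect_lte(mn, mx)
  ser <- subgroup_series(sim)
  expect_true(all(ser$n_subgroups >= 1 & ser$n_subgroups <= 6))
  # a single component at some step implies largest = n_pups there
  expect_true(all((ser$largest == 6) == (ser$n_subgroups == 1) |
                    ser$largest < 6))
})

test_that("mean body temperature reduces correctly", {
  tr <- hand_traj(list(c(1, 1), c(1, 1)))
  tr$tb <- c(30, 32, 40, 38)
  expect_equal(mean_body_temperature(tr), 35)
  expect_equal(mean_body_temperature(tr, per_pup = TRUE), c(31, 39))
  # endothermic simulations report exactly the clamp
  cfg <- sim_config("endothermic", t_a = 20, n_pups = 4L,
                    n_thermometers = 60L, steps = 50L, settle_steps = 5L)
  expect_equal(mean_body_temperature(run_simulation(cfg, seed = 2)), 37)
})

test_that("subgroup counting is invariant to relabelling and rigid motion", {
  set.seed(17)
  litter <- litter_state(runif(7, -3, 3), runif(7, -3, 3))
  base <- count_subgroups(litter)
  perm <- sample(7)
  expect_equal(count_subgroups(litter_state(litter$x[perm],
                                            litter$y[perm])), base)
  a <- 0.8
  moved <- litter_state(2 + cos(a) * litter$x - sin(a) * litter$y,
                        -1 + sin(a) * litter$x + cos(a) * litter$y)
  expect_equal(count_subgroups(moved), base)
})
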