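base_hn <- function(delta1 = 0.5, seed = 1) {
  assign_purposes(generate_overlapping_hypernetwork(100, 15, 10, 0.5,
                                                    seed = seed),
                  delta1, seed = seed + 1000L)
}

test_that("seeding places the initial urn on distinct random nodes", {
  hn <- base_hn()
  traj <- initialize_state(hn, urn_params(0.5, 0.5), "false", seed = 3)
  expect_identical(nrow(traj$decisions), 10L)
  expect_identical(tail(traj$decisions$n_red, 1), 1L)
  expect_identical(tail(traj$decisions$n_blue, 1), 9L)
  expect_false(anyDuplicated(traj$decisions$node) > 0)
  expect_true(all(traj$decisions$step == 0L))
  eq <- initialize_state(hn, urn_params(0.5, 0.5), "equal", seed = 4)
  expect_identical(tail(eq$decisions$n_red, 1), 5L)
  empty <- initialize_state(hn, urn_params(0.5, 0.5),
                            start_condition("custom", 0, 0), seed = 5)
  expect_identical(nrow(empty$decisions), 0L)
  expect_error(initialize_state(fully_connected_hypernetwork(5, "RED"),
                                urn_params(0.5, 0.5), "false"),
               class = "hyperurn_invalid_config")
})

test_that("the local urn counts one ball per decided neighbour", {
  hn <- two_edge_fixture()
  traj <- initialize_state(hn, urn_params(0.5, 0.5),
                           start_condition("custom", 0, 0), seed = 1)
  expect_identical(local_urn(traj, 1), c(RED = 0L, BLUE = 0L))
  # hand-decide: 2,3,4 RED and 6 BLUE; node 5 sees all four, node 1 three
  traj$state[c(2, 3, 4)] <- "RED"
  traj$state[6] <- "BLUE"
  expect_identical(local_urn(traj, 5), c(RED = 3L, BLUE = 1L))
  expect_identical(local_urn(traj, 1), c(RED = 3L, BLUE = 0L))
  expect_identical(local_urn(traj, 7), c(RED = 0L, BLUE = 1L))
})

test_that("decide_one follows the forced branches", {
  hn <- two_edge_fixture()
  # ps = 1 with unanimous RED neighbours: any decider copies RED
  traj <- initialize_state(hn, urn_params(1, 0),
                           start_condition("custom", 3, 0), seed = 2)
  for (i in 1:6) traj <- decide_one(traj)
  expect_true(all(traj$state == "RED"))
  # ps = 0, pc = 1: everyone adopts a purpose colour
  hn_red <- hn
  hn_red$purposes <- c("RED", "RED")
  traj <- initialize_state(hn_red, urn_params(0, 1),
                           start_condition("custom", 0, 1), seed = 3)
  for (i in 1:8) traj <- decide_one(traj)
  expect_identical(sum(traj$state == "RED"), 8L)
  # ps = 0, pc = 0, qs = 1: pure preference
  traj <- initialize_state(hn, urn_params(0, 0, qs = 1),
                           start_condition("custom", 0, 0), seed = 4)
  traj <- decide_one(traj)
  expect_identical(unname(traj$state[!is.na(traj$state)]), "RED")
  expect_error({
    t2 <- initialize_state(fully_connected_hypernetwork(2, "RED"),
                           urn_params(0.5, 0.5),
                           start_condition("custom", 1, 1), seed = 1)
    decide_one(t2)
  }, class = "hyperurn_invalid_config")
})

test_that("forced parameter corners give exact final urns", {
  hn <- base_hn()
  for (engine in c("compiled", "reference")) {
    t1 <- run_simulation(hn, urn_params(0, 0, qs = 1), "false", seed = 5,
                         engine = engine)
    expect_identical(tail(t1$decisions$n_red, 1), 91L)
    expect_identical(tail(t1$decisions$n_blue, 1), 9L)
    expect_equal(final_shares(t1)$share, c(0.91, 0.09))
  }
  hn_red <- hn
  hn_red$purposes <- rep("RED", length(hn$hyperedges))
  t2 <- run_simulation(hn_red, urn_params(0, 1), "equal", seed = 6)
  expect_identical(tail(t2$decisions$n_red, 1), 95L)
  t3 <- run_simulation(hn, urn_params(0, 0, qs = 0), "correct", seed = 7)
  expect_identical(tail(t3$decisions$n_red, 1), 9L)
})

test_that("trajectories conserve the urn and decide everyone exactly once", {
  hn <- base_hn(delta1 = 0.3, seed = 9)
  for (seed in 1:5) {
    traj <- run_simulation(hn, urn_params(0.6, 0.4), "equal", seed = seed)
    d <- traj$decisions
    expect_identical(nrow(d), 100L)
    expect_identical(sort(d$node), 1:100)
    expect_true(all(d$n_red + d$n_blue == seq_len(100)))
    expect_true(all(diff(d$n_red) >= 0) && all(diff(d$n_blue) >= 0))
    expect_identical(d$step, c(rep(0L, 10L), 1:90))
  }
})

test_that("identical seeds reproduce trajectories and ensembles exactly", {
  hn <- base_hn()
  a <- run_simulation(hn, urn_params(0.5, 0.5), "false", seed = 11)
  b <- run_simulation(hn, urn_params(0.5, 0.5), "false", seed = 11)
  expect_identical(a$decisions, b$decisions)
  e1 <- run_ensemble(function() assign_purposes(hn, 0.5),
                     urn_params(0.5, 0.5), "false", runs = 20, base_seed = 3)
  e2 <- run_ensemble(function() assign_purposes(hn, 0.5),
                     urn_params(0.5, 0.5), "false", runs = 20, base_seed = 3)
  expect_identical(e1$shares, e2$shares)
})

test_that("ps = 0 ensembles match the binomial mean-field prediction", {
  # With no imitation every non-seed decision is an independent draw with
  # success probability pc * P(purpose RED) + (1 - pc) * qs.
  hn <- base_hn(delta1 = 0.3, seed = 13)
  pc <- 0.6
  p_red_edge <- mean(vapply(1:100, function(v) {
    own <- which(vapply(hn$hyperedges, function(e) v %in% e, logical(1)))
    mean(hn$purposes[own] == "RED")
  }, numeric(1)))
  p_hit <- pc * p_red_edge + (1 - pc) * 1
  W <- 400
  ens <- run_ensemble(hn, urn_params(0, pc, delta1 = 0.3), "false",
                      runs = W, base_seed = 21)
  expected <- (1 + 90 * p_hit) / 100
  se <- sqrt(90 * p_hit * (1 - p_hit)) / 100 / sqrt(W)
  expect_lt(abs(mean(ens$shares$red) - expected), 3 * se)
})

test_that("pure imitation on the full network is a martingale", {
  fc <- fully_connected_hypernetwork(100, "RED")
  W <- 400
  ens <- run_ensemble(fc, urn_params(1, 0.5), "false", runs = W,
                      base_seed = 31)
  # exact finite-n variance of the final share from the recursion
  d <- distribution_recursion(90, 10, 1, analytic_params(1, 0.5, 1, 1))
  shares <- (0:90 + 1) / 100
  mu <- sum(d$probs * shares)
  sigma2 <- sum(d$probs * (shares - mu)^2)
  expect_equal(mu, 0.1, tolerance = 1e-12)
  expect_lt(abs(mean(ens$shares$red) - 0.1), 3 * sqrt(sigma2 / W))
  # spread stays wide: no collapse to a point
  expect_gt(sd(ens$shares$red), 0.05)
})

test_that("reference engine matches the analytic distribution on one edge", {
  # m = 8, fixed RED purpose: the slow R stepper must reproduce the exact
  # mean-field distribution of final RED counts (chi-square, alpha = 0.001)
  fc <- fully_connected_hypernetwork(8, "RED")
  par <- urn_params(0.5, 0.5, delta1 = 1, qs = 1)
  start <- start_condition("custom", 1, 1)
  W <- 1500
  withr::with_seed(91, {
    finals <- vapply(seq_len(W), function(w)
      tail(run_simulation(fc, par, start, engine = "reference")$decisions$n_red,
           1), integer(1))
  })
  d <- distribution_recursion(6, 2, 1, analytic_params(0.5, 0.5, 1, 1))
  counts <- tabulate(finals, nbins = 7)  # final RED in 1..7
  expect_gt(gof_pvalue(counts, d$probs), 0.001)
})

test_that("ensembles record time-resolved urn counts on the common grid", {
  hn <- base_hn()
  ens <- run_ensemble(hn, urn_params(0.5, 0.5), "false", runs = 30,
                      base_seed = 41, record_time = TRUE)
  expect_identical(dim(ens$time_red), c(30L, 91L))
  expect_true(all(ens$time_red[, 1] == 1L))
  expect_identical(ens$time_red[, 91] / 100, ens$shares$red)
  expect_true(all(apply(ens$time_red, 1, function(r) all(diff(r) >= 0))))
})

test_that("trajectory and ensemble tidiers and CSV exports are consistent", {
  hn <- base_hn()
  traj <- run_simulation(hn, urn_params(0.5, 0.5), "false", seed = 51)
  td <- tidy(traj)
  expect_identical(nrow(td), 100L)
  expect_equal(td$share_red[100], glance(traj)$share_red)
  ens <- run_ensemble(hn, urn_params(0.5, 0.5), "false", runs = 10,
                      base_seed = 61)
  long <- tidy(ens)
  expect_identical(nrow(long), 20L)
  expect_true(all(long$share >= 0 & long$share <= 1))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, p1)
  write_ensemble_csv(ens, p2)
  expect_identical(nrow(utils::read.csv(p1)), 100L)
  expect_identical(nrow(utils::read.csv(p2)), 10L)
})
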