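test_that("enabled transitions follow rule/state disagreement and rates", {
  net <- boolean_network(list(
    node_decl("Prol_KC", "Prol_KC", rate_up = 1, rate_down = 0.2),
    node_decl("STAT3", "STAT3", rate_up = 1, rate_down = 0.2),
    node_decl("AMP", "Prol_KC AND STAT3", rate_up = "$ku_amp",
              rate_down = 0.7)))
  st <- c(Prol_KC = 1, STAT3 = 1, AMP = 0)
  en <- enabled_transitions(st, net, c(ku_amp = 1.5))
  # AMP's rule is satisfied by its inputs but AMP is off -> flips up at k_up
  expect_identical(en$node, "AMP")
  expect_equal(en$rate, 1.5)
  # state where every rule is satisfied is absorbing
  en2 <- enabled_transitions(c(Prol_KC = 1, STAT3 = 1, AMP = 1), net,
                             c(ku_amp = 1.5))
  expect_equal(nrow(en2), 0L)
  # AMP on with one input off -> flips down at k_down
  en3 <- enabled_transitions(c(Prol_KC = 0, STAT3 = 1, AMP = 1), net,
                             c(ku_amp = 1.5))
  expect_equal(en3[en3$node == "AMP", "rate"], 0.7)
})

test_that("two-node chain has exactly one enabled transition from (1,0)", {
  # enumerate the 4 states by hand: A constant-true, B copies A
  net <- two_node_chain()
  en <- enabled_transitions(c(A = 1, B = 0), net)
  expect_identical(en$node, "B")
  expect_equal(en$rate, 2)  # B's activation rate
  # from (0,0): only A is enabled (B's rule value equals its state)
  en0 <- enabled_transitions(c(A = 0, B = 0), net)
  expect_identical(en0$node, "A")
})

test_that("clamped nodes are never enabled", {
  net <- apply_clamp(two_node_chain(), "B", 0)
  en <- enabled_transitions(c(A = 1, B = 0), net)
  expect_equal(nrow(en), 0L)
})

test_that("trajectories are reproducible and stop in absorbing states", {
  net <- two_node_chain()
  t1 <- simulate_trajectory(net, numeric(0), c(A = 0, B = 0), 10, seed = 42)
  t2 <- simulate_trajectory(net, numeric(0), c(A = 0, B = 0), 10, seed = 42)
  expect_identical(t1, t2)
  expect_true(all(diff(t1$times) > 0))
  # all rates zero -> no jumps
  frozen <- boolean_network(list(node_decl("X", "1", 0, 0)))
  t0 <- simulate_trajectory(frozen, numeric(0), c(X = 0), 5, seed = 1)
  expect_length(t0$times, 0)
})

test_that("single constant-true node activates like 1 - exp(-kt)", {
  net <- boolean_network(list(node_decl("X", "1", rate_up = 1, rate_down = 0)))
  trajs <- simulate_trajectories(net, numeric(0), c(X = 0), 2, n = 10000,
                                 seed = 7)
  # fraction active at t = 1: count trajectories whose single jump came before 1
  active_at_1 <- mean(vapply(trajs, function(tr) {
    length(tr$times) > 0 && tr$times[1] <= 1
  }, logical(1)))
  p <- 1 - exp(-1)
  se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(active_at_1 - p), 3 * se)
})

test_that("estimate_marginals averages occupancy with weights", {
  frozen_on <- structure(
    list(init = c(X = 1L), times = numeric(0), flips = character(0),
         t_max = 4, nodes = "X"), class = "ctmc_trajectory")
  frozen_off <- structure(
    list(init = c(X = 0L), times = numeric(0), flips = character(0),
         t_max = 4, nodes = "X"), class = "ctmc_trajectory")
  m1 <- estimate_marginals(list(frozen_on, frozen_on), window_dt = 1)
  expect_true(all(m1$prob == 1))
  m2 <- estimate_marginals(list(frozen_on, frozen_off), window_dt = 1)
  expect_true(all(m2$prob == 0.5))
  m3 <- estimate_marginals(list(frozen_on, frozen_off), window_dt = 2,
                           weights = c(3, 1))
  expect_true(all(m3$prob == 0.75))
  # a jump mid-window splits occupancy proportionally
  jumpy <- structure(
    list(init = c(X = 0L), times = 0.5, flips = "X", t_max = 1, nodes = "X"),
    class = "ctmc_trajectory")
  expect_equal(as.vector(estimate_marginals(list(jumpy), 1)$prob), 0.5)
  expect_error(estimate_marginals(list(), 1), "empty")
})

test_that("windowed marginals match the analytic exponential activation", {
  ac <- make_analytic_case("exponential_activation", k = 1,
                           n_trajectories = 20000, t_max = 5,
                           window_dt = 0.5, seed = 3)
  tc <- run_ctmc(ac$net, ac$cfg)
  # exact window average of 1 - exp(-t)
  t0 <- tc$window_start
  t1 <- t0 + 0.5
  expected <- 1 - (exp(-t0) - exp(-t1)) / 0.5
  se <- sqrt(expected * (1 - expected) / 20000)
  expect_true(all(abs(tc$prob[, "X"] - expected) < 3 * pmax(se, 1e-4)))
})

test_that("ensemble marginals agree with the master equation (2-node oracle)", {
  net <- two_node_chain(ku_A = 0.8, kd_A = 0.4, ku_B = 1.5, kd_B = 0.7)
  cfg <- sim_config(n_trajectories = 20000, t_max = 6, window_dt = 1,
                    seed = 11)
  mc <- run_ctmc(net, cfg)
  ex <- master_equation_windows(net, numeric(0), numeric(0), 6, 1)
  se <- sqrt(ex$prob * (1 - ex$prob) / 20000)
  expect_true(all(abs(mc$prob - ex$prob) < 3 * pmax(se, 1e-4)))
})

test_that("a clamped node's marginal is constant at the clamp value", {
  net <- apply_clamp(two_node_chain(), "A", 1)
  cfg <- sim_config(n_trajectories = 2000, t_max = 4, window_dt = 1, seed = 5)
  tc <- run_ctmc(net, cfg)
  expect_true(all(tc$prob[, "A"] == 1))
})

test_that("after absorption marginals stay constant", {
  # A -> on (absorbing once both on, no down rates)
  net <- boolean_network(list(
    node_decl("A", "1", rate_up = 5, rate_down = 0),
    node_decl("B", "A", rate_up = 5, rate_down = 0)))
  cfg <- sim_config(n_trajectories = 500, t_max = 20, window_dt = 1, seed = 2)
  tc <- run_ctmc(net, cfg)
  expect_equal(unname(tc$prob[15, ]), c(1, 1))
  expect_equal(tc$prob[15, ], tc$prob[20, ])
})

test_that("timecourse export writes long-format TSV and JSON", {
  tc <- run_ctmc(two_node_chain(),
                 sim_config(n_trajectories = 100, t_max = 2, window_dt = 1,
                            seed = 1))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_timecourse(tc, tsv)
  write_timecourse(tc, js)
  back <- utils::read.delim(tsv)
  expect_identical(names(back), c("window_start", "node", "probability"))
  expect_equal(nrow(back), 4L)
  expect_equal(nrow(jsonlite::fromJSON(js)), 4L)
})
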