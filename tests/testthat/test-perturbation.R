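toy_fixture <- function(n_traj = 800, seed = 5) {
  toy <- make_toy_multiscale(seed = 3, n_trajectories = n_traj,
                             seed_sim = seed)
  toy$popcfg$n_steps <- 40
  toy
}

test_that("response_pct implements the percent-change formula", {
  expect_equal(response_pct(0.5, 0.5), 0)
  expect_equal(response_pct(0.18, 0.5), -64)
  expect_equal(response_pct(0.575, 0.5), 15)
  expect_true(is.na(response_pct(0.2, 0)))
  # antisymmetry identity: r(a,b) = -100 r(b,a) / (100 + r(b,a))
  set.seed(2)
  a <- stats::runif(20, 0.01, 1)
  b <- stats::runif(20, 0.01, 1)
  r_ab <- response_pct(a, b)
  r_ba <- response_pct(b, a)
  expect_equal(r_ab, -100 * r_ba / (100 + r_ba))
})

test_that("clamps validate their targets and force the state", {
  net <- two_node_chain()
  expect_error(apply_clamp(net, "Ghost", 0), "Ghost")
  expect_error(apply_clamp(net, "A", 2), "0 or 1")
  clamped <- apply_clamp(net, "B", 1)
  cfg <- sim_config(n_trajectories = 500, t_max = 3, window_dt = 1, seed = 1)
  expect_true(all(run_ctmc(clamped, cfg)$prob[, "B"] == 1))
})

test_that("treated arm equals untreated arm exactly before the switch", {
  toy <- toy_fixture()
  spec <- perturbation_spec(clamps = c(Lig1 = 0), switch_time = 20)
  res <- chained_run(toy$net, toy$cfg, toy$popcfg, spec, t_max = 40)
  pre <- res$untreated$time <= 20
  expect_identical(as.data.frame(res$untreated)[pre, ],
                   as.data.frame(res$treated)[pre, ])
})

test_that("a clamp holds the node marginal at the clamp value after the switch", {
  toy <- toy_fixture(n_traj = 400)
  spec <- perturbation_spec(clamps = c(Lig1 = 0), switch_time = 20)
  res <- chained_run(toy$net, toy$cfg, toy$popcfg, spec, t_max = 40)
  post <- res$treated$time > 20
  expect_true(all(res$treated$Lig1[post] == 0))
})

test_that("switching at t_max makes the arms identical", {
  toy <- toy_fixture(n_traj = 300)
  spec <- perturbation_spec(clamps = c(Lig1 = 0), switch_time = 40)
  res <- chained_run(toy$net, toy$cfg, toy$popcfg, spec, t_max = 40)
  expect_identical(as.data.frame(res$untreated), as.data.frame(res$treated))
  expect_true(all(res$response$response_pct == 0, na.rm = TRUE))
})

test_that("inhibiting the driving ligand suppresses a readout that is
           logically downstream of it only", {
  # Trigger -> L -> R -> out; out depends on nothing else, so clamping L at 0
  # must push the readout's response toward -100%.
  net <- boolean_network(list(
    node_decl("Trigger", "1", 0, 0, node_class = "utility"),
    node_decl("L", "Trigger", 2, 0.1, node_class = "ligand"),
    node_decl("R", "L", 2, 1, node_class = "receptor"),
    node_decl("Out", "R", 2, 1, node_class = "cell_state")))
  cfg <- sim_config(init = c(Trigger = 1), n_trajectories = 3000, t_max = 30,
                    window_dt = 1, seed = 7)
  popcfg <- pop_config(step_dt = 1, n_steps = 30)
  spec <- perturbation_spec(clamps = c(L = 0), switch_time = 10)
  res <- chained_run(net, cfg, popcfg, spec, t_max = 30,
                     readouts = data.frame(node = "Out", measure = "marginal"))
  expect_lt(res$response$response_pct, -90)
})

test_that("a self-sustaining positive loop does not revert when the trigger
           is removed (hysteresis)", {
  net <- boolean_network(list(
    node_decl("Trigger", "1", 0, 0, node_class = "utility"),
    node_decl("P", "Trigger OR Q", 2, 0.2),
    node_decl("Q", "P", 2, 0.2)))
  cfg <- sim_config(init = c(Trigger = 1), n_trajectories = 2000, t_max = 40,
                    window_dt = 1, seed = 13)
  popcfg <- pop_config(step_dt = 1, n_steps = 40)
  spec <- perturbation_spec(clamps = c(Trigger = 0), switch_time = 20)
  res <- chained_run(net, cfg, popcfg, spec, t_max = 40,
                     readouts = data.frame(node = c("P", "Q"),
                                           measure = "marginal"))
  # the on-state is absorbing for the P/Q loop: P=Q=1 satisfies both rules,
  # so the psoriatic-like state persists without the trigger
  last <- nrow(res$treated)
  expect_gt(res$treated$P[last], 0.9)
  expect_gt(res$treated$Q[last], 0.9)
})

test_that("rate-multiplier perturbations change the targeted parameter only", {
  # raising the inactivation rate of a toggling node lowers its steady level
  net <- boolean_network(list(node_decl("X", "NOT X", "$ku", "$kd")))
  cfg <- sim_config(parameters = c(ku = 1, kd = 1), n_trajectories = 4000,
                    t_max = 40, window_dt = 1, seed = 21)
  popcfg <- pop_config(step_dt = 1, n_steps = 40)
  spec <- perturbation_spec(rate_factors = c(kd = 3), switch_time = 20)
  res <- chained_run(net, cfg, popcfg, spec, t_max = 40,
                     readouts = data.frame(node = "X", measure = "marginal"))
  # steady level falls from ku/(ku+kd) = 0.5 to 1/(1+3) = 0.25
  expect_equal(res$response$untreated, 0.5, tolerance = 0.05)
  expect_equal(res$response$treated, 0.25, tolerance = 0.08)
})

test_that("the screen shares one untreated arm and counts rows correctly", {
  toy <- toy_fixture(n_traj = 400)
  cands <- druggable_targets(toy$net, switch_time = 20)
  readouts <- data.frame(node = c("Prol", "Cell1"), measure = "size")
  tab <- screen(toy$net, toy$cfg, toy$popcfg, cands, readouts, t_max = 40)
  expect_equal(nrow(tab), length(cands) * nrow(readouts))
  expect_identical(unique(tab$candidate), names(cands))
  # deterministic: rerun gives the same table
  tab2 <- screen(toy$net, toy$cfg, toy$popcfg, cands, readouts, t_max = 40)
  expect_identical(tab, tab2)
  # empty readout list -> empty table
  empty <- screen(toy$net, toy$cfg, toy$popcfg, cands,
                  data.frame(node = character(0), measure = character(0)),
                  t_max = 40)
  expect_equal(nrow(empty), 0L)
})

test_that("receptor candidates collapse onto their ligand when requested", {
  toy <- toy_fixture()
  with_rec <- druggable_targets(toy$net, collapse_receptors = FALSE)
  collapsed <- druggable_targets(toy$net, collapse_receptors = TRUE)
  receptors <- node_annotations(toy$net)
  receptors <- receptors$node[receptors$node_class == "receptor"]
  expect_true(all(receptors %in% names(with_rec)))
  expect_false(any(receptors %in% names(collapsed)))
  expect_true(all(setdiff(names(with_rec), receptors) %in% names(collapsed)))
})
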