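# Synthetic models -----------------------------------------------------------
#
# Three families of generated fixtures: (i) analytic CTMC cases whose exact
# behaviour has a closed form or an exactly integrable master equation;
# (ii) toy multiscale disease models with the architecture of the full
# psoriasis model (trigger, cell nodes, ligand -> receptor -> transcription
# factor chains, a proliferating cell state wired to Division/Death,
# optional cross-layer feedback, receptor rates updated from ligand
# probabilities); (iii) random signed digraphs for FVS oracle testing.

#' Analytically solvable simulation cases
#'
#' * `exponential_activation`: one constant-true node with activation rate
#'   `k`; P(on at t) = 1 - exp(-k t).
#' * `birth_growth`: a Division node firing at constant rate `d` with no
#'   death; pop_ratio(t) -> exp(d t) as step_dt -> 0.
#' * `death_decay`: a Death node firing at constant rate `m`;
#'   pop_ratio(t) -> exp(-m t).
#' * `two_node_master_equation`: A toggling between its states (rule
#'   `NOT A`, so both rates act), B copying A; the exact marginals come
#'   from the 4-state master equation.
#'
#' @param name one of the cases above.
#' @param k,d,m,ku_A,kd_A,ku_B,kd_B case rates (per hour).
#' @param step_dt population step for the birth/death cases.
#' @param n_trajectories,t_max,window_dt,seed Monte-Carlo settings.
#' @return list with `net`, `cfg`, `popcfg` (population cases only), and
#'   `expectation`, a function of time giving the exact marginal of the
#'   `watch` node (activation cases) or the exact small-step pop_ratio
#'   limit (population cases).
#' @export
make_analytic_case <- function(name = c("exponential_activation",
                                        "birth_growth", "death_decay",
                                        "two_node_master_equation"),
                               k = 1, d = 0.05, m = 0.05,
                               ku_A = 1, kd_A = 0.5, ku_B = 2, kd_B = 1,
                               step_dt = 0.1, n_trajectories = 50000,
                               t_max = 10, window_dt = 1, seed = 1L) {
  name <- match.arg(name)
  switch(
    name,
    exponential_activation = {
      net <- boolean_network(list(
        node_decl("X", "1", rate_up = "$k", rate_down = 0)))
      cfg <- sim_config(parameters = c(k = k),
                        n_trajectories = n_trajectories, t_max = t_max,
                        window_dt = window_dt, seed = seed)
      list(net = net, cfg = cfg, popcfg = NULL, watch = "X",
           expectation = function(t) 1 - exp(-k * t))
    },
    birth_growth = {
      net <- boolean_network(list(
        node_decl("Division", "1", rate_up = "$d", rate_down = 0,
                  node_class = "utility")))
      cfg <- sim_config(parameters = c(d = d),
                        n_trajectories = n_trajectories, t_max = t_max,
                        window_dt = step_dt, seed = seed)
      popcfg <- pop_config(step_dt = step_dt,
                           n_steps = round(t_max / step_dt))
      list(net = net, cfg = cfg, popcfg = popcfg, watch = "Division",
           expectation = function(t) exp(d * t))
    },
    death_decay = {
      net <- boolean_network(list(
        node_decl("Death", "1", rate_up = "$m", rate_down = 0,
                  node_class = "utility")))
      cfg <- sim_config(parameters = c(m = m),
                        n_trajectories = n_trajectories, t_max = t_max,
                        window_dt = step_dt, seed = seed)
      popcfg <- pop_config(step_dt = step_dt,
                           n_steps = round(t_max / step_dt))
      list(net = net, cfg = cfg, popcfg = popcfg, watch = "Death",
           expectation = function(t) exp(-m * t))
    },
    two_node_master_equation = {
      net <- boolean_network(list(
        node_decl("A", "NOT A", rate_up = "$ku_A", rate_down = "$kd_A"),
        node_decl("B", "A", rate_up = "$ku_B", rate_down = "$kd_B")))
      params <- c(ku_A = ku_A, kd_A = kd_A, ku_B = ku_B, kd_B = kd_B)
      cfg <- sim_config(parameters = params,
                        n_trajectories = n_trajectories, t_max = t_max,
                        window_dt = window_dt, seed = seed)
      list(net = net, cfg = cfg, popcfg = NULL, watch = c("A", "B"),
           expectation = function(t) {
             master_equation_marginals(net, params, numeric(0), t)
           })
    })
}

.log_uniform <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

#' Generate a toy multiscale disease model
#'
#' Emulates the architecture of the full psoriasis model at a size where the
#' master-equation oracle stays feasible: a Trigger activates an immune cell
#' layer; each active cell drives one or more ligand -> receptor ->
#' transcription factor chains; the first chain's transcription factor
#' drives a proliferating cell state (`Prol`) that is wired to Division and
#' Death; with `feedback = TRUE` the proliferating state produces a ligand
#' that re-activates the cell layer, closing the cross-layer loop that makes
#' the disease state self-sustaining.  Receptor activation rates are
#' declared as population-step update rules on their ligand's probability.
#' Rates are sampled log-uniformly in \[0.01, 10\] per hour within
#' type-specific bands (ligands decay fast), reproducibly under `seed`.
#'
#' @param n_cells number of parallel cell nodes (>= 1).
#' @param n_ligand_chains ligand/receptor/TF chains per cell.
#' @param feedback close the Prol -> ligand -> cell loop.
#' @param seed RNG seed for rate sampling.
#' @param n_trajectories,seed_sim Monte-Carlo settings of the returned
#'   configuration.
#' @return list with `net`, `cfg`, `popcfg`.
#' @export
make_toy_multiscale <- function(n_cells = 1, n_ligand_chains = 2,
                                feedback = TRUE, seed = 1L,
                                n_trajectories = 5000, seed_sim = 1L) {
  stopifnot(n_cells >= 1, n_ligand_chains >= 1)
  set.seed(seed)
  nodes <- list()
  params <- numeric(0)
  upd <- character(0)
  add <- function(name, logic, ku, kd, cls) {
    params[[paste0("ku_", name)]] <<- ku
    params[[paste0("kd_", name)]] <<- kd
    nodes[[length(nodes) + 1L]] <<- node_decl(
      name, logic, rate_up = paste0("$ku_", name),
      rate_down = paste0("$kd_", name), node_class = cls)
  }
  add("Trigger", "1", 0, 0, "utility")  # both rates 0: holds its initial state
  cells <- paste0("Cell", seq_len(n_cells))
  fb_receptor <- "Rec_FB"
  for (ci in seq_len(n_cells)) {
    logic <- if (feedback && ci == 1L) {
      sprintf("Trigger OR %s", fb_receptor)
    } else "Trigger"
    add(cells[ci], logic, .log_uniform(1, 0.2, 2), .log_uniform(1, 0.01, 0.1),
        "cell")
  }
  for (li in seq_len(n_ligand_chains)) {
    lig <- paste0("Lig", li)
    rec <- paste0("Rec", li)
    tf <- paste0("TF", li)
    add(lig, cells[1L + (li - 1L) %% n_cells],
        .log_uniform(1, 0.5, 2), .log_uniform(1, 2, 10), "ligand")
    add(rec, lig, 0, .log_uniform(1, 0.1, 1), "receptor")
    c_rec <- .log_uniform(1, 0.5, 2)
    params[[paste0("c_", rec)]] <- c_rec
    upd[[paste0("ku_", rec)]] <- sprintf("$c_%s * p(%s)", rec, lig)
    add(tf, rec, .log_uniform(1, 0.5, 2), .log_uniform(1, 0.1, 1),
        "transcription_factor")
  }
  add("Prol", "TF1", .log_uniform(1, 0.5, 2), .log_uniform(1, 0.01, 0.1),
      "cell_state")
  add("Division", "Prol", .log_uniform(1, 0.02, 0.1), 0, "utility")
  add("Death", "NOT Prol", .log_uniform(1, 0.005, 0.02), 0, "utility")
  if (feedback) {
    add("Lig_FB", "Prol", .log_uniform(1, 0.5, 2), .log_uniform(1, 2, 10),
        "ligand")
    add(fb_receptor, "Lig_FB", 0, .log_uniform(1, 0.1, 1), "receptor")
    c_rec <- .log_uniform(1, 0.5, 2)
    params[["c_Rec_FB"]] <- c_rec
    upd[["ku_Rec_FB"]] <- "$c_Rec_FB * p(Lig_FB)"
  }
  net <- boolean_network(nodes)
  cfg <- sim_config(parameters = params, init = c(Trigger = 1),
                    n_trajectories = n_trajectories, t_max = 100,
                    window_dt = 1, seed = seed_sim)
  popcfg <- pop_config(step_dt = 1, n_steps = 100, update_rules = upd)
  list(net = net, cfg = cfg, popcfg = popcfg)
}

#' Random signed digraph
#'
#' Directed Erdős–Rényi graph with independent edge probability and random
#' +/-1 signs, reproducible under `seed`; used as the test bed for the FVS
#' enumeration oracle.
#'
#' @param n number of nodes.
#' @param edge_prob probability of each ordered (u, v) edge, u != v.
#' @param seed RNG seed.
#' @param allow_self_loops include u -> u edges (default FALSE).
#' @return igraph with `sign` edge attribute; nodes named `n01`, `n02`, ...
#' @export
make_random_digraph <- function(n, edge_prob, seed = 1L,
                                allow_self_loops = FALSE) {
  set.seed(seed)
  nn <- sprintf("n%02d", seq_len(n))
  pairs <- expand.grid(from = nn, to = nn, stringsAsFactors = FALSE)
  if (!allow_self_loops) pairs <- pairs[pairs$from != pairs$to, ]
  keep <- stats::runif(nrow(pairs)) < edge_prob
  edges <- pairs[keep, , drop = FALSE]
  edges$sign <- ifelse(stats::runif(nrow(edges)) < 0.5, -1L, 1L)
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nn)
}
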