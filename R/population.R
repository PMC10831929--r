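# Population layer (UPMaBoSS semantics) -------------------------------------
#
# The CTMC runs in synchronous steps of step_dt hours.  At the end of each
# step the weighted distribution of joint states is adjusted: trajectories
# with the Death node active lose all mass; trajectories with the Division
# node active have their mass doubled and the Division bit reset (daughters
# inherit the mother's other node states).  The total mass after adjustment
# is the step's growth factor, accumulated multiplicatively into pop_ratio.
# Finally the externally updated rate parameters (receptor activation driven
# by ligand probability, the cell-communication mechanism) are recomputed
# from the end-of-step marginals before the next step begins.

#' Weighted distribution over joint states
#'
#' @param states logical/0-1 matrix, one row per trajectory, columns named
#'   by node.
#' @param weights nonnegative weights summing to 1 (renormalised if not).
#' @return object of class `step_distribution`.
#' @export
step_distribution <- function(states, weights = NULL) {
  states <- as.matrix(states) > 0
  if (is.null(weights)) weights <- rep(1 / nrow(states), nrow(states))
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  s <- sum(weights)
  if (s <= 0) stop("total weight must be positive", call. = FALSE)
  structure(list(states = states, weights = weights / s),
            class = "step_distribution")
}

#' Apply the Division/Death population update
#'
#' States with the Death node active are removed (weight set to 0); states
#' with the Division node active have their weight doubled and the Division
#' bit reset to 0.  When both nodes are active in the same state,
#' `death_precedence` decides which applies.  The growth factor is the total
#' mass after adjustment — `1 + P(division) - P(death)` when the two are
#' disjoint — and the returned distribution is renormalised.
#'
#' @param dist a [step_distribution()].
#' @param division_node,death_node node names (either may be `NULL`).
#' @param death_precedence if `TRUE` (default), Death wins on a state with
#'   both nodes active.
#' @return list with `dist` (renormalised `step_distribution`, or `NULL` on
#'   extinction), `growth_factor`, and `extinct` flag.
#' @export
apply_division_death <- function(dist, division_node = "Division",
                                 death_node = "Death",
                                 death_precedence = TRUE) {
  stopifnot(inherits(dist, "step_distribution"))
  states <- dist$states
  w <- dist$weights
  dying <- if (!is.null(death_node) && death_node %in% colnames(states)) {
    states[, death_node]
  } else rep(FALSE, nrow(states))
  dividing <- if (!is.null(division_node) && division_node %in% colnames(states)) {
    states[, division_node]
  } else rep(FALSE, nrow(states))
  if (death_precedence) {
    dividing <- dividing & !dying
  } else {
    dying <- dying & !dividing
  }
  w2 <- w
  w2[dying] <- 0
  w2[dividing] <- 2 * w2[dividing]
  growth <- sum(w2)
  if (growth <= 0) {
    return(list(dist = NULL, growth_factor = 0, extinct = TRUE))
  }
  if (any(dividing)) states[dividing, division_node] <- FALSE
  list(dist = step_distribution(states, w2), growth_factor = growth,
       extinct = FALSE)
}

#' Recompute externally updated rate parameters
#'
#' Each update rule sets one parameter from a formula over end-of-step node
#' marginals (`p(Node)`) and the current `pop_ratio`; every other parameter
#' is untouched.  New values must be nonnegative and finite.
#'
#' @param params named numeric vector of current parameter values.
#' @param marginals named numeric vector of node activation probabilities.
#' @param pop_ratio current population ratio.
#' @param update_rules the `update_rules` element of a [pop_config()].
#' @return updated parameter vector.
#' @export
update_external_rates <- function(params, marginals, pop_ratio, update_rules) {
  if (length(update_rules) == 0L) return(params)
  marg <- marginals
  pfun <- function(node) {
    nm <- as.character(substitute(node))
    if (!nm %in% names(marg)) {
      # allow p("Name") as well as p(Name)
      if (is.character(node) && node %in% names(marg)) return(marg[[node]])
      stop(sprintf("update formula references unknown node '%s'", nm),
           call. = FALSE)
    }
    marg[[nm]]
  }
  env <- list2env(as.list(params), parent = baseenv())
  assign("p", pfun, envir = env)
  assign("pop_ratio", pop_ratio, envir = env)
  assign("min", min, envir = env)
  assign("max", max, envir = env)
  for (r in update_rules) {
    val <- eval(r$expr, envir = env)
    if (!is.finite(val) || val < 0) {
      stop(sprintf("update rule for '%s' produced an invalid rate (%s)",
                   r$param, format(val)), call. = FALSE)
    }
    params[[r$param]] <- val
  }
  params
}

# Core synchronous-step loop.  `state` carries everything that evolves:
# trajectory states/weights, bound parameters, pop_ratio, step counter.
# Returns the records plus the final state, so runs can be chained.
.pop_engine <- function(net, params, popcfg, states, weights, pop_ratio,
                        n_steps, step_offset = 0L) {
  cm <- .compile_model(net, params)
  nn <- cm$nodes
  cell_nodes <- node_annotations(net)
  cell_nodes <- cell_nodes$node[cell_nodes$node_class %in% c("cell", "cell_state")]
  rec_marg <- matrix(NA_real_, n_steps, length(nn), dimnames = list(NULL, nn))
  rec_ratio <- numeric(n_steps)
  extinct_at <- NA_integer_
  for (s in seq_len(n_steps)) {
    res <- .simulate_window(cm, states, popcfg$step_dt)
    states <- res$states
    # time-averaged marginals within the step, weighted by entry weights
    rec_marg[s, ] <- colSums(res$occ * weights) / popcfg$step_dt
    upd <- apply_division_death(
      step_distribution(states, weights),
      division_node = net$division_node, death_node = net$death_node,
      death_precedence = popcfg$death_precedence)
    if (upd$extinct) {
      pop_ratio <- 0
      rec_ratio[s] <- 0
      extinct_at <- step_offset + s
      rec_marg <- rec_marg[seq_len(s), , drop = FALSE]
      rec_ratio <- rec_ratio[seq_len(s)]
      break
    }
    states <- upd$dist$states
    weights <- upd$dist$weights
    # systematic resampling when division/death reweighting has collapsed
    # the effective sample size; keeps the ensemble unbiased while
    # restoring equal weights (the next step redraws from the updated
    # distribution, as in distribution-based population updating)
    n_traj <- nrow(states)
    if (1 / sum(weights^2) < n_traj / 2) {
      pos <- (stats::runif(1L) + seq_len(n_traj) - 1L) / n_traj
      idx <- pmin(findInterval(pos, cumsum(weights)) + 1L, n_traj)
      states <- states[idx, , drop = FALSE]
      weights <- rep(1 / n_traj, n_traj)
    }
    pop_ratio <- pop_ratio * upd$growth_factor
    rec_ratio[s] <- pop_ratio
    if (length(popcfg$update_rules)) {
      end_marg <- stats::setNames(colSums(states * weights), nn)
      params <- update_external_rates(params, end_marg, pop_ratio,
                                      popcfg$update_rules)
      cm <- .compile_model(net, params)
    }
  }
  list(marginals = rec_marg, pop_ratio = rec_ratio, states = states,
       weights = weights, params = params, final_ratio = pop_ratio,
       cell_nodes = cell_nodes, extinct_at = extinct_at)
}

.pop_timecourse_from_engine <- function(eng, popcfg, step_offset = 0L) {
  n <- nrow(eng$marginals)
  steps <- step_offset + seq_len(n)
  df <- data.frame(step = steps, time = steps * popcfg$step_dt,
                   pop_ratio = eng$pop_ratio)
  df <- cbind(df, as.data.frame(eng$marginals))
  for (cn in eng$cell_nodes) {
    df[[paste0("size_", cn)]] <- eng$marginals[, cn] * eng$pop_ratio
  }
  structure(df, class = c("pop_timecourse", "data.frame"),
            step_dt = popcfg$step_dt, cell_nodes = eng$cell_nodes,
            extinct_at = eng$extinct_at)
}

#' Run a population simulation
#'
#' Loops `n_steps` synchronous steps: simulate `step_dt` hours of CTMC
#' dynamics from the current weighted distribution, apply the
#' Division/Death update, accumulate `pop_ratio`, and recompute the
#' externally updated rates.  With no Division/Death nodes and no update
#' rules this reduces exactly to the plain windowed ensemble run (same
#' seeds, same numbers).
#'
#' @param net a `boolean_network`.
#' @param cfg a [sim_config()] (`t_max`/`window_dt` are ignored here; the
#'   horizon is `popcfg$n_steps * popcfg$step_dt`).
#' @param popcfg a [pop_config()].
#' @return a `pop_timecourse` data.frame: `step`, `time`, `pop_ratio`, one
#'   column per node (step-averaged marginal) and `size_<node>` columns for
#'   cell/cell-state nodes (marginal times pop_ratio).  A population that
#'   goes extinct truncates the timecourse; the step is recorded in the
#'   `extinct_at` attribute.
#' @export
run_population <- function(net, cfg, popcfg) {
  .validate_popcfg(popcfg, net, cfg$parameters)
  set.seed(cfg$seed)
  states <- .sample_init_states(net, cfg, cfg$n_trajectories)
  weights <- rep(1 / nrow(states), nrow(states))
  eng <- .pop_engine(net, cfg$parameters, popcfg, states, weights,
                     pop_ratio = 1, n_steps = popcfg$n_steps)
  .pop_timecourse_from_engine(eng, popcfg)
}

#' @export
print.pop_timecourse <- function(x, ...) {
  cat(sprintf("pop_timecourse: %d steps of %g h, final pop_ratio %.4g\n",
              nrow(x), attr(x, "step_dt"), x$pop_ratio[nrow(x)]))
  if (!is.na(attr(x, "extinct_at"))) {
    cat(sprintf("  population extinct at step %d\n", attr(x, "extinct_at")))
  }
  invisible(x)
}

# Marginal columns of a pop_timecourse (excludes bookkeeping and sizes).
.tc_marginal_cols <- function(tc) {
  setdiff(names(tc), c("step", "time", "pop_ratio",
                       grep("^size_", names(tc), value = TRUE)))
}
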