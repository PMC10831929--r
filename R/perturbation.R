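# Chained perturbation simulations ------------------------------------------
#
# Protocol: the untreated arm runs from the trigger at t = 0 to t_max; the
# treated arm reuses the untreated population state at switch_time, applies
# the perturbation (node clamps and/or rate-parameter multipliers), and
# continues to t_max.  Both arms share the random stream up to the switch
# and at the switch, so pre-switch windows are identical and post-switch
# differences are treatment, not Monte-Carlo noise.  Responses are
# quantified per readout as 100 * (p_treated - p_untreated) / p_untreated
# at the evaluation time.

#' Clamp a node
#'
#' Forces a node's state to 0 (inhibitory perturbation) or 1 (activating
#' perturbation): the node undergoes no further transitions; other nodes'
#' logic is unchanged.
#'
#' @param net a `boolean_network`.
#' @param node node name.
#' @param value 0 or 1.
#' @return the network with the clamp recorded.
#' @export
apply_clamp <- function(net, node, value) {
  if (!node %in% node_names(net)) {
    stop(sprintf("unknown node '%s'", node), call. = FALSE)
  }
  if (!value %in% c(0, 1)) stop("clamp value must be 0 or 1", call. = FALSE)
  net$clamped[node] <- value
  net
}

#' Describe a perturbation
#'
#' @param clamps named 0/1 vector: nodes fixed at the given value from the
#'   switch onwards.
#' @param rate_factors named numeric vector: rate parameters multiplied by
#'   the given factor at the switch (e.g. faster downregulation of a target).
#' @param switch_time hours at which the perturbation is introduced.
#' @return object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(clamps = numeric(0), rate_factors = numeric(0),
                              switch_time = 300) {
  if (length(clamps) && !all(clamps %in% c(0, 1))) {
    stop("clamp values must be 0 or 1", call. = FALSE)
  }
  if (length(rate_factors) && any(rate_factors < 0)) {
    stop("rate factors must be nonnegative", call. = FALSE)
  }
  if (length(clamps) + length(rate_factors) == 0L) {
    stop("empty perturbation", call. = FALSE)
  }
  structure(list(clamps = clamps, rate_factors = rate_factors,
                 switch_time = switch_time),
            class = "perturbation_spec")
}

#' @export
print.perturbation_spec <- function(x, ...) {
  cat("perturbation:",
      paste(c(sprintf("%s=%d", names(x$clamps), x$clamps),
              sprintf("%s x%g", names(x$rate_factors), x$rate_factors)),
            collapse = ", "),
      sprintf("at t=%g\n", x$switch_time))
  invisible(x)
}

.describe_spec <- function(spec) {
  paste(c(sprintf("%s=%d", names(spec$clamps), spec$clamps),
          sprintf("%s*%g", names(spec$rate_factors), spec$rate_factors)),
        collapse = "+")
}

#' Percent response of a readout
#'
#' `100 * (p_treated - p_untreated) / p_untreated`; undefined (NA) where the
#' untreated probability is 0.
#'
#' @param p_treated,p_wt probabilities (vectorised).
#' @return percent change.
#' @export
response_pct <- function(p_treated, p_wt) {
  out <- 100 * (p_treated - p_wt) / p_wt
  out[p_wt == 0] <- NA_real_
  out
}

#' Default readouts of a model
#'
#' Cell and cell-state nodes, measured as population size when the model has
#' a Division node (size = marginal x pop_ratio) and as plain activation
#' probability otherwise.
#'
#' @param net a `boolean_network`.
#' @return data.frame with columns `node`, `measure`.
#' @export
default_readouts <- function(net) {
  ann <- node_annotations(net)
  nodes <- ann$node[ann$node_class %in% c("cell", "cell_state")]
  if (length(nodes) == 0L) nodes <- setdiff(node_names(net),
                                            c(net$division_node,
                                              net$death_node,
                                              net$trigger_node))
  measure <- if (!is.null(net$division_node)) "size" else "marginal"
  data.frame(node = nodes, measure = measure, stringsAsFactors = FALSE)
}

.as_readouts <- function(readouts, net) {
  if (is.null(readouts)) return(default_readouts(net))
  if (is.character(readouts)) {
    readouts <- data.frame(node = readouts,
                           measure = if (!is.null(net$division_node))
                             "size" else "marginal",
                           stringsAsFactors = FALSE)
  }
  unknown <- setdiff(readouts$node, node_names(net))
  if (length(unknown)) {
    stop(sprintf("unknown readout node(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  bad <- !readouts$measure %in% c("marginal", "size")
  if (any(bad)) stop("readout measure must be 'marginal' or 'size'",
                     call. = FALSE)
  readouts
}

.readout_value <- function(tc, node, measure, at_time) {
  i <- which.min(abs(tc$time - at_time))
  if (measure == "size") {
    col <- paste0("size_", node)
    if (!col %in% names(tc)) col <- node  # fall back to marginal
  } else {
    col <- node
  }
  tc[[col]][i]
}

# Shared pre-switch arm: run to the switch, snapshot everything needed to
# branch (states, weights, bound parameters, pop_ratio, the RNG state).
.baseline_to_switch <- function(net, cfg, popcfg, switch_time) {
  n_pre <- round(switch_time / popcfg$step_dt)
  if (abs(switch_time / popcfg$step_dt - n_pre) > 1e-9) {
    stop("step_dt must divide switch_time", call. = FALSE)
  }
  .validate_popcfg(popcfg, net, cfg$parameters)
  set.seed(cfg$seed)
  states <- .sample_init_states(net, cfg, cfg$n_trajectories)
  weights <- rep(1 / nrow(states), nrow(states))
  eng <- if (n_pre > 0L) {
    .pop_engine(net, cfg$parameters, popcfg, states, weights, 1, n_pre)
  } else {
    list(marginals = matrix(numeric(0), 0L, length(node_names(net)),
                            dimnames = list(NULL, node_names(net))),
         pop_ratio = numeric(0), states = states, weights = weights,
         params = cfg$parameters, final_ratio = 1,
         cell_nodes = default_readouts(net)$node, extinct_at = NA_integer_)
  }
  if (!is.na(eng$extinct_at)) {
    stop("population extinct before the switch", call. = FALSE)
  }
  list(eng = eng, n_pre = n_pre, rng = .GlobalEnv$.Random.seed)
}

.continue_arm <- function(net, popcfg, base, n_post) {
  assign(".Random.seed", base$rng, envir = .GlobalEnv)
  eng <- .pop_engine(net, base$eng$params, popcfg, base$eng$states,
                     base$eng$weights, base$eng$final_ratio, n_post,
                     step_offset = base$n_pre)
  pre <- base$eng
  full <- list(
    marginals = rbind(pre$marginals, eng$marginals),
    pop_ratio = c(pre$pop_ratio, eng$pop_ratio),
    cell_nodes = pre$cell_nodes, extinct_at = eng$extinct_at)
  .pop_timecourse_from_engine(full, popcfg)
}

.perturbed_net_params <- function(net, params, spec) {
  for (nm in names(spec$clamps)) {
    net <- apply_clamp(net, nm, spec$clamps[[nm]])
  }
  for (nm in names(spec$rate_factors)) {
    if (!nm %in% names(params)) {
      stop(sprintf("unknown rate parameter '%s'", nm), call. = FALSE)
    }
    params[[nm]] <- params[[nm]] * spec$rate_factors[[nm]]
  }
  list(net = net, params = params)
}

.treated_arm <- function(net, popcfg, base, spec, n_post) {
  pp <- .perturbed_net_params(net, base$eng$params, spec)
  states <- base$eng$states
  for (nm in names(spec$clamps)) {
    states[, nm] <- spec$clamps[[nm]] > 0
  }
  assign(".Random.seed", base$rng, envir = .GlobalEnv)
  eng <- .pop_engine(pp$net, pp$params, popcfg, states, base$eng$weights,
                     base$eng$final_ratio, n_post, step_offset = base$n_pre)
  pre <- base$eng
  full <- list(
    marginals = rbind(pre$marginals, eng$marginals),
    pop_ratio = c(pre$pop_ratio, eng$pop_ratio),
    cell_nodes = pre$cell_nodes, extinct_at = eng$extinct_at)
  .pop_timecourse_from_engine(full, popcfg)
}

#' Chained untreated/treated run
#'
#' @param net a `boolean_network` (trigger applied via `cfg$init`).
#' @param cfg a [sim_config()].
#' @param popcfg a [pop_config()].
#' @param spec a [perturbation_spec()].
#' @param t_max full horizon in hours (default 600).
#' @param eval_time time at which responses are computed (default `t_max`).
#' @param readouts `NULL` for [default_readouts()], a character vector of
#'   node names, or a data.frame with columns `node` and `measure`
#'   (`"marginal"` or `"size"`).
#' @return object of class `perturbation_result`: `untreated` and `treated`
#'   `pop_timecourse`s and a `response` table (node, measure, untreated,
#'   treated, response_pct).
#' @export
chained_run <- function(net, cfg, popcfg, spec, t_max = 600,
                        eval_time = t_max, readouts = NULL) {
  stopifnot(inherits(spec, "perturbation_spec"))
  if (spec$switch_time > t_max) {
    stop("switch_time must lie within the horizon", call. = FALSE)
  }
  readouts <- .as_readouts(readouts, net)
  n_post <- round((t_max - spec$switch_time) / popcfg$step_dt)
  base <- .baseline_to_switch(net, cfg, popcfg, spec$switch_time)
  untreated <- .continue_arm(net, popcfg, base, n_post)
  treated <- .treated_arm(net, popcfg, base, spec, n_post)
  resp <- .response_table(untreated, treated, readouts, eval_time)
  structure(list(untreated = untreated, treated = treated, response = resp,
                 spec = spec, eval_time = eval_time),
            class = "perturbation_result")
}

.response_table <- function(untreated, treated, readouts, eval_time) {
  if (nrow(readouts) == 0L) {
    return(data.frame(node = character(0), measure = character(0),
                      untreated = numeric(0), treated = numeric(0),
                      response_pct = numeric(0)))
  }
  p_wt <- mapply(.readout_value, readouts$node, readouts$measure,
                 MoreArgs = list(tc = untreated, at_time = eval_time))
  p_tr <- mapply(.readout_value, readouts$node, readouts$measure,
                 MoreArgs = list(tc = treated, at_time = eval_time))
  data.frame(node = readouts$node, measure = readouts$measure,
             untreated = unname(p_wt), treated = unname(p_tr),
             response_pct = unname(response_pct(p_tr, p_wt)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat(sprintf("perturbation_result: %s, evaluated at t=%g\n",
              .describe_spec(x$spec), x$eval_time))
  print(x$response, digits = 4)
  invisible(x)
}

#' Systematic perturbation screen
#'
#' Runs the shared untreated arm once, then one treated continuation per
#' candidate, and tabulates the percent response of every readout at the
#' evaluation time.  Rows are ordered by candidate then readout.
#'
#' @inheritParams chained_run
#' @param candidates non-empty named list of [perturbation_spec()]s sharing
#'   one `switch_time`.
#' @return data.frame: `candidate`, `perturbation`, `node`, `measure`,
#'   `untreated`, `treated`, `response_pct`.
#' @export
screen <- function(net, cfg, popcfg, candidates, readouts = NULL,
                   t_max = 600, eval_time = t_max) {
  if (length(candidates) == 0L) stop("no candidates", call. = FALSE)
  if (is.null(names(candidates))) {
    names(candidates) <- vapply(candidates, .describe_spec, character(1))
  }
  switch_times <- unique(vapply(candidates, `[[`, numeric(1), "switch_time"))
  if (length(switch_times) != 1L) {
    stop("all candidates must share one switch_time", call. = FALSE)
  }
  readouts <- .as_readouts(readouts, net)
  n_post <- round((t_max - switch_times) / popcfg$step_dt)
  base <- .baseline_to_switch(net, cfg, popcfg, switch_times)
  untreated <- .continue_arm(net, popcfg, base, n_post)
  rows <- lapply(names(candidates), function(id) {
    treated <- .treated_arm(net, popcfg, base, candidates[[id]], n_post)
    tab <- .response_table(untreated, treated, readouts, eval_time)
    if (nrow(tab)) {
      cbind(candidate = id,
            perturbation = .describe_spec(candidates[[id]]), tab)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(candidate = character(0), perturbation = character(0),
                      node = character(0), measure = character(0),
                      untreated = numeric(0), treated = numeric(0),
                      response_pct = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Single-target inhibition candidates over druggable nodes
#'
#' Builds one clamp-to-`value` perturbation per druggable node (ligands,
#' receptors, transcription factors).  Since inhibiting a cytokine or its
#' receptor has near-identical effects, `collapse_receptors = TRUE` drops a
#' receptor whose rule is a bare copy of a single druggable ligand, keeping
#' only the ligand.
#'
#' @param net a `boolean_network`.
#' @param value clamp value (0 = inhibition, default; 1 = activation).
#' @param switch_time passed to [perturbation_spec()].
#' @param collapse_receptors drop single-ligand copy receptors.
#' @return named list of `perturbation_spec`.
#' @export
druggable_targets <- function(net, value = 0, switch_time = 300,
                              collapse_receptors = TRUE) {
  ann <- node_annotations(net)
  targets <- ann$node[ann$druggable]
  if (collapse_receptors) {
    drop <- vapply(targets, function(nm) {
      nd <- net$nodes[[nm]]
      if (nd$node_class != "receptor") return(FALSE)
      is.symbol(nd$logic) &&
        isTRUE(ann$druggable[ann$node == as.character(nd$logic)])
    }, logical(1))
    targets <- targets[!drop]
  }
  stats::setNames(lapply(targets, function(nm) {
    perturbation_spec(clamps = stats::setNames(value, nm),
                      switch_time = switch_time)
  }), targets)
}
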