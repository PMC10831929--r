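# Simulation and population configuration ----------------------------------

#' Monte-Carlo simulation configuration
#'
#' @param parameters named numeric vector binding the `$`-rate parameters.
#' @param init named vector of activation probabilities at t = 0 (independent
#'   marginals); nodes not listed start inactive.
#' @param n_trajectories ensemble size (default 50000).
#' @param t_max simulated horizon in hours.
#' @param window_dt reporting-window width in hours; must divide `t_max`.
#' @param seed master seed for the random stream.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(parameters = numeric(0), init = numeric(0),
                       n_trajectories = 50000, t_max = 100,
                       window_dt = 1, seed = 1L) {
  parameters <- unlist(parameters)
  init <- unlist(init)
  if (length(init) && (any(init < 0) || any(init > 1))) {
    stop("initial probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (length(parameters) && any(!is.finite(parameters) | parameters < 0)) {
    stop("rate parameters must be nonnegative and finite", call. = FALSE)
  }
  if (n_trajectories < 1) stop("n_trajectories must be >= 1", call. = FALSE)
  if (t_max <= 0 || window_dt <= 0) {
    stop("t_max and window_dt must be positive", call. = FALSE)
  }
  n_win <- t_max / window_dt
  if (abs(n_win - round(n_win)) > 1e-9) {
    stop("window_dt must divide t_max", call. = FALSE)
  }
  structure(
    list(parameters = parameters, init = init,
         n_trajectories = as.integer(n_trajectories), t_max = t_max,
         window_dt = window_dt, seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d parameters, %d trajectories, t_max %g h, window %g h, seed %d\n",
    length(x$parameters), x$n_trajectories, x$t_max, x$window_dt, x$seed))
  invisible(x)
}

# Update formulas: arithmetic over p(Node), pop_ratio and $parameters.
.parse_update_formula <- function(text) {
  text <- trimws(text)
  expr <- tryCatch(str2lang(gsub("$", "", text, fixed = TRUE)),
                   error = function(e) {
                     stop(sprintf("invalid update formula '%s'", text),
                          call. = FALSE)
                   })
  nodes <- character(0)
  walk <- function(e) {
    if (is.call(e)) {
      if (identical(e[[1L]], as.symbol("p"))) {
        if (length(e) != 2L) {
          stop(sprintf("p() takes one node name in '%s'", text), call. = FALSE)
        }
        nodes[[length(nodes) + 1L]] <<- as.character(e[[2L]])
      } else {
        if (!as.character(e[[1L]]) %in% c("+", "-", "*", "/", "(", "min", "max")) {
          stop(sprintf("disallowed function '%s' in update formula '%s'",
                       as.character(e[[1L]]), text), call. = FALSE)
        }
        for (a in as.list(e)[-1L]) walk(a)
      }
    }
  }
  walk(expr)
  list(text = text, expr = expr, nodes = unique(nodes))
}

#' Population-layer configuration
#'
#' Describes the synchronous population update: the step length, the number
#' of steps, how clashes between Division and Death are resolved, and the
#' rate parameters recomputed from end-of-step node marginals (the
#' cell-communication mechanism, e.g. receptor activation driven by ligand
#' probability).
#'
#' @param step_dt duration of one population step in hours (> 0).
#' @param n_steps number of synchronous steps.
#' @param update_rules named character vector: parameter name -> formula over
#'   `p(Node)` terms, `pop_ratio` and `$`-parameters, e.g.
#'   `c(ku_IL10R = "2 * p(IL10)")`.
#' @param death_precedence if `TRUE` (default) a state with both Division and
#'   Death active dies.
#' @return object of class `pop_config`.
#' @export
pop_config <- function(step_dt = 1, n_steps = 100, update_rules = character(0),
                       death_precedence = TRUE) {
  if (step_dt <= 0) stop("step_dt must be > 0", call. = FALSE)
  if (n_steps < 1) stop("n_steps must be >= 1", call. = FALSE)
  rules <- lapply(seq_along(update_rules), function(i) {
    f <- .parse_update_formula(update_rules[[i]])
    f$param <- names(update_rules)[i]
    f
  })
  if (length(rules) && any(!nzchar(vapply(rules, `[[`, character(1), "param")))) {
    stop("every update rule must be named after the parameter it sets",
         call. = FALSE)
  }
  structure(
    list(step_dt = step_dt, n_steps = as.integer(n_steps),
         update_rules = rules, death_precedence = isTRUE(death_precedence)),
    class = "pop_config")
}

#' @export
print.pop_config <- function(x, ...) {
  cat(sprintf("pop_config: %d steps of %g h, %d update rule(s), death %s division\n",
              x$n_steps, x$step_dt, length(x$update_rules),
              if (x$death_precedence) "overrides" else "yields to"))
  invisible(x)
}

# Validate a pop_config against a network: update formulas may only reference
# declared nodes, and updated parameters must exist in the rate symbols.
.validate_popcfg <- function(popcfg, net, parameters) {
  for (r in popcfg$update_rules) {
    unknown <- setdiff(r$nodes, node_names(net))
    if (length(unknown)) {
      stop(sprintf("update formula for '%s' references unknown node(s): %s",
                   r$param, paste(unknown, collapse = ", ")), call. = FALSE)
    }
    if (!r$param %in% names(parameters)) {
      stop(sprintf("update rule targets unknown parameter '%s'", r$param),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}
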