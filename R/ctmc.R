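# Continuous-time Markov chain engine ---------------------------------------
#
# MaBoSS semantics: a node whose rule value disagrees with its current state
# is enabled to flip, at its activation rate (state 0 -> 1) or inactivation
# rate (1 -> 0).  The waiting time to the next flip is exponential with the
# sum of enabled rates; the flipped node is drawn proportionally to rate
# (Gillespie).  A state with no enabled transition is absorbing.
#
# Two code paths share these semantics: a scalar per-trajectory simulator
# returning explicit jump sequences, and a vectorised ensemble kernel that
# advances all trajectories of a reporting window together and accumulates
# state-occupancy time (used by the windowed-marginal and population layers).

.compile_model <- function(net, params) {
  nn <- node_names(net)
  ku <- vapply(net$nodes, function(nd) eval_rate(nd$rate_up, params), numeric(1))
  kd <- vapply(net$nodes, function(nd) eval_rate(nd$rate_down, params), numeric(1))
  clamp <- rep(NA_real_, length(nn))
  names(clamp) <- nn
  if (length(net$clamped)) clamp[names(net$clamped)] <- net$clamped
  list(nodes = nn, ku = unname(ku), kd = unname(kd), clamp = unname(clamp),
       exprs = unname(lapply(net$nodes, `[[`, "logic")))
}

# Rule values for a batch of states (rows).  Clamped nodes never move.
.rule_targets <- function(cm, states) {
  n <- nrow(states)
  env <- list2env(stats::setNames(
    lapply(seq_along(cm$nodes), function(j) states[, j]), cm$nodes),
    parent = baseenv())
  tgt <- states
  for (j in seq_along(cm$exprs)) {
    if (!is.na(cm$clamp[j])) next
    tgt[, j] <- rep_len(as.logical(eval(cm$exprs[[j]], envir = env)), n)
  }
  tgt
}

# Advance every trajectory (row of `states`) from time 0 to t_end; returns
# end states and the per-trajectory, per-node time spent in state 1.
.simulate_window <- function(cm, states, t_end) {
  n <- nrow(states)
  m <- ncol(states)
  occ <- matrix(0, n, m)
  tnow <- numeric(n)
  alive <- rep(TRUE, n)
  while (any(alive)) {
    idx <- which(alive)
    st <- states[idx, , drop = FALSE]
    tgt <- .rule_targets(cm, st)
    en <- tgt != st
    kumat <- matrix(cm$ku, length(idx), m, byrow = TRUE)
    kdmat <- matrix(cm$kd, length(idx), m, byrow = TRUE)
    rmat <- en * (st * kdmat + (!st) * kumat)
    total <- rowSums(rmat)
    absorbing <- total <= 0
    if (any(absorbing)) {
      ia <- idx[absorbing]
      occ[ia, ] <- occ[ia, ] + (t_end - tnow[ia]) * st[absorbing, , drop = FALSE]
      tnow[ia] <- t_end
      alive[ia] <- FALSE
    }
    if (all(absorbing)) next
    act <- which(!absorbing)
    ii <- idx[act]
    tot <- total[act]
    dt <- stats::rexp(length(ii)) / tot
    tnew <- tnow[ii] + dt
    occ[ii, ] <- occ[ii, ] +
      (pmin(tnew, t_end) - tnow[ii]) * st[act, , drop = FALSE]
    crossed <- tnew >= t_end
    if (any(crossed)) {
      ic <- ii[crossed]
      tnow[ic] <- t_end
      alive[ic] <- FALSE
    }
    flip <- !crossed
    if (any(flip)) {
      jf <- ii[flip]
      rsub <- rmat[act, , drop = FALSE][flip, , drop = FALSE]
      u <- stats::runif(length(jf)) * tot[flip]
      pick <- integer(length(jf))
      acc <- numeric(length(jf))
      for (j in seq_len(m)) {
        acc <- acc + rsub[, j]
        hit <- pick == 0L & u <= acc
        pick[hit] <- j
      }
      pick[pick == 0L] <- m  # guard against floating-point undershoot
      lin <- cbind(jf, pick)
      states[lin] <- !states[lin]
      tnow[jf] <- tnew[flip]
    }
  }
  list(states = states, occ = occ)
}

# Initial ensemble: independent Bernoulli marginals from cfg$init (0 for
# unlisted nodes); clamped nodes start at their clamp value.
.sample_init_states <- function(net, cfg, n) {
  nn <- node_names(net)
  p <- stats::setNames(rep(0, length(nn)), nn)
  p[names(cfg$init)] <- cfg$init
  if (length(net$clamped)) p[names(net$clamped)] <- net$clamped
  matrix(stats::runif(n * length(nn)) < rep(p, each = n), n, length(nn),
         dimnames = list(NULL, nn))
}

#' Transitions enabled in a state
#'
#' @param state named 0/1 (or logical) vector over all nodes.
#' @param net a `boolean_network` (clamped nodes are never enabled).
#' @param params named numeric vector binding the rate parameters.
#' @return data.frame with columns `node` and `rate`: the nodes whose rule
#'   value differs from their state, with the activation rate when the state
#'   is 0 and the inactivation rate when it is 1.
#' @export
enabled_transitions <- function(state, net, params = numeric(0)) {
  cm <- .compile_model(net, params)
  st <- matrix(as.logical(state[cm$nodes]), 1L,
               dimnames = list(NULL, cm$nodes))
  tgt <- .rule_targets(cm, st)
  en <- which(tgt[1L, ] != st[1L, ])
  data.frame(node = cm$nodes[en],
             rate = ifelse(st[1L, en], cm$kd[en], cm$ku[en]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate one Gillespie trajectory
#'
#' @param net a `boolean_network`.
#' @param params named numeric vector of rate-parameter values.
#' @param init named 0/1 vector, the state at t = 0.
#' @param t_max end of the simulated horizon (hours).
#' @param seed optional seed for this trajectory's stream.
#' @return object of class `ctmc_trajectory`: the initial state, the jump
#'   times, the node flipped at each jump, and `t_max`.
#' @export
simulate_trajectory <- function(net, params, init, t_max, seed = NULL) {
  stopifnot(t_max > 0)
  if (!is.null(seed)) set.seed(seed)
  cm <- .compile_model(net, params)
  state <- as.logical(init[cm$nodes])
  if (length(net$clamped)) {
    state[match(names(net$clamped), cm$nodes)] <- net$clamped > 0
  }
  tnow <- 0
  times <- numeric(0)
  flips <- character(0)
  st <- matrix(state, 1L, dimnames = list(NULL, cm$nodes))
  repeat {
    tgt <- .rule_targets(cm, st)
    en <- which(tgt[1L, ] != st[1L, ])
    rates <- ifelse(st[1L, en], cm$kd[en], cm$ku[en])
    total <- sum(rates)
    if (total <= 0) break  # absorbing
    tnow <- tnow + stats::rexp(1L, total)
    if (tnow >= t_max) break
    j <- en[.categorical1(rates)]
    st[1L, j] <- !st[1L, j]
    times <- c(times, tnow)
    flips <- c(flips, cm$nodes[j])
  }
  structure(list(init = stats::setNames(as.integer(state), cm$nodes),
                 times = times, flips = flips, t_max = t_max,
                 nodes = cm$nodes),
            class = "ctmc_trajectory")
}

.categorical1 <- function(w) {
  u <- stats::runif(1L) * sum(w)
  j <- findInterval(u, cumsum(w), left.open = TRUE) + 1L
  min(j, length(w))
}

#' Simulate an ensemble of trajectories
#'
#' Each trajectory runs on its own stream whose seed is derived from the
#' master seed, so any single trajectory can be reproduced in isolation.
#'
#' @inheritParams simulate_trajectory
#' @param n ensemble size.
#' @param seed master seed.
#' @return list of `ctmc_trajectory`.
#' @export
simulate_trajectories <- function(net, params, init, t_max, n, seed = 1L) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n)
  lapply(seeds, function(s) simulate_trajectory(net, params, init, t_max,
                                                seed = s))
}

#' Windowed marginals from explicit trajectories
#'
#' The probability of a node in a window is the ensemble- and time-averaged
#' occupancy of state 1 within that window; trajectory weights (for
#' population reweighting) are supported.
#'
#' @param trajectories non-empty list of `ctmc_trajectory` with a common
#'   `t_max`.
#' @param window_dt window width; must divide `t_max`.
#' @param weights optional nonnegative trajectory weights (default equal).
#' @return a `marginal_timecourse`.
#' @export
estimate_marginals <- function(trajectories, window_dt, weights = NULL) {
  if (length(trajectories) == 0L) stop("empty ensemble", call. = FALSE)
  t_max <- trajectories[[1L]]$t_max
  if (!all(vapply(trajectories, `[[`, numeric(1), "t_max") == t_max)) {
    stop("trajectories must share t_max", call. = FALSE)
  }
  n_win <- round(t_max / window_dt)
  if (abs(t_max / window_dt - n_win) > 1e-9) {
    stop("window_dt must divide t_max", call. = FALSE)
  }
  nodes <- trajectories[[1L]]$nodes
  if (is.null(weights)) weights <- rep(1, length(trajectories))
  weights <- weights / sum(weights)
  occ <- matrix(0, n_win, length(nodes), dimnames = list(NULL, nodes))
  bounds <- seq(0, t_max, by = window_dt)
  for (k in seq_along(trajectories)) {
    tr <- trajectories[[k]]
    seg_start <- c(0, tr$times)
    seg_end <- c(tr$times, t_max)
    state <- as.logical(tr$init)
    for (s in seq_along(seg_start)) {
      if (s > 1L) {
        j <- match(tr$flips[s - 1L], nodes)
        state[j] <- !state[j]
      }
      if (!any(state)) next
      w0 <- findInterval(seg_start[s], bounds, left.open = FALSE,
                         rightmost.closed = TRUE)
      w1 <- findInterval(seg_end[s], bounds, left.open = TRUE,
                         rightmost.closed = TRUE)
      for (w in w0:w1) {
        ov <- min(seg_end[s], bounds[w + 1L]) - max(seg_start[s], bounds[w])
        if (ov > 0) occ[w, state] <- occ[w, state] + ov * weights[k]
      }
    }
  }
  marginal_timecourse(occ / window_dt, window_dt,
                      n_trajectories = length(trajectories))
}

#' Windowed marginal timecourse container
#'
#' @param prob windows-by-nodes matrix of activation probabilities.
#' @param window_dt window width in hours.
#' @param n_trajectories ensemble size behind the estimate.
#' @return object of class `marginal_timecourse`.
#' @export
marginal_timecourse <- function(prob, window_dt, n_trajectories = NA_integer_) {
  stopifnot(is.matrix(prob))
  if (any(prob < -1e-9 | prob > 1 + 1e-9)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  prob <- pmin(pmax(prob, 0), 1)
  structure(list(prob = prob, window_dt = window_dt,
                 window_start = (seq_len(nrow(prob)) - 1L) * window_dt,
                 n_trajectories = n_trajectories),
            class = "marginal_timecourse")
}

#' @export
print.marginal_timecourse <- function(x, ...) {
  cat(sprintf(
    "marginal_timecourse: %d windows of %g h, %d nodes, %s trajectories\n",
    nrow(x$prob), x$window_dt, ncol(x$prob),
    format(x$n_trajectories)))
  invisible(x)
}

#' @export
as.data.frame.marginal_timecourse <- function(x, ...) {
  data.frame(
    window_start = rep(x$window_start, ncol(x$prob)),
    node = rep(colnames(x$prob), each = nrow(x$prob)),
    probability = as.vector(x$prob),
    stringsAsFactors = FALSE)
}

#' Write a timecourse as long-format TSV or JSON
#'
#' @param x a `marginal_timecourse` or `pop_timecourse`.
#' @param path output file; format chosen from the extension (`.json` vs TSV).
#' @export
write_timecourse <- function(x, path) {
  df <- as.data.frame(x)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, digits = NA)
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Monte-Carlo windowed marginals for a whole configuration
#'
#' Runs the vectorised ensemble kernel window by window from the configured
#' initial distribution.  At window boundaries the exponential waiting time
#' is redrawn, which by memorylessness leaves the law of the process
#' unchanged.
#'
#' @param net a `boolean_network`.
#' @param cfg a [sim_config()].
#' @return a `marginal_timecourse`.
#' @export
run_ctmc <- function(net, cfg) {
  set.seed(cfg$seed)
  cm <- .compile_model(net, cfg$parameters)
  states <- .sample_init_states(net, cfg, cfg$n_trajectories)
  weights <- rep(1 / nrow(states), nrow(states))
  n_win <- round(cfg$t_max / cfg$window_dt)
  P <- matrix(0, n_win, length(cm$nodes), dimnames = list(NULL, cm$nodes))
  for (w in seq_len(n_win)) {
    res <- .simulate_window(cm, states, cfg$window_dt)
    states <- res$states
    P[w, ] <- colSums(res$occ * weights) / cfg$window_dt
  }
  marginal_timecourse(P, cfg$window_dt, cfg$n_trajectories)
}
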