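# Exact master equation for small networks ----------------------------------
#
# For networks of up to ~12 nodes the full state space (2^m Boolean states)
# is enumerated and the Kolmogorov forward equations are integrated
# numerically.  This is the exact counterpart of the Monte-Carlo engine and
# serves as its oracle in validation.

.enumerate_states <- function(m) {
  n_states <- 2L^m
  st <- matrix(FALSE, n_states, m)
  for (j in seq_len(m)) {
    st[, j] <- bitwAnd(seq_len(n_states) - 1L, bitwShiftL(1L, j - 1L)) > 0L
  }
  st
}

# Precompute, for every joint state, the enabled flip rates and the index of
# the destination state after each flip.
.me_generator <- function(net, params) {
  cm <- .compile_model(net, params)
  m <- length(cm$nodes)
  if (m > 14L) stop("master equation limited to <= 14 nodes", call. = FALSE)
  st <- .enumerate_states(m)
  colnames(st) <- cm$nodes
  tgt <- .rule_targets(cm, st)
  en <- tgt != st
  kumat <- matrix(cm$ku, nrow(st), m, byrow = TRUE)
  kdmat <- matrix(cm$kd, nrow(st), m, byrow = TRUE)
  rmat <- en * (st * kdmat + (!st) * kumat)
  dest <- matrix(0L, nrow(st), m)
  for (j in seq_len(m)) {
    dest[, j] <- seq_len(nrow(st)) + ifelse(st[, j], -1L, 1L) * bitwShiftL(1L, j - 1L)
  }
  list(states = st, rmat = rmat, dest = dest, nodes = cm$nodes,
       clamp = cm$clamp)
}

# Product initial distribution from independent marginals.
.me_init <- function(gen, init) {
  m <- ncol(gen$states)
  p <- stats::setNames(rep(0, m), gen$nodes)
  p[names(init)] <- init
  if (any(!is.na(gen$clamp))) {
    p[!is.na(gen$clamp)] <- gen$clamp[!is.na(gen$clamp)]
  }
  pr <- rep(1, nrow(gen$states))
  for (j in seq_len(m)) {
    pr <- pr * ifelse(gen$states[, j], p[j], 1 - p[j])
  }
  pr
}

#' Exact node marginals by master-equation integration
#'
#' Numerically integrates the forward equations of the continuous-time
#' Markov chain over all joint Boolean states (feasible for small networks)
#' and returns the instantaneous marginal P(node = 1) at the requested
#' times.  Clamped nodes are held fixed.
#'
#' @param net a `boolean_network` with at most 14 nodes.
#' @param params named numeric rate-parameter values.
#' @param init named initial activation probabilities (independent
#'   marginals; unlisted nodes start at 0).
#' @param times numeric vector of time points (must include increasing
#'   values starting at or after 0).
#' @return matrix `length(times)` x nodes of marginals, with the times as
#'   a `times` attribute.
#' @export
master_equation_marginals <- function(net, params, init, times) {
  gen <- .me_generator(net, params)
  y0 <- .me_init(gen, init)
  rmat <- gen$rmat
  dest <- gen$dest
  m <- ncol(gen$states)
  deriv <- function(t, y, parms) {
    dy <- -rowSums(rmat) * y
    for (j in seq_len(m)) {
      flux <- rmat[, j] * y
      nz <- flux != 0
      if (any(nz)) {
        dy[dest[nz, j]] <- dy[dest[nz, j]] + flux[nz]
      }
    }
    list(dy)
  }
  tt <- sort(unique(c(0, times)))
  sol <- deSolve::ode(y = y0, times = tt, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  P <- sol[match(times, tt), -1L, drop = FALSE]
  out <- P %*% (gen$states * 1)
  colnames(out) <- gen$nodes
  attr(out, "times") <- times
  out
}

#' Exact window-averaged marginals
#'
#' Time-averages the master-equation solution within each reporting window
#' (trapezoid rule on a fine grid), matching what the Monte-Carlo engine
#' estimates.
#'
#' @inheritParams master_equation_marginals
#' @param t_max horizon; `window_dt` must divide it.
#' @param window_dt window width.
#' @param n_grid sub-grid points per window for the quadrature.
#' @return a `marginal_timecourse` (exact, `n_trajectories = NA`).
#' @export
master_equation_windows <- function(net, params, init, t_max, window_dt,
                                    n_grid = 20L) {
  n_win <- round(t_max / window_dt)
  grid <- seq(0, t_max, length.out = n_win * n_grid + 1L)
  M <- master_equation_marginals(net, params, init, grid)
  P <- matrix(0, n_win, ncol(M), dimnames = list(NULL, colnames(M)))
  for (w in seq_len(n_win)) {
    idx <- ((w - 1L) * n_grid + 1L):(w * n_grid + 1L)
    # trapezoid weights
    wt <- c(0.5, rep(1, n_grid - 1L), 0.5) / n_grid
    P[w, ] <- colSums(M[idx, , drop = FALSE] * wt)
  }
  marginal_timecourse(P, window_dt)
}
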