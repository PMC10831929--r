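# Feedback vertex sets and propagation ranking -------------------------------
#
# A feedback vertex set (FVS) intersects every directed cycle; removing it
# leaves the influence graph acyclic, and controlling it can steer the
# network's long-term dynamics.  Candidate two-node FVSs are enumerated over
# the cycle-participating nodes, filtered for druggability, and ranked by
# three propagation metrics — PRINCE smoothing on the undirected graph,
# a directed signed variant ("modified PRINCE"), and CheiRank (PageRank on
# the edge-reversed graph) — combined by top-fraction intersection.

#' Nodes on at least one directed cycle
#'
#' Members of nontrivial strongly connected components, plus self-loop
#' nodes.
#'
#' @param g an igraph (directed).
#' @return sorted character vector of node names.
#' @export
cycle_nodes <- function(g) {
  comp <- igraph::components(g, mode = "strong")
  in_scc <- comp$membership %in% which(comp$csize > 1L)
  loops <- igraph::which_loop(g)
  self <- unique(igraph::as_edgelist(g)[loops, 1L])
  sort(unique(c(igraph::V(g)$name[in_scc], self)))
}

#' Is a node set a feedback vertex set?
#'
#' @param g an igraph.
#' @param node_set character vector of node names (subset of `V(g)`).
#' @return `TRUE` iff `g` minus `node_set` contains no directed cycle.
#' @export
is_fvs <- function(g, node_set) {
  stopifnot(all(node_set %in% igraph::V(g)$name))
  h <- igraph::delete_vertices(g, node_set)
  if (any(igraph::which_loop(h))) return(FALSE)
  igraph::is_dag(h)
}

#' Singleton feedback vertex sets
#'
#' @param g an igraph.
#' @return character vector of single nodes whose removal makes `g` acyclic.
#' @export
fvs_singletons <- function(g) {
  cyc <- cycle_nodes(g)
  cyc[vapply(cyc, function(v) is_fvs(g, v), logical(1))]
}

#' Enumerate all two-node feedback vertex sets
#'
#' All unordered pairs of cycle-participating nodes whose joint removal
#' leaves the graph acyclic, in lexicographic order.
#'
#' @param g an igraph.
#' @return data.frame with columns `node1` < `node2`.
#' @export
enumerate_fvs_pairs <- function(g) {
  cyc <- cycle_nodes(g)
  empty <- data.frame(node1 = character(0), node2 = character(0),
                      stringsAsFactors = FALSE)
  if (length(cyc) < 2L) return(empty)
  pairs <- utils::combn(cyc, 2L)
  keep <- apply(pairs, 2L, function(p) is_fvs(g, p))
  if (!any(keep)) return(empty)
  out <- data.frame(node1 = pairs[1L, keep], node2 = pairs[2L, keep],
                    stringsAsFactors = FALSE)
  out[order(out$node1, out$node2), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Filter candidate pairs for druggability
#'
#' Keeps pairs whose both members are druggable; the `counts` attribute
#' reports both counting conventions (pairs containing at least one
#' non-druggable member, and pairs with both members druggable) for audit.
#'
#' @param pairs data.frame from [enumerate_fvs_pairs()].
#' @param annotations named logical vector (node -> druggable) or a
#'   data.frame with columns `node` and `druggable`.
#' @return filtered pairs; attribute `counts` holds `n_total`,
#'   `n_with_nondruggable`, `n_both_druggable`.
#' @export
filter_druggable <- function(pairs, annotations) {
  if (is.data.frame(annotations)) {
    annotations <- stats::setNames(as.logical(annotations$druggable),
                                   annotations$node)
  }
  members <- unique(c(pairs$node1, pairs$node2))
  missing <- setdiff(members, names(annotations))
  if (length(missing)) {
    stop(sprintf("unannotated node(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  both <- annotations[pairs$node1] & annotations[pairs$node2]
  out <- pairs[both, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- c(n_total = nrow(pairs),
                           n_with_nondruggable = sum(!both),
                           n_both_druggable = sum(both))
  out
}

# Undirected, unsigned, degree-symmetric-normalised adjacency.
.prince_W <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(
    igraph::as_undirected(g, mode = "collapse"), sparse = FALSE))
  A[A > 0] <- 1
  diag(A)[diag(A) > 0] <- 1
  d <- rowSums(A)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  A * outer(dinv, dinv)
}

.prince_iterate <- function(W, Y, alpha, tol, max_iter) {
  f <- Y
  for (i in seq_len(max_iter)) {
    f_new <- alpha * (W %*% f) + (1 - alpha) * Y
    if (max(abs(f_new - f)) < tol) {
      return(stats::setNames(as.vector(f_new), rownames(W)))
    }
    f <- f_new
  }
  stop("propagation did not converge", call. = FALSE)
}

#' PRINCE network propagation scores
#'
#' Iterates `F <- alpha * W' * F + (1 - alpha) * Y` to its fixed point,
#' where `W'` is the symmetric degree-normalised adjacency of the
#' underlying undirected graph and `Y` the indicator of the seed set.
#'
#' @param g an igraph.
#' @param seeds character vector of seed node names.
#' @param alpha restart/smoothing parameter in (0, 1), default 0.85.
#' @param tol convergence tolerance on the max absolute update (1e-9).
#' @param max_iter iteration cap.
#' @return named numeric vector of nonnegative scores.
#' @export
prince_scores <- function(g, seeds, alpha = 0.85, tol = 1e-9,
                          max_iter = 100000L) {
  stopifnot(alpha > 0, alpha < 1, all(seeds %in% igraph::V(g)$name))
  W <- .prince_W(g)
  Y <- stats::setNames(as.numeric(igraph::V(g)$name %in% seeds),
                       igraph::V(g)$name)
  .prince_iterate(W, Y, alpha, tol, max_iter)
}

# Directed, out-degree-normalised, sign-weighted propagation matrix: entry
# (v, u) carries mass from u to v along a u->v edge.
.modified_prince_W <- function(g) {
  el <- igraph::as_edgelist(g)
  nn <- igraph::V(g)$name
  sign <- igraph::edge_attr(g, "sign")
  if (is.null(sign)) sign <- rep(1, nrow(el))
  A <- matrix(0, length(nn), length(nn), dimnames = list(nn, nn))
  for (k in seq_len(nrow(el))) {
    A[el[k, 1L], el[k, 2L]] <- A[el[k, 1L], el[k, 2L]] + sign[k]
  }
  outdeg <- rowSums(abs(A))
  Anorm <- A / ifelse(outdeg > 0, outdeg, 1)
  t(Anorm)
}

#' Directed, sign-aware propagation scores ("modified PRINCE")
#'
#' Same fixed-point iteration as [prince_scores()] but on the directed
#' graph: mass flows along edge direction, rows are out-degree normalised,
#' and edge signs are carried as weights, so scores can be negative;
#' rankings aggregate absolute values.
#'
#' @inheritParams prince_scores
#' @return named numeric vector of scores (signed).
#' @export
modified_prince_scores <- function(g, seeds, alpha = 0.85, tol = 1e-9,
                                   max_iter = 100000L) {
  stopifnot(alpha > 0, alpha < 1, all(seeds %in% igraph::V(g)$name))
  W <- .modified_prince_W(g)
  Y <- stats::setNames(as.numeric(igraph::V(g)$name %in% seeds),
                       igraph::V(g)$name)
  .prince_iterate(W, Y, alpha, tol, max_iter)
}

#' CheiRank scores
#'
#' PageRank computed on the edge-reversed graph: nodes are scored by their
#' outgoing influence rather than incoming support.  Scores sum to 1.
#'
#' @param g an igraph.
#' @param damping PageRank damping factor (default 0.85).
#' @return named numeric vector summing to 1.
#' @export
cheirank_scores <- function(g, damping = 0.85) {
  stopifnot(damping > 0, damping < 1)
  pr <- igraph::page_rank(igraph::reverse_edges(g), damping = damping,
                          weights = NA)
  stats::setNames(pr$vector, igraph::V(g)$name)
}

#' Rank candidate FVS pairs by propagation-metric intersection
#'
#' For each pair the two PRINCE variants are seeded at the pair and their
#' scores summed over all nodes (total influence; absolute values for the
#' signed variant), and the two nodes' CheiRank values are summed.  Pairs
#' get a dense rank per metric (1 = best).  Pairs in the top fraction of
#' all three metrics form the intersection and are ordered first by mean
#' rank; the rest follow, also by mean rank; ties break lexicographically.
#'
#' @param g an igraph.
#' @param pairs data.frame from [enumerate_fvs_pairs()] (or a filtered
#'   subset).
#' @param alpha PRINCE smoothing parameter.
#' @param damping CheiRank damping factor.
#' @param top_fraction fraction of pairs that counts as "top" per metric for
#'   the intersection (default 0.2).
#' @return object of class `fvs_ranking`: the pair table with per-metric
#'   scores and ranks, `in_intersection`, and `final_rank`.
#' @export
rank_pairs <- function(g, pairs, alpha = 0.85, damping = 0.85,
                       top_fraction = 0.2) {
  if (nrow(pairs) == 0L) stop("no candidate pairs", call. = FALSE)
  cr <- cheirank_scores(g, damping)
  score_one <- function(n1, n2) {
    c(prince = sum(prince_scores(g, c(n1, n2), alpha)),
      modified_prince = sum(abs(modified_prince_scores(g, c(n1, n2), alpha))),
      cheirank = cr[[n1]] + cr[[n2]])
  }
  sc <- t(mapply(score_one, pairs$node1, pairs$node2))
  out <- cbind(pairs, as.data.frame(sc))
  dense_rank_desc <- function(x) match(x, sort(unique(x), decreasing = TRUE))
  out$rank_prince <- dense_rank_desc(out$prince)
  out$rank_modified_prince <- dense_rank_desc(out$modified_prince)
  out$rank_cheirank <- dense_rank_desc(out$cheirank)
  cutoff <- ceiling(top_fraction * nrow(out))
  top_by <- function(r) r <= cutoff
  out$in_intersection <- top_by(out$rank_prince) &
    top_by(out$rank_modified_prince) & top_by(out$rank_cheirank)
  out$mean_rank <- rowMeans(out[, c("rank_prince", "rank_modified_prince",
                                    "rank_cheirank")])
  ord <- order(!out$in_intersection, out$mean_rank, out$node1, out$node2)
  out <- out[ord, , drop = FALSE]
  out$final_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("fvs_ranking", "data.frame"),
            alpha = alpha, damping = damping, top_fraction = top_fraction)
}

#' @export
print.fvs_ranking <- function(x, n = 10L, ...) {
  cat(sprintf(
    "fvs_ranking: %d pairs (%d in the 3-metric intersection at top %g%%)\n",
    nrow(x), sum(x$in_intersection), 100 * attr(x, "top_fraction")))
  print.data.frame(utils::head(x, n), digits = 4)
  invisible(x)
}

#' Write an FVS ranking as TSV
#' @param ranking an `fvs_ranking`.
#' @param path output file.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(as.data.frame(ranking), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
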