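# Shared fixtures and independent oracles, built in code.

# Two-node chain A -> B: A is constant-true, B copies A.
two_node_chain <- function(ku_A = 1, kd_A = 0.5, ku_B = 2, kd_B = 1) {
  boolean_network(list(
    node_decl("A", "1", rate_up = ku_A, rate_down = kd_A),
    node_decl("B", "A", rate_up = ku_B, rate_down = kd_B)))
}

# Three-node negative-feedback toy used against the master equation.
three_node_net <- function() {
  boolean_network(list(
    node_decl("A", "1", rate_up = "$ku", rate_down = 0.5),
    node_decl("B", "A AND NOT C", rate_up = 1, rate_down = 1),
    node_decl("C", "B", rate_up = 1, rate_down = 1)))
}

# Independent acyclicity oracle: Kahn's algorithm on an edge list, no igraph.
kahn_acyclic <- function(edges, nodes) {
  if (nrow(edges) == 0L) return(TRUE)
  if (any(edges$from == edges$to)) return(FALSE)
  indeg <- stats::setNames(rep(0L, length(nodes)), nodes)
  tab <- table(edges$to)
  indeg[names(tab)] <- as.integer(tab)
  adj <- split(edges$to, factor(edges$from, levels = nodes))
  queue <- nodes[indeg == 0L]
  removed <- 0L
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    removed <- removed + 1L
    for (w in adj[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  removed == length(nodes)
}

graph_edges <- function(g) {
  el <- igraph::as_edgelist(g)
  data.frame(from = el[, 1L], to = el[, 2L], stringsAsFactors = FALSE)
}

# Exhaustive two-node-FVS oracle: boolean transitive closure for cycle
# membership, then Kahn on every candidate pair's reduced graph.
oracle_fvs_pairs <- function(g) {
  nodes <- igraph::V(g)$name
  edges <- graph_edges(g)
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  A[cbind(edges$from, edges$to)] <- TRUE
  R <- A
  for (i in seq_len(n)) R <- R | ((R %*% A) > 0)
  on_cycle <- nodes[diag(R)]
  if (length(on_cycle) < 2L) {
    return(data.frame(node1 = character(0), node2 = character(0)))
  }
  pairs <- utils::combn(sort(on_cycle), 2L)
  keep <- apply(pairs, 2L, function(p) {
    sub <- edges[!(edges$from %in% p | edges$to %in% p), , drop = FALSE]
    kahn_acyclic(sub, setdiff(nodes, p))
  })
  data.frame(node1 = pairs[1L, keep], node2 = pairs[2L, keep],
             stringsAsFactors = FALSE)
}
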