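# Signed influence graph ----------------------------------------------------

#' Derive the signed influence graph of a network
#'
#' One directed edge per distinct (regulator, target, sign) triple across all
#' rules.  Sign is syntactic: a regulator under an even number of `NOT`s is
#' activating (+1), under an odd number inhibiting (-1); a regulator occurring
#' with both parities in one rule contributes two edges of opposite sign.
#'
#' @param net a `boolean_network`.
#' @param include_utility keep the Division/Death/Trigger and
#'   `utility`-class nodes (default `TRUE`); set `FALSE` for network-control
#'   analyses, where these are artefacts of the population layer rather than
#'   disease circuitry.
#' @return an [igraph::graph] with vertex attributes `node_class` and
#'   `druggable` and edge attribute `sign`.
#' @export
influence_graph <- function(net, include_utility = TRUE) {
  edges <- do.call(rbind, lapply(net$nodes, function(nd) {
    s <- logic_signs(nd$logic)
    if (nrow(s) == 0L) return(NULL)
    data.frame(from = s$regulator, to = nd$name, sign = s$sign,
               stringsAsFactors = FALSE)
  }))
  ann <- node_annotations(net)
  g <- igraph::graph_from_data_frame(
    if (is.null(edges)) data.frame(from = character(0), to = character(0),
                                   sign = integer(0)) else edges,
    directed = TRUE, vertices = ann)
  if (!include_utility) {
    drop <- unique(c(net$division_node, net$death_node, net$trigger_node,
                     ann$node[ann$node_class == "utility"]))
    g <- igraph::delete_vertices(g, intersect(drop, igraph::V(g)$name))
  }
  g
}

#' Write a signed graph as SIF
#'
#' Tab-separated `source relation target`, with relation `activates` /
#' `inhibits` from the `sign` edge attribute (`interacts` when absent).
#'
#' @param g an igraph.
#' @param path output file.
#' @export
write_sif <- function(g, path) {
  el <- igraph::as_edgelist(g)
  sign <- igraph::edge_attr(g, "sign")
  rel <- if (is.null(sign)) {
    rep("interacts", nrow(el))
  } else ifelse(sign >= 0, "activates", "inhibits")
  lines <- if (nrow(el)) paste(el[, 1L], rel, el[, 2L], sep = "\t") else character(0)
  writeLines(lines, path)
  # isolated vertices: SIF convention, name on its own line
  iso <- igraph::V(g)$name[igraph::degree(g) == 0]
  if (length(iso)) cat(iso, file = path, sep = "\n", append = TRUE)
  invisible(path)
}

#' Read a SIF file into a signed digraph
#'
#' @param path SIF file (`source relation target`, tab- or space-separated).
#' @return igraph with edge attribute `sign` (+1 unless the relation contains
#'   "inhibit" or is "-1").
#' @export
read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[\t ]+")
  triples <- Filter(function(p) length(p) >= 3L, parts)
  singles <- unlist(lapply(Filter(function(p) length(p) == 1L, parts), `[[`, 1L))
  edges <- if (length(triples)) {
    data.frame(
      from = vapply(triples, `[[`, character(1), 1L),
      to = vapply(triples, `[[`, character(1), 3L),
      sign = ifelse(grepl("inhibit|^-1$",
                          vapply(triples, `[[`, character(1), 2L),
                          ignore.case = TRUE), -1L, 1L),
      stringsAsFactors = FALSE)
  } else data.frame(from = character(0), to = character(0), sign = integer(0))
  verts <- unique(c(edges$from, edges$to, singles))
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = verts)
}

#' Write a signed graph as GraphML
#' @param g an igraph.
#' @param path output file.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
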