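# BooleanNetwork container -------------------------------------------------

.NODE_CLASSES <- c("cell", "cell_state", "ligand", "receptor",
                   "transcription_factor", "signaling", "utility")
.DRUGGABLE_CLASSES <- c("ligand", "receptor", "transcription_factor")

#' Declare a network node
#'
#' A node carries a Boolean update rule, an activation rate (used when the
#' rule says 1 but the state is 0), an inactivation rate (the converse), and
#' a class annotation.  Druggability is not free: per the field convention
#' used here, a node is druggable iff it is a ligand, a receptor or a
#' transcription factor, never a cell-type or cell-state node.
#'
#' @param name identifier (letters, digits, underscore; must not start with a
#'   digit).
#' @param logic rule text over node names, e.g. `"Prol_KC AND STAT3"`.
#' @param rate_up,rate_down numeric constant or rate text such as `"$ku_X"`.
#' @param node_class one of `r paste0('"', .NODE_CLASSES, '"', collapse = ", ")`.
#' @return object of class `node_decl`.
#' @export
node_decl <- function(name, logic, rate_up = 1, rate_down = 1,
                      node_class = "signaling") {
  stopifnot(is.character(name), length(name) == 1L)
  if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", name)) {
    stop(sprintf("invalid node name '%s'", name), call. = FALSE)
  }
  node_class <- match.arg(node_class, .NODE_CLASSES)
  expr <- if (is.character(logic)) parse_logic(logic) else logic
  ru <- if (is.character(rate_up)) parse_rate(rate_up) else rate_up
  rd <- if (is.character(rate_down)) parse_rate(rate_down) else rate_down
  structure(
    list(name = name, logic = expr, rate_up = ru, rate_down = rd,
         node_class = node_class,
         druggable = node_class %in% .DRUGGABLE_CLASSES),
    class = "node_decl")
}

#' Assemble a Boolean network
#'
#' Validates that node names are unique, every identifier referenced in a
#' rule is a declared node, and the Division/Death/Trigger designations (if
#' given) name declared nodes.  When not given, nodes literally named
#' `Division`, `Death` and `Trigger` are picked up automatically.
#'
#' @param nodes list of [node_decl()] objects.
#' @param division_node,death_node,trigger_node identifiers or `NULL`.
#' @return object of class `boolean_network`.
#' @export
boolean_network <- function(nodes, division_node = NULL, death_node = NULL,
                            trigger_node = NULL) {
  names(nodes) <- vapply(nodes, `[[`, character(1), "name")
  if (anyDuplicated(names(nodes))) {
    stop(sprintf("duplicate node name(s): %s",
                 paste(unique(names(nodes)[duplicated(names(nodes))]),
                       collapse = ", ")), call. = FALSE)
  }
  declared <- names(nodes)
  for (nd in nodes) {
    refs <- logic_inputs(nd$logic)
    unknown <- setdiff(refs, declared)
    if (length(unknown)) {
      stop(sprintf("rule of node '%s' references undeclared node(s): %s",
                   nd$name, paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  auto <- function(given, conventional) {
    if (!is.null(given)) {
      if (!given %in% declared) {
        stop(sprintf("'%s' is not a declared node", given), call. = FALSE)
      }
      given
    } else if (conventional %in% declared) conventional else NULL
  }
  net <- structure(
    list(nodes = nodes,
         division_node = auto(division_node, "Division"),
         death_node = auto(death_node, "Death"),
         trigger_node = auto(trigger_node, "Trigger"),
         clamped = numeric(0)),
    class = "boolean_network")
  net
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("Boolean network: %d nodes\n", length(x$nodes)))
  cls <- table(vapply(x$nodes, `[[`, character(1), "node_class"))
  cat("  classes:", paste(sprintf("%s=%d", names(cls), cls), collapse = ", "),
      "\n")
  for (role in c("division_node", "death_node", "trigger_node")) {
    if (!is.null(x[[role]])) cat(sprintf("  %s: %s\n", role, x[[role]]))
  }
  if (length(x$clamped)) {
    cat("  clamped:",
        paste(sprintf("%s=%d", names(x$clamped), x$clamped), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Node names of a network
#' @param net a `boolean_network`.
#' @export
node_names <- function(net) names(net$nodes)

#' Symbolic rate parameters used by a network
#' @param net a `boolean_network`.
#' @return character vector of `$`-parameter names across all rate expressions.
#' @export
rate_params <- function(net) {
  out <- character(0)
  for (nd in net$nodes) {
    for (r in list(nd$rate_up, nd$rate_down)) {
      if (inherits(r, "rate_expr")) out <- c(out, r$params)
    }
  }
  unique(out)
}

#' Annotate node classes
#'
#' @param net a `boolean_network`.
#' @param classes named character vector, node -> class.
#' @return network with updated `node_class` and derived `druggable` flags.
#' @export
set_node_classes <- function(net, classes) {
  unknown <- setdiff(names(classes), node_names(net))
  if (length(unknown)) {
    stop(sprintf("annotation for undeclared node(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  for (nm in names(classes)) {
    cls <- match.arg(classes[[nm]], .NODE_CLASSES)
    net$nodes[[nm]]$node_class <- cls
    net$nodes[[nm]]$druggable <- cls %in% .DRUGGABLE_CLASSES
  }
  net
}

#' Node annotation table
#'
#' @param net a `boolean_network`.
#' @return data.frame with columns `node`, `node_class`, `druggable`.
#' @export
node_annotations <- function(net) {
  data.frame(
    node = node_names(net),
    node_class = vapply(net$nodes, `[[`, character(1), "node_class"),
    druggable = vapply(net$nodes, `[[`, logical(1), "druggable"),
    row.names = NULL, stringsAsFactors = FALSE)
}
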