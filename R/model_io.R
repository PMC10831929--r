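# MaBoSS-dialect model files ------------------------------------------------
#
# Three text files describe a population model:
#   .bnd  node blocks:      node NAME { logic = ...; rate_up = ...; rate_down = ...; }
#   .cfg  parameters:       $name = value;   NAME.istate = p;   n_trajectories = ...;
#   .upp  population layer: division_node = ...; n_steps = ...; update $par = formula;
# plus an optional TSV annotation side-file (node, node_class, druggable)
# carrying the cell/ligand/receptor/TF classes used for druggability.

.strip_comments <- function(lines) {
  sub("(//|#).*$", "", lines)
}

#' Parse a logic (.bnd) file
#'
#' @param text file contents as a single string or character vector of lines.
#' @return a validated [boolean_network()].
#' @export
parse_bnd <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1L]]
  } else text
  raw <- lines
  lines <- .strip_comments(lines)
  nodes <- list()
  i <- 1L
  n <- length(lines)
  syntax_err <- function(ln, msg) {
    stop(sprintf("line %d: %s ('%s')", ln, msg, trimws(raw[ln])), call. = FALSE)
  }
  while (i <= n) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) { i <- i + 1L; next }
    m <- regmatches(ln, regexec("^[Nn]ode\\s+([A-Za-z_][A-Za-z0-9_]*)\\s*\\{\\s*$", ln))[[1L]]
    if (length(m) == 0L) syntax_err(i, "expected 'node NAME {'")
    name <- m[2L]
    if (name %in% vapply(nodes, `[[`, character(1), "name")) {
      syntax_err(i, sprintf("duplicate node '%s'", name))
    }
    fields <- list()
    i <- i + 1L
    repeat {
      if (i > n) stop(sprintf("unterminated block for node '%s'", name),
                      call. = FALSE)
      ln <- trimws(lines[i])
      if (ln == "}") break
      if (!nzchar(ln)) { i <- i + 1L; next }
      fm <- regmatches(ln, regexec(
        "^(logic|rate_up|rate_down)\\s*=\\s*(.*?)\\s*;\\s*$", ln))[[1L]]
      if (length(fm) == 0L) syntax_err(i, "expected 'field = value;'")
      fields[[fm[2L]]] <- fm[3L]
      i <- i + 1L
    }
    i <- i + 1L
    if (is.null(fields$logic)) {
      stop(sprintf("node '%s' has no logic rule", name), call. = FALSE)
    }
    nodes[[length(nodes) + 1L]] <- node_decl(
      name, fields$logic,
      rate_up = if (is.null(fields$rate_up)) 1 else fields$rate_up,
      rate_down = if (is.null(fields$rate_down)) 1 else fields$rate_down)
  }
  if (length(nodes) == 0L) stop("no node declarations found", call. = FALSE)
  boolean_network(nodes)
}

#' Parse a configuration (.cfg) file
#'
#' Binds every symbolic rate parameter of `net`, sets initial activation
#' probabilities (`NAME.istate = p;`, defaulting to 0 for unlisted nodes),
#' and reads the Monte-Carlo settings (`n_trajectories`, `t_max`,
#' `window_dt`, `seed`).  Unset settings take the package defaults and are
#' recorded in the `defaults_applied` attribute.
#'
#' @param text file contents.
#' @param net the network the configuration belongs to.
#' @return a [sim_config()].
#' @export
parse_cfg <- function(text, net) {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1L]]
  } else text
  lines <- .strip_comments(lines)
  params <- numeric(0)
  init <- numeric(0)
  settings <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    pm <- regmatches(ln, regexec(
      "^\\$([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*([-+0-9.eE]+)\\s*;\\s*$", ln))[[1L]]
    if (length(pm)) {
      params[pm[2L]] <- as.numeric(pm[3L])
      next
    }
    im <- regmatches(ln, regexec(
      "^\\[?([A-Za-z_][A-Za-z0-9_]*)\\]?\\.istate\\s*=\\s*([0-9.eE+-]+)\\s*;\\s*$",
      ln))[[1L]]
    if (length(im)) {
      if (!im[2L] %in% node_names(net)) {
        stop(sprintf("line %d: istate for undeclared node '%s'", i, im[2L]),
             call. = FALSE)
      }
      init[im[2L]] <- as.numeric(im[3L])
      next
    }
    sm <- regmatches(ln, regexec(
      "^(n_trajectories|t_max|window_dt|seed)\\s*=\\s*([-+0-9.eE]+)\\s*;\\s*$",
      ln))[[1L]]
    if (length(sm)) {
      settings[[sm[2L]]] <- as.numeric(sm[3L])
      next
    }
    stop(sprintf("line %d: cannot parse '%s'", i, ln), call. = FALSE)
  }
  if (length(params) && any(params < 0)) {
    bad <- names(params)[params < 0][1L]
    stop(sprintf("negative rate parameter '%s'", bad), call. = FALSE)
  }
  needed <- rate_params(net)
  missing <- setdiff(needed, names(params))
  if (length(missing)) {
    stop(sprintf("unbound rate parameter(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  defaults <- setdiff(c("n_trajectories", "t_max", "window_dt", "seed"),
                      names(settings))
  cfg <- sim_config(
    parameters = params, init = init,
    n_trajectories = settings$n_trajectories %||% 50000,
    t_max = settings$t_max %||% 100,
    window_dt = settings$window_dt %||% 1,
    seed = settings$seed %||% 1L)
  attr(cfg, "defaults_applied") <- defaults
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a population-update (.upp) file
#'
#' Declares the Division/Death nodes, the synchronous step settings, and the
#' explicit list of externally updated parameters with their formulas
#' (`update $par = formula;`).  Which parameters are external is taken
#' verbatim from this file, never inferred.
#'
#' @param text file contents.
#' @param net the network (update formulas may only reference its nodes).
#' @return list with elements `popcfg` (a [pop_config()]) and `net` (the
#'   network with division/death designations applied).
#' @export
parse_upp <- function(text, net) {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1L]]
  } else text
  lines <- .strip_comments(lines)
  opts <- list()
  rules <- character(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    um <- regmatches(ln, regexec(
      "^update\\s+\\$([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*?)\\s*;\\s*$", ln))[[1L]]
    if (length(um)) {
      rules[um[2L]] <- um[3L]
      next
    }
    om <- regmatches(ln, regexec(
      "^(division_node|death_node|trigger_node|step_dt|n_steps|death_precedence)\\s*=\\s*(.*?)\\s*;\\s*$",
      ln))[[1L]]
    if (length(om)) {
      opts[[om[2L]]] <- om[3L]
      next
    }
    stop(sprintf("line %d: cannot parse '%s'", i, ln), call. = FALSE)
  }
  for (role in c("division_node", "death_node", "trigger_node")) {
    if (!is.null(opts[[role]])) {
      if (!opts[[role]] %in% node_names(net)) {
        stop(sprintf("%s '%s' is not a declared node", role, opts[[role]]),
             call. = FALSE)
      }
      net[[role]] <- opts[[role]]
    }
  }
  popcfg <- pop_config(
    step_dt = as.numeric(opts$step_dt %||% 1),
    n_steps = as.integer(opts$n_steps %||% 100),
    update_rules = rules,
    death_precedence = toupper(opts$death_precedence %||% "TRUE") %in%
      c("TRUE", "T", "1", "YES"))
  for (r in popcfg$update_rules) {
    unknown <- setdiff(r$nodes, node_names(net))
    if (length(unknown)) {
      stop(sprintf("update formula for '%s' references unknown node(s): %s",
                   r$param, paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  list(popcfg = popcfg, net = net)
}

#' Read a model from .bnd / .cfg / .upp / annotation files
#'
#' @param bnd,cfg,upp,annotations file paths (`cfg`, `upp`, `annotations`
#'   optional).
#' @return list with `net`, `cfg` (or NULL), `popcfg` (or NULL).
#' @export
read_model <- function(bnd, cfg = NULL, upp = NULL, annotations = NULL) {
  net <- parse_bnd(readLines(bnd, warn = FALSE))
  if (!is.null(annotations)) net <- read_annotations(annotations, net)
  config <- if (!is.null(cfg)) parse_cfg(readLines(cfg, warn = FALSE), net)
  popcfg <- NULL
  if (!is.null(upp)) {
    up <- parse_upp(readLines(upp, warn = FALSE), net)
    net <- up$net
    popcfg <- up$popcfg
  }
  list(net = net, cfg = config, popcfg = popcfg)
}

#' Write a model to .bnd / .cfg / .upp / annotation files
#'
#' The written files parse back to a semantically identical model: same
#' nodes, Boolean-equivalent rules, same parameter bindings and update
#' formulas (round-trip contract).
#'
#' @param net a `boolean_network`.
#' @param cfg optional `sim_config`.
#' @param popcfg optional `pop_config`.
#' @param basename path prefix; writes `<basename>.bnd` and, when given,
#'   `<basename>.cfg`, `<basename>.upp`, `<basename>_nodes.tsv`.
#' @return invisibly, the named vector of files written.
#' @export
write_model <- function(net, cfg = NULL, popcfg = NULL, basename) {
  files <- c(bnd = paste0(basename, ".bnd"))
  out <- character(0)
  for (nd in net$nodes) {
    out <- c(out,
             sprintf("node %s {", nd$name),
             sprintf("  logic = %s;", deparse_logic(nd$logic)),
             sprintf("  rate_up = %s;", format_rate(nd$rate_up)),
             sprintf("  rate_down = %s;", format_rate(nd$rate_down)),
             "}", "")
  }
  writeLines(out, files["bnd"])
  ann <- node_annotations(net)
  files["annotations"] <- paste0(basename, "_nodes.tsv")
  utils::write.table(ann, files["annotations"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(cfg)) {
    files["cfg"] <- paste0(basename, ".cfg")
    out <- c(
      sprintf("$%s = %s;", names(cfg$parameters),
              vapply(cfg$parameters, format, character(1), digits = 17)),
      sprintf("%s.istate = %s;", names(cfg$init),
              vapply(cfg$init, format, character(1), digits = 17)),
      sprintf("n_trajectories = %d;", cfg$n_trajectories),
      sprintf("t_max = %s;", format(cfg$t_max, digits = 17)),
      sprintf("window_dt = %s;", format(cfg$window_dt, digits = 17)),
      sprintf("seed = %d;", cfg$seed))
    writeLines(out, files["cfg"])
  }
  if (!is.null(popcfg)) {
    files["upp"] <- paste0(basename, ".upp")
    out <- character(0)
    if (!is.null(net$division_node)) {
      out <- c(out, sprintf("division_node = %s;", net$division_node))
    }
    if (!is.null(net$death_node)) {
      out <- c(out, sprintf("death_node = %s;", net$death_node))
    }
    if (!is.null(net$trigger_node)) {
      out <- c(out, sprintf("trigger_node = %s;", net$trigger_node))
    }
    out <- c(out,
             sprintf("step_dt = %s;", format(popcfg$step_dt, digits = 17)),
             sprintf("n_steps = %d;", popcfg$n_steps),
             sprintf("death_precedence = %s;", popcfg$death_precedence),
             vapply(popcfg$update_rules, function(r) {
               sprintf("update $%s = %s;", r$param, r$text)
             }, character(1)))
    writeLines(out, files["upp"])
  }
  invisible(files)
}

#' Read / apply a node annotation TSV
#'
#' @param path TSV with columns `node`, `node_class` (and optionally
#'   `druggable`, which is ignored: druggability is derived from the class).
#' @param net network to annotate.
#' @return annotated network.
#' @export
read_annotations <- function(path, net) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("node", "node_class") %in% names(tab))) {
    stop("annotation file needs columns 'node' and 'node_class'", call. = FALSE)
  }
  set_node_classes(net, stats::setNames(tab$node_class, tab$node))
}
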