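# Boolean rule expressions ------------------------------------------------
#
# Rules are written over node identifiers with AND / OR / NOT (case-insensitive
# keywords) or the symbolic equivalents & | !, plus parentheses and the
# literals 0/1/TRUE/FALSE.  Internally a rule is an ordinary R language object
# using `&`, `|`, `!`, so it can be evaluated vectorised over state columns.

.tokenize_logic <- function(text) {
  pat <- "\\s*([A-Za-z_][A-Za-z0-9_]*|&&|\\|\\||[&|!()]|\\b[01]\\b)"
  tokens <- character(0)
  rest <- text
  while (nzchar(trimws(rest))) {
    m <- regexpr(pat, rest, perl = TRUE)
    if (m != 1L) {
      stop(sprintf("invalid token near '%s' in rule '%s'",
                   substr(trimws(rest), 1, 12), text), call. = FALSE)
    }
    tok <- trimws(regmatches(rest, m))
    tokens <- c(tokens, tok)
    rest <- substr(rest, attr(m, "match.length") + 1L, nchar(rest))
  }
  tokens
}

.tok_kind <- function(tok) {
  up <- toupper(tok)
  if (up %in% c("AND", "&", "&&")) return("AND")
  if (up %in% c("OR", "|", "||")) return("OR")
  if (up %in% c("NOT", "!")) return("NOT")
  if (up %in% c("TRUE", "1")) return("TRUE")
  if (up %in% c("FALSE", "0")) return("FALSE")
  if (tok %in% c("(", ")")) return(tok)
  "IDENT"
}

#' Parse a Boolean rule into an R expression
#'
#' Accepts `AND`/`OR`/`NOT` keywords (any case) or `&`/`|`/`!`, parentheses,
#' node identifiers and the constants `0`/`1`/`TRUE`/`FALSE`.  `NOT` binds
#' tightest, then `AND`, then `OR`.
#'
#' @param text rule text, e.g. `"Prol_KC AND STAT3"`.
#' @return an R language object over node-name symbols using `&`, `|`, `!`.
#' @examples
#' parse_logic("Th0 AND RORgamma")
#' parse_logic("NOT (A | B)")
#' @export
parse_logic <- function(text) {
  tokens <- .tokenize_logic(text)
  if (length(tokens) == 0L) stop("empty logic rule", call. = FALSE)
  kinds <- vapply(tokens, .tok_kind, character(1), USE.NAMES = FALSE)
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) kinds[pos] else "EOF"
  advance <- function() {
    tok <- tokens[pos]
    pos <<- pos + 1L
    tok
  }
  parse_or <- function() {
    e <- parse_and()
    while (peek() == "OR") {
      advance()
      e <- call("|", e, parse_and())
    }
    e
  }
  parse_and <- function() {
    e <- parse_not()
    while (peek() == "AND") {
      advance()
      e <- call("&", e, parse_not())
    }
    e
  }
  parse_not <- function() {
    if (peek() == "NOT") {
      advance()
      return(call("!", parse_not()))
    }
    parse_primary()
  }
  parse_primary <- function() {
    k <- peek()
    if (k == "(") {
      advance()
      e <- parse_or()
      if (peek() != ")") stop(sprintf("missing ')' in rule '%s'", text), call. = FALSE)
      advance()
      return(e)
    }
    if (k == "TRUE") { advance(); return(TRUE) }
    if (k == "FALSE") { advance(); return(FALSE) }
    if (k == "IDENT") return(as.symbol(advance()))
    stop(sprintf("unexpected token '%s' in rule '%s'", tokens[pos], text),
         call. = FALSE)
  }
  e <- parse_or()
  if (pos <= length(tokens)) {
    stop(sprintf("trailing input '%s' in rule '%s'", tokens[pos], text),
         call. = FALSE)
  }
  e
}

#' Node identifiers referenced by a rule
#'
#' @param expr parsed rule (from [parse_logic()]) or rule text.
#' @return character vector of distinct identifiers, in order of appearance.
#' @export
logic_inputs <- function(expr) {
  if (is.character(expr)) expr <- parse_logic(expr)
  out <- character(0)
  walk <- function(e) {
    if (is.symbol(e)) {
      out[[length(out) + 1L]] <<- as.character(e)
    } else if (is.call(e)) {
      for (a in as.list(e)[-1L]) walk(a)
    }
  }
  walk(expr)
  unique(out)
}

#' Syntactic regulator signs of a rule
#'
#' Sign is the parity of `NOT` nesting around each occurrence of a regulator:
#' even parity is activating (+1), odd is inhibiting (-1).  A regulator that
#' occurs under both parities is reported twice, once per sign, so ambiguous
#' dual-role inputs are surfaced rather than hidden.
#'
#' @inheritParams logic_inputs
#' @return data.frame with columns `regulator` and `sign` (+1 / -1).
#' @export
logic_signs <- function(expr) {
  if (is.character(expr)) expr <- parse_logic(expr)
  regs <- character(0)
  signs <- integer(0)
  walk <- function(e, parity) {
    if (is.symbol(e)) {
      regs[[length(regs) + 1L]] <<- as.character(e)
      signs[[length(signs) + 1L]] <<- if (parity %% 2L == 0L) 1L else -1L
    } else if (is.call(e)) {
      op <- as.character(e[[1L]])
      if (op == "!") {
        walk(e[[2L]], parity + 1L)
      } else {
        for (a in as.list(e)[-1L]) walk(a, parity)
      }
    }
  }
  walk(expr, 0L)
  out <- unique(data.frame(regulator = regs, sign = signs,
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Render a parsed rule back to the keyword dialect
#'
#' @param expr parsed rule.
#' @return single string using `AND`/`OR`/`NOT`.
#' @export
deparse_logic <- function(expr) {
  render <- function(e, parent_prec) {
    if (isTRUE(e)) return("1")
    if (isFALSE(e)) return("0")
    if (is.symbol(e)) return(as.character(e))
    op <- as.character(e[[1L]])
    if (op == "!") {
      s <- paste("NOT", render(e[[2L]], 3L))
      return(if (parent_prec > 3L) paste0("(", s, ")") else s)
    }
    prec <- if (op == "&") 2L else 1L
    kw <- if (op == "&") "AND" else "OR"
    s <- paste(render(e[[2L]], prec), kw, render(e[[3L]], prec))
    if (parent_prec > prec) paste0("(", s, ")") else s
  }
  render(expr, 0L)
}

# Rate expressions ---------------------------------------------------------
#
# A rate is a nonnegative constant, a symbolic parameter written `$name`, or
# an arithmetic formula over those (+ - * / and parentheses).  Parameters are
# bound at simulation time from the configuration.

.RATE_TOKEN_RE <- "^\\s*(([0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?)|\\$[A-Za-z_][A-Za-z0-9_]*|[-+*/()]|\\s+)+\\s*$"

#' Parse a rate expression
#'
#' @param text e.g. `"0.5"`, `"$ku_AMP"`, `"2 * $c"`.
#' @return object of class `rate_expr`: the parsed expression plus the
#'   parameter names it references.
#' @export
parse_rate <- function(text) {
  text <- trimws(text)
  if (!nzchar(text)) stop("empty rate expression", call. = FALSE)
  if (!grepl(.RATE_TOKEN_RE, text)) {
    stop(sprintf("invalid rate expression '%s'", text), call. = FALSE)
  }
  params <- unique(unlist(regmatches(
    text, gregexpr("\\$[A-Za-z_][A-Za-z0-9_]*", text))))
  params <- sub("^\\$", "", params)
  expr <- str2lang(gsub("$", "", text, fixed = TRUE))
  structure(list(text = text, expr = expr, params = params),
            class = "rate_expr")
}

#' Evaluate a rate expression under a parameter assignment
#'
#' @param rate a `rate_expr` (or a bare number).
#' @param params named numeric vector of parameter values.
#' @return nonnegative finite numeric scalar.
#' @export
eval_rate <- function(rate, params = numeric(0)) {
  if (is.numeric(rate)) {
    val <- rate
  } else {
    missing <- setdiff(rate$params, names(params))
    if (length(missing)) {
      stop(sprintf("unbound rate parameter(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    val <- eval(rate$expr, envir = as.list(params), enclos = baseenv())
  }
  if (!is.finite(val) || val < 0) {
    stop(sprintf("rate evaluates to a non-finite or negative value (%s)",
                 format(val)), call. = FALSE)
  }
  as.numeric(val)
}

format_rate <- function(rate) {
  if (is.numeric(rate)) format(rate, digits = 17) else rate$text
}
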