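#' Parse a Boolean rule expression
#'
#' Parses the textual rule dialect used in network-definition files into an
#' R language object. The dialect has the three operators \code{AND},
#' \code{OR} and \code{NOT} (upper case, whitespace-delimited), parentheses
#' for grouping, and bare node names as literals. Node names may contain any
#' non-blank character except parentheses and commas, so names such as
#' \code{MEK1/2}, \code{c-Src} or \code{p90RSK} need no quoting.
#'
#' Operator precedence is the usual one: \code{NOT} binds tightest, then
#' \code{AND}, then \code{OR}.
#'
#' @param text a single character string holding one expression.
#' @return an R call composed of \code{`&`}, \code{`|`}, \code{`!`} and
#'   symbols, suitable for [eval()] against a named list of logicals.
#' @seealso [deparse_bool_expr()], [bool_expr_vars()]
#' @export
#' @examples
#' e <- parse_bool_expr("Sos1 AND NOT (ERK1/2 OR p90RSK)")
#' eval(e, list(Sos1 = TRUE, `ERK1/2` = FALSE, p90RSK = FALSE))
parse_bool_expr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- tokenize_bool(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  e <- parse_or(st)
  if (st$pos <= length(st$toks))
    stop("malformed expression: trailing input at '", st$toks[st$pos],
         "' in: ", text, call. = FALSE)
  e
}

tokenize_bool <- function(text) {
  spaced <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(spaced), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) stop("malformed expression: empty", call. = FALSE)
  toks
}

peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

advance <- function(st) { st$pos <- st$pos + 1L; invisible(NULL) }

parse_or <- function(st) {
  e <- parse_and(st)
  while (identical(peek(st), "OR")) {
    advance(st)
    e <- call("|", e, parse_and(st))
  }
  e
}

parse_and <- function(st) {
  e <- parse_not(st)
  while (identical(peek(st), "AND")) {
    advance(st)
    e <- call("&", e, parse_not(st))
  }
  e
}

parse_not <- function(st) {
  tok <- peek(st)
  if (is.na(tok))
    stop("malformed expression: unexpected end of input", call. = FALSE)
  if (identical(tok, "NOT")) {
    advance(st)
    return(call("!", parse_not(st)))
  }
  if (identical(tok, "(")) {
    advance(st)
    e <- parse_or(st)
    if (!identical(peek(st), ")"))
      stop("malformed expression: missing ')'", call. = FALSE)
    advance(st)
    return(e)
  }
  if (tok %in% c(")", "AND", "OR"))
    stop("malformed expression: unexpected '", tok, "'", call. = FALSE)
  advance(st)
  as.name(tok)
}

#' Render a Boolean rule expression as text
#'
#' Inverse of [parse_bool_expr()]: produces the canonical textual form with
#' \code{AND}/\code{OR}/\code{NOT} and explicit parentheses wherever a
#' lower-precedence subexpression appears under a higher-precedence
#' operator, so that \code{parse_bool_expr(deparse_bool_expr(e))} is
#' structurally identical to \code{e}.
#'
#' @param expr an R call as produced by [parse_bool_expr()].
#' @return a character string.
#' @export
deparse_bool_expr <- function(expr) deparse_prec(expr)$text

# precedence: OR = 1, AND = 2, NOT = 3, literal = 4
deparse_prec <- function(expr) {
  if (is.name(expr)) return(list(text = as.character(expr), prec = 4L))
  if (!is.call(expr)) stop("not a Boolean expression: ", class(expr)[1])
  op <- as.character(expr[[1]])
  wrap <- function(sub, minp) {
    d <- deparse_prec(sub)
    if (d$prec < minp) paste0("(", d$text, ")") else d$text
  }
  switch(op,
    "|" = list(text = paste(wrap(expr[[2]], 1L), "OR", wrap(expr[[3]], 2L)),
               prec = 1L),
    "&" = list(text = paste(wrap(expr[[2]], 2L), "AND", wrap(expr[[3]], 3L)),
               prec = 2L),
    "!" = list(text = paste("NOT", wrap(expr[[2]], 4L)), prec = 3L),
    stop("unsupported operator in Boolean expression: ", op)
  )
}

#' List the node names referenced by a rule expression
#'
#' @param expr an R call as produced by [parse_bool_expr()].
#' @return character vector of distinct literal names, in order of first use.
#' @export
bool_expr_vars <- function(expr) {
  out <- character(0)
  walk <- function(e) {
    if (is.name(e)) out[[length(out) + 1L]] <<- as.character(e)
    else if (is.call(e)) for (i in seq_along(e)[-1]) walk(e[[i]])
  }
  walk(expr)
  unique(out)
}

# Signed literal occurrences: data.frame(node, sign) where sign is +1 for a
# literal under an even number of NOTs, -1 under odd (inhibition).
bool_expr_signed_vars <- function(expr) {
  nodes <- character(0); signs <- integer(0)
  walk <- function(e, neg) {
    if (is.name(e)) {
      nodes[[length(nodes) + 1L]] <<- as.character(e)
      signs[[length(signs) + 1L]] <<- if (neg) -1L else 1L
    } else if (is.call(e)) {
      op <- as.character(e[[1]])
      if (op == "!") walk(e[[2]], !neg)
      else for (i in seq_along(e)[-1]) walk(e[[i]], neg)
    }
  }
  walk(expr, FALSE)
  unique(data.frame(node = nodes, sign = signs))
}
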