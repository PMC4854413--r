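#' Construct a Boolean signalling network
#'
#' The central container of the package: a set of named binary nodes, one
#' update rule per non-input, non-constitutive node, and (optionally) a
#' regulator hierarchy for the Rac1 rule. Nodes without a rule (the clamped
#' input, constitutive inhibitors, knocked-out nodes) hold their state for
#' all time.
#'
#' @param nodes data.frame with columns \code{name} (unique strings),
#'   \code{kind} (one of \code{"input"}, \code{"output"},
#'   \code{"intermediate"}), \code{initial} (0/1) and \code{constitutive}
#'   (logical; input-less nodes whose state is clamped, e.g. basal
#'   inhibitory phosphatases).
#' @param rules named list of update expressions (R calls as produced by
#'   [parse_bool_expr()]), one per target node.
#' @param hierarchy optional [hierarchy_spec()] recorded as the precedence
#'   ordering the Rac1 rule was compiled from.
#' @param provenance optional named character vector of free-text citation
#'   tags, one per rule target.
#' @param metadata free-text character scalar.
#' @return an object of class \code{boolean_network}.
#' @seealso [parse_network()], [rcp_network()], [simulate_synchronous()]
#' @export
boolean_network <- function(nodes, rules, hierarchy = NULL,
                            provenance = NULL, metadata = "") {
  if (is.null(nodes$constitutive)) nodes$constitutive <- FALSE
  nodes$name <- as.character(nodes$name)
  nodes$kind <- as.character(nodes$kind)
  nodes$initial <- as.integer(nodes$initial)
  nodes$constitutive <- as.logical(nodes$constitutive)
  if (is.null(nodes$clamped))
    nodes$clamped <- nodes$kind == "input" | nodes$constitutive
  nodes$clamped <- as.logical(nodes$clamped) | nodes$kind == "input" |
    nodes$constitutive
  net <- structure(
    list(nodes = nodes, rules = rules, hierarchy = hierarchy,
         provenance = provenance, metadata = metadata),
    class = "boolean_network")
  validate_network(net)
  net
}

#' Validate a Boolean network
#'
#' Checks the structural invariants: unique node names, known kinds, binary
#' initial states, at most one input node, one rule per declared target,
#' every rule literal referencing a declared node, no rule on the input or
#' on constitutive nodes, and a rule on every other node.
#'
#' @param net a [boolean_network()].
#' @return the network, invisibly; errors describe the first violation.
#' @export
validate_network <- function(net) {
  nodes <- net$nodes
  if (anyDuplicated(nodes$name))
    stop("duplicate node name: ",
         nodes$name[duplicated(nodes$name)][1], call. = FALSE)
  bad_kind <- setdiff(unique(nodes$kind), c("input", "output", "intermediate"))
  if (length(bad_kind))
    stop("unknown node kind: ", bad_kind[1], call. = FALSE)
  if (!all(nodes$initial %in% c(0L, 1L)))
    stop("initial states must be 0 or 1", call. = FALSE)
  if (sum(nodes$kind == "input") > 1L)
    stop("at most one input node is allowed", call. = FALSE)
  targets <- names(net$rules)
  if (anyDuplicated(targets))
    stop("duplicate rule for target: ",
         targets[duplicated(targets)][1], call. = FALSE)
  unknown_target <- setdiff(targets, nodes$name)
  if (length(unknown_target))
    stop("rule targets undeclared node: ", unknown_target[1], call. = FALSE)
  for (tg in targets) {
    refs <- bool_expr_vars(net$rules[[tg]])
    missing <- setdiff(refs, nodes$name)
    if (length(missing))
      stop("rule for '", tg, "' references undeclared node: ",
           missing[1], call. = FALSE)
  }
  clamped <- nodes$name[nodes$clamped]
  ruled_clamp <- intersect(targets, clamped)
  if (length(ruled_clamp))
    stop("clamped node must not carry a rule: ", ruled_clamp[1],
         call. = FALSE)
  need_rule <- setdiff(nodes$name, clamped)
  unruled <- setdiff(need_rule, targets)
  if (length(unruled))
    stop("node lacks an update rule: ", unruled[1], call. = FALSE)
  invisible(net)
}

#' @export
print.boolean_network <- function(x, ...) {
  k <- table(factor(x$nodes$kind, c("input", "output", "intermediate")))
  cat(sprintf("<boolean_network> %d nodes (%d input, %d output, %d intermediate), %d rules\n",
              nrow(x$nodes), k[["input"]], k[["output"]],
              k[["intermediate"]], length(x$rules)))
  if (!is.null(x$hierarchy))
    cat("  hierarchy:", format_hierarchy(x$hierarchy), "\n")
  if (nzchar(x$metadata)) cat("  ", x$metadata, "\n", sep = "")
  invisible(x)
}

#' Names of clamped nodes (no rule; state held for all time)
#' @param net a [boolean_network()].
#' @return character vector.
#' @export
clamped_nodes <- function(net) {
  setdiff(net$nodes$name, names(net$rules))
}

#' Initial state vector of a network
#' @param net a [boolean_network()].
#' @return named integer vector of 0/1, one entry per node.
#' @export
initial_state <- function(net) {
  stats::setNames(net$nodes$initial, net$nodes$name)
}

# ---- network-definition text format ------------------------------------

#' Parse a network-definition document
#'
#' Reads the line-oriented network format. The document has three sections:
#' \describe{
#'   \item{\code{[nodes]}}{lines \code{name, kind, initial} with an optional
#'     fourth field \code{constitutive};}
#'   \item{\code{[rules]}}{lines \code{target, expression} in the
#'     [parse_bool_expr()] dialect, optionally followed by
#'     \code{ | provenance tag};}
#'   \item{\code{[hierarchy]}}{a single line of tiers separated by \code{>},
#'     members comma-separated, e.g. \code{Sos1E > pRacGAP1 > Vav2, RalBP1}.}
#' }
#' \code{#} starts a comment; blank lines are ignored. A two-line shorthand
#' with no section headers is also accepted, in which \code{name, <input>}
#' declares the input and \code{target, expression} declares both the node
#' and its rule.
#'
#' @param text character vector of lines (or one string with embedded
#'   newlines), or the path of a file to read.
#' @return a validated [boolean_network()].
#' @export
#' @examples
#' net <- parse_network(c("EGF, <input>", "EGFR1, EGF"))
#' net$rules$EGFR1
parse_network <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- nzchar(trimws(lines))
  raw <- trimws(lines[keep])
  lineno <- which(keep)

  section <- "rules"  # header-less shorthand defaults to rule lines
  nodes <- list(); rules <- list(); prov <- character(0); hier_line <- NULL
  shorthand <- !any(grepl("^\\[", raw))

  for (i in seq_along(raw)) {
    ln <- raw[i]
    if (grepl("^\\[", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (!section %in% c("nodes", "rules", "hierarchy"))
        stop("line ", lineno[i], ": unknown section [", section, "]",
             call. = FALSE)
      next
    }
    if (section == "nodes") {
      f <- trimws(strsplit(ln, ",", fixed = TRUE)[[1]])
      if (length(f) < 3L)
        stop("line ", lineno[i], ": node line needs 'name, kind, initial'",
             call. = FALSE)
      flags <- if (length(f) >= 4L) f[-(1:3)] else character(0)
      nodes[[length(nodes) + 1L]] <- data.frame(
        name = f[1], kind = f[2], initial = as.integer(f[3]),
        constitutive = "constitutive" %in% flags,
        clamped = any(c("constitutive", "clamped") %in% flags) ||
          f[2] == "input")
    } else if (section == "rules") {
      m <- regexpr(",", ln, fixed = TRUE)
      if (m < 0)
        stop("line ", lineno[i], ": rule line needs 'target, expression'",
             call. = FALSE)
      target <- trimws(substr(ln, 1L, m - 1L))
      rhs <- trimws(substr(ln, m + 1L, nchar(ln)))
      ptag <- ""
      bar <- regexpr("|", rhs, fixed = TRUE)
      if (bar > 0) {
        stop_at <- bar  # '|' is not a dialect operator, so safe to split
        ptag <- trimws(substr(rhs, stop_at + 1L, nchar(rhs)))
        rhs <- trimws(substr(rhs, 1L, stop_at - 1L))
      }
      if (target %in% names(rules))
        stop("line ", lineno[i], ": duplicate rule for target '", target,
             "'", call. = FALSE)
      if (shorthand && identical(rhs, "<input>")) {
        nodes[[length(nodes) + 1L]] <- data.frame(
          name = target, kind = "input", initial = 1L,
          constitutive = FALSE, clamped = TRUE)
        next
      }
      rules[[target]] <- tryCatch(parse_bool_expr(rhs), error = function(e)
        stop("line ", lineno[i], ": ", conditionMessage(e), call. = FALSE))
      prov[[target]] <- ptag
    } else if (section == "hierarchy") {
      hier_line <- ln
    }
  }

  if (shorthand) {
    declared <- vapply(nodes, function(n) n$name, "")
    for (tg in names(rules)) {
      if (!tg %in% declared) {
        nodes[[length(nodes) + 1L]] <- data.frame(
          name = tg, kind = "intermediate", initial = 0L,
          constitutive = FALSE, clamped = FALSE)
        declared <- c(declared, tg)
      }
    }
    refs <- unique(unlist(lapply(rules, bool_expr_vars)))
    missing <- setdiff(refs, declared)
    if (length(missing))
      stop("rule references undeclared node: ", missing[1], call. = FALSE)
  }
  nodes <- do.call(rbind, nodes)
  hierarchy <- if (!is.null(hier_line)) parse_hierarchy(hier_line) else NULL
  boolean_network(nodes, rules, hierarchy = hierarchy,
                  provenance = if (length(prov)) prov else NULL)
}

#' Write a network-definition document
#'
#' Inverse of [parse_network()]: renders the network in the sectioned text
#' format such that \code{parse_network(write_network(net))} is structurally
#' identical to \code{net}.
#'
#' @param net a [boolean_network()].
#' @param file optional path; when given, the document is written there.
#' @return character vector of lines, invisibly when \code{file} is given.
#' @export
write_network <- function(net, file = NULL) {
  flag <- ifelse(net$nodes$constitutive, ", constitutive",
                 ifelse(net$nodes$clamped & net$nodes$kind != "input",
                        ", clamped", ""))
  nl <- paste0(net$nodes$name, ", ", net$nodes$kind, ", ",
               net$nodes$initial, flag)
  rl <- vapply(names(net$rules), function(tg) {
    line <- paste0(tg, ", ", deparse_bool_expr(net$rules[[tg]]))
    ptag <- net$provenance[[tg]]
    if (!is.null(ptag) && length(ptag) && nzchar(ptag))
      line <- paste0(line, " | ", ptag)
    line
  }, "")
  out <- c("[nodes]", nl, "", "[rules]", rl)
  if (!is.null(net$hierarchy))
    out <- c(out, "", "[hierarchy]", format_hierarchy(net$hierarchy))
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
}

#' Signed edge list of a network
#'
#' Flattens every rule into directed regulator/target edges with a sign:
#' \code{+1} when the regulator literal appears under an even number of
#' \code{NOT}s (activation), \code{-1} under an odd number (inhibition).
#' Suitable for export to graph tools.
#'
#' @param net a [boolean_network()].
#' @param file optional CSV path.
#' @return data.frame with columns \code{from}, \code{to}, \code{sign}.
#' @export
network_edges <- function(net, file = NULL) {
  rows <- lapply(names(net$rules), function(tg) {
    sv <- bool_expr_signed_vars(net$rules[[tg]])
    data.frame(from = sv$node, to = tg, sign = sv$sign)
  })
  edges <- do.call(rbind, rows)
  rownames(edges) <- NULL
  if (!is.null(file)) utils::write.csv(edges, file, row.names = FALSE)
  edges
}
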