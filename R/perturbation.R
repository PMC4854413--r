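# In-silico knockout screen: clamp one node for all time and re-classify
# the Rac1/RhoA output dynamics.

#' Apply a single-node knockout
#'
#' \code{clamp_off} removes every inward edge (the node's rule) and sets
#' the node's state to 0 for all time, including \code{t = 0}; this is how
#' every regular node is perturbed. Input-less constitutive inhibitors
#' (e.g. the basal phosphatases) have no inward edges to remove, so their
#' perturbation is \code{clamp_on}: the node is set to 1 for all time.
#' The original network is not modified.
#'
#' @param net a [boolean_network()].
#' @param node name of the node to perturb; must not be an output.
#' @param mode \code{"clamp_off"} (default) or \code{"clamp_on"}.
#' @return a new, validated [boolean_network()].
#' @export
#' @examples
#' ko <- apply_knockout(rcp_network(), "MEK1/2")
#' find_attractor(ko)$node_class[c("Rac1", "RhoA")]
apply_knockout <- function(net, node, mode = c("clamp_off", "clamp_on")) {
  mode <- match.arg(mode)
  i <- match(node, net$nodes$name)
  if (is.na(i)) stop("unknown node: ", node, call. = FALSE)
  if (net$nodes$kind[i] == "output")
    stop("output nodes cannot be knocked out: ", node, call. = FALSE)
  if (mode == "clamp_on" && !net$nodes$constitutive[i])
    stop("clamp_on is reserved for constitutive input-less inhibitors: ",
         node, call. = FALSE)
  net$rules[[node]] <- NULL
  net$provenance <- net$provenance[setdiff(names(net$provenance), node)]
  net$nodes$initial[i] <- if (mode == "clamp_on") 1L else 0L
  net$nodes$clamped[i] <- TRUE
  validate_network(net)
}

#' Default perturbation mode for a node
#'
#' Constitutive input-less inhibitors are clamped ON; every other node is
#' clamped OFF.
#'
#' @param net a [boolean_network()].
#' @param node node name.
#' @return \code{"clamp_on"} or \code{"clamp_off"}.
#' @export
knockout_mode <- function(net, node) {
  i <- match(node, net$nodes$name)
  if (is.na(i)) stop("unknown node: ", node, call. = FALSE)
  if (net$nodes$constitutive[i]) "clamp_on" else "clamp_off"
}

#' Run an in-silico knockout screen
#'
#' For every non-output node and every hierarchy, clamps the node (per
#' [knockout_mode()]), finds the synchronous attractor and classifies the
#' Rac1/RhoA outputs. The unperturbed classification for each hierarchy is
#' included as the \code{"(none)"} row, and each knockout row records
#' whether it changed the category relative to that baseline
#' (\code{effect}).
#'
#' @param net_factory function mapping a [hierarchy_spec()] to a network;
#'   defaults to [rcp_network()].
#' @param hierarchies list of [hierarchy_spec()]s to screen; defaults to
#'   the two experimentally admissible ones (cyclic-inducing Sos1E-top and
#'   switch-inducing pRacGAP1-top).
#' @param nodes nodes to knock out; defaults to every non-output node.
#' @return data.frame of class \code{knockout_screen} with columns
#'   \code{node}, \code{mode}, \code{hierarchy}, \code{rac1_class},
#'   \code{rhoa_class}, \code{category}, \code{rhoa_dominant},
#'   \code{effect}.
#' @export
run_screen <- function(net_factory = rcp_network,
                       hierarchies = list(hierarchy_spec("Sos1E"),
                                          hierarchy_spec()),
                       nodes = NULL) {
  rows <- list()
  for (h in hierarchies) {
    net <- net_factory(h)
    hlab <- format_hierarchy(h)
    base <- classify_hierarchy_output(find_attractor(net))
    ko_nodes <- if (is.null(nodes))
      net$nodes$name[net$nodes$kind != "output"] else nodes
    rows[[length(rows) + 1L]] <- data.frame(
      node = "(none)", mode = "none", hierarchy = hlab,
      rac1_class = base$rac1_class, rhoa_class = base$rhoa_class,
      category = base$category,
      rhoa_dominant = isTRUE(base$rhoa_dominant), effect = FALSE)
    for (nd in ko_nodes) {
      mode <- knockout_mode(net, nd)
      cls <- classify_hierarchy_output(
        find_attractor(apply_knockout(net, nd, mode)))
      rows[[length(rows) + 1L]] <- data.frame(
        node = nd, mode = mode, hierarchy = hlab,
        rac1_class = cls$rac1_class, rhoa_class = cls$rhoa_class,
        category = cls$category,
        rhoa_dominant = isTRUE(cls$rhoa_dominant),
        effect = cls$category != base$category)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("knockout_screen", "data.frame")
  out
}

#' Compare knockout screens run under two hierarchies
#'
#' The two baselines already differ (cyclic vs switch), so the comparison
#' is at the level of each knockout's \emph{effect}: did the knockout
#' change the output category away from that hierarchy's unperturbed
#' category? The result lists every node whose effect status differs
#' between the screens — e.g. the MAPK feedback-loop members, whose removal
#' re-wires the output only under the cyclic hierarchy.
#'
#' @param a,b \code{knockout_screen}s over the same node set, each with a
#'   single hierarchy.
#' @return data.frame with columns \code{node}, \code{category_a},
#'   \code{category_b}, \code{effect_a}, \code{effect_b}, one row per node
#'   whose effect differs; zero rows when the screens agree everywhere.
#' @export
compare_hierarchy_screens <- function(a, b) {
  a <- a[a$node != "(none)", ]
  b <- b[b$node != "(none)", ]
  if (!setequal(a$node, b$node))
    stop("screens cover different node sets", call. = FALSE)
  b <- b[match(a$node, b$node), ]
  diff <- a$effect != b$effect
  out <- data.frame(node = a$node,
                    category_a = a$category, category_b = b$category,
                    effect_a = a$effect, effect_b = b$effect)[diff, ]
  rownames(out) <- NULL
  out
}

#' Nodes with no directed path to a target node
#'
#' Uses the signed edge list to find regulators from which the target is
#' unreachable. Knocking out such a node can never change the target's
#' dynamics, which is the reachability guard property-tested on random
#' networks.
#'
#' @param net a [boolean_network()].
#' @param target node name.
#' @return character vector of nodes (excluding \code{target}) with no
#'   directed path to \code{target}.
#' @export
unreachable_nodes <- function(net, target) {
  edges <- network_edges(net)
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     vertices = net$nodes$name)
  reach <- igraph::subcomponent(g, target, mode = "in")
  setdiff(net$nodes$name, c(names(reach), target))
}

#' Export a knockout screen as CSV
#'
#' @param screen a \code{knockout_screen}.
#' @param file path of the CSV to write.
#' @return \code{file}, invisibly.
#' @export
export_screen_csv <- function(screen, file) {
  utils::write.csv(as.data.frame(screen), file, row.names = FALSE)
  invisible(file)
}
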