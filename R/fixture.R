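#' The transcribed RCP/alpha5beta1/EGFR1 leading-edge network
#'
#' Loads the 41-node Boolean model of EGFR1 signalling at the front of an
#' invasively migrating cell: one clamped input (EGF, sustained
#' stimulation), the two output GTPases Rac1 and RhoA, and 38
#' intermediates, including the Sos1/Ras/Raf1/MEK1\\/2/ERK1\\/2/p90RSK
#' negative feedback loop onto Sos1 and the Akt-dependent pRacGAP1 brake on
#' Rac1. Basal activity (PDK1, mTor, c-Src, Pip2 and Rac1 ON) matches the
#' assumed pre-stimulation state; the input-less inhibitory phosphatases
#' PTEN, SHIP2 and PP2a are constitutive and default OFF.
#'
#' The Rac1 update rule is compiled from \code{hierarchy} with
#' [compile_rac1_rule()], with the direct RhoA-to-Rac1 antagonism edge
#' guarded together with the inhibitor (so an activator placed above
#' pRacGAP1 also overrides RhoA's antagonism).
#'
#' @param hierarchy a [hierarchy_spec()]; the default is the
#'   experimentally supported Sos1E > pRacGAP1 > Vav2, RalBP1 ordering.
#' @return a validated [boolean_network()] with the requested hierarchy.
#' @export
#' @examples
#' net <- rcp_network()
#' table(net$nodes$kind)
rcp_network <- function(hierarchy = hierarchy_spec("Sos1E")) {
  stopifnot(inherits(hierarchy, "hierarchy_spec"))
  path <- system.file("extdata", "rcp_egfr_network.txt",
                      package = "rhoswitch", mustWork = TRUE)
  net <- parse_network(path)
  rule <- compile_rac1_rule(hierarchy = hierarchy, extra_guard = "RhoA")
  net$rules[["Rac1"]] <- rule$expression
  net$hierarchy <- hierarchy
  net$metadata <- paste0("RCP/a5b1/EGFR1 leading-edge network; hierarchy ",
                         format_hierarchy(hierarchy))
  validate_network(net)
}

#' Census of a network's node kinds
#'
#' @param net a [boolean_network()].
#' @return named integer vector with counts of \code{input}, \code{output},
#'   \code{intermediate} and \code{total} nodes.
#' @export
node_census <- function(net) {
  k <- table(factor(net$nodes$kind, c("input", "output", "intermediate")))
  c(input = unname(k[["input"]]), output = unname(k[["output"]]),
    intermediate = unname(k[["intermediate"]]), total = nrow(net$nodes))
}
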