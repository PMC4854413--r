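#' Regulator precedence hierarchy for the Rac1 rule
#'
#' A GEF and a GAP cannot engage a GTPase in the same spatiotemporal state,
#' so when several Rac1 regulators are simultaneously active the one with
#' the higher binding precedence wins. The model has three Rac1 activators
#' (Vav2, RalBP1 and Sos1E, the Sos1-Eps8-Abi1 complex) and a single
#' inhibitor (pRacGAP1). A hierarchy places each activator either strictly
#' above the inhibitor (it engages Rac1 regardless of the inhibitor) or
#' strictly below it (it only acts while the inhibitor is OFF). Activators
#' on the same side are unordered among themselves, which is what makes
#' exactly eight distinct hierarchies (see [enumerate_hierarchies()]).
#'
#' @param above character vector of activators ranked above the inhibitor
#'   (possibly empty).
#' @param activators all activator names; defaults to the model's three.
#' @param inhibitor the single inhibitor name.
#' @return an object of class \code{hierarchy_spec} with fields
#'   \code{above}, \code{below}, \code{activators}, \code{inhibitor} and
#'   the canonical ordered \code{tiers}.
#' @export
#' @examples
#' hierarchy_spec("Sos1E")  # Sos1E > pRacGAP1 > Vav2, RalBP1
hierarchy_spec <- function(above = character(0),
                           activators = c("Vav2", "RalBP1", "Sos1E"),
                           inhibitor = "pRacGAP1") {
  above <- as.character(above)
  if (inhibitor %in% above)
    stop("a tier must not mix the inhibitor with an activator",
         call. = FALSE)
  unknown <- setdiff(above, activators)
  if (length(unknown))
    stop("not a declared activator: ", unknown[1], call. = FALSE)
  above <- sort(unique(above))
  below <- sort(setdiff(activators, above))
  tiers <- Filter(length, list(above, inhibitor, below))
  structure(list(above = above, below = below,
                 activators = sort(activators), inhibitor = inhibitor,
                 tiers = tiers),
            class = "hierarchy_spec")
}

#' @export
print.hierarchy_spec <- function(x, ...) {
  cat("<hierarchy_spec>", format_hierarchy(x), "\n")
  invisible(x)
}

#' Render a hierarchy as its tier notation
#' @param h a [hierarchy_spec()].
#' @return string such as \code{"Sos1E > pRacGAP1 > RalBP1, Vav2"}.
#' @export
format_hierarchy <- function(h) {
  paste(vapply(h$tiers, paste, "", collapse = ", "), collapse = " > ")
}

#' Parse tier notation into a hierarchy
#'
#' Accepts the \code{">"}-separated tier notation produced by
#' [format_hierarchy()]. Exactly one tier must hold the inhibitor alone.
#'
#' @param text e.g. \code{"Sos1E > pRacGAP1 > Vav2, RalBP1"}.
#' @param activators,inhibitor as in [hierarchy_spec()].
#' @return a [hierarchy_spec()].
#' @export
parse_hierarchy <- function(text, activators = c("Vav2", "RalBP1", "Sos1E"),
                            inhibitor = "pRacGAP1") {
  tiers <- lapply(strsplit(text, ">", fixed = TRUE)[[1]], function(t)
    trimws(strsplit(t, ",", fixed = TRUE)[[1]]))
  tiers <- lapply(tiers, function(t) t[nzchar(t)])
  has_inh <- vapply(tiers, function(t) inhibitor %in% t, NA)
  if (sum(has_inh) != 1L)
    stop("hierarchy must contain the inhibitor '", inhibitor,
         "' in exactly one tier", call. = FALSE)
  k <- which(has_inh)
  if (length(tiers[[k]]) > 1L)
    stop("a tier must not mix the inhibitor with an activator",
         call. = FALSE)
  members <- unlist(tiers[-k])
  if (!setequal(members, activators))
    stop("hierarchy tiers must cover exactly the activators: ",
         paste(activators, collapse = ", "), call. = FALSE)
  above <- unlist(tiers[seq_len(k - 1L)])
  hierarchy_spec(above, activators = activators, inhibitor = inhibitor)
}

#' Enumerate all distinct regulator hierarchies
#'
#' With a single inhibitor and unordered activators on either side of it,
#' a hierarchy is determined by the subset of activators placed above the
#' inhibitor; the three activators thus give the \eqn{2^3 = 8} canonical
#' hierarchies.
#'
#' @inheritParams hierarchy_spec
#' @return list of eight [hierarchy_spec()] objects, from the empty
#'   top tier (inhibitor-dominant) to all activators above.
#' @export
enumerate_hierarchies <- function(activators = c("Vav2", "RalBP1", "Sos1E"),
                                  inhibitor = "pRacGAP1") {
  n <- length(activators)
  out <- list()
  for (size in 0:n) {
    sets <- utils::combn(sort(activators), size, simplify = FALSE)
    for (s in sets)
      out[[length(out) + 1L]] <- hierarchy_spec(
        s, activators = activators, inhibitor = inhibitor)
  }
  out
}

#' Compile the Rac1 update rule from a hierarchy
#'
#' Encodes the precedence semantics: an activator ranked above the inhibitor
#' switches Rac1 on unconditionally; an activator ranked below only acts
#' while every inhibitor above it is OFF; and a self-maintenance literal
#' keeps basally active Rac1 on until an inhibitor fires. Formally
#' \deqn{Rac1' = \bigvee_A \big[A \wedge \neg(\textstyle\bigvee
#'   I_{>A})\big] \;\vee\; \big[Rac1 \wedge \neg I\big]}
#' where \eqn{I_{>A}} are the inhibitors strictly above activator \eqn{A}.
#' \code{extra_guard} names nodes treated as inhibitors at the inhibitor's
#' own tier (used for the direct RhoA antagonism edge of the transcribed
#' network).
#'
#' @param activators activator node names.
#' @param inhibitor the single inhibitor node name.
#' @param hierarchy a [hierarchy_spec()] over these regulators.
#' @param extra_guard further node names OR-ed into the inhibitor guard.
#' @param self the GTPase's own name for the self-maintenance literal.
#' @return list with \code{target} (\code{self}) and \code{expression}
#'   (an R call), i.e. an update rule.
#' @export
#' @examples
#' r <- compile_rac1_rule(hierarchy = hierarchy_spec("Sos1E"))
#' deparse_bool_expr(r$expression)
compile_rac1_rule <- function(activators = c("Vav2", "RalBP1", "Sos1E"),
                              inhibitor = "pRacGAP1",
                              hierarchy = hierarchy_spec(),
                              extra_guard = character(0),
                              self = "Rac1") {
  stopifnot(inherits(hierarchy, "hierarchy_spec"))
  if (!setequal(activators, hierarchy$activators) ||
      !identical(inhibitor, hierarchy$inhibitor))
    stop("hierarchy does not range over the given regulators", call. = FALSE)
  guard_names <- c(inhibitor, extra_guard)
  guard <- call("!", or_join(lapply(guard_names, as.name)))
  terms <- lapply(sort(activators), function(a) {
    if (a %in% hierarchy$above) as.name(a)
    else call("&", as.name(a), guard)
  })
  terms <- c(terms, list(call("&", as.name(self), guard)))
  list(target = self, expression = or_join(terms))
}

or_join <- function(terms) Reduce(function(x, y) call("|", x, y), terms)
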