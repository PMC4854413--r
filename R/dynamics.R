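# Simulation engine. All reactions take one time increment; a state vector
# assigns 0/1 to every node; clamped nodes (no rule) hold their value.

check_state <- function(net, state) {
  if (!setequal(names(state), net$nodes$name))
    stop("state must cover every node exactly once", call. = FALSE)
  if (!all(state %in% c(0L, 1L)))
    stop("state values must be 0 or 1", call. = FALSE)
  state[net$nodes$name]
}

state_env <- function(state) {
  e <- as.list(state == 1L)
  names(e) <- names(state)
  e
}

#' One synchronous update step
#'
#' Every ruled node recomputes from the current state simultaneously;
#' clamped nodes (the input, constitutive nodes, knocked-out nodes) keep
#' their value.
#'
#' @param net a [boolean_network()].
#' @param state named 0/1 vector over all nodes.
#' @return the successor state, in the network's node order.
#' @export
step_synchronous <- function(net, state) {
  state <- check_state(net, state)
  env <- state_env(state)
  nxt <- state
  for (tg in names(net$rules))
    nxt[[tg]] <- as.integer(eval(net$rules[[tg]], env))
  nxt
}

new_trace <- function(mat, scheme, seed = NULL) {
  structure(mat, scheme = scheme, seed = seed, class = c("bn_trace", "matrix"))
}

#' Synchronous time-course simulation
#'
#' Deterministic trajectory of \code{T} increments from the network's
#' declared initial condition (or \code{state}).
#'
#' @param net a [boolean_network()].
#' @param T number of increments (columns \code{t = 0..T} are returned).
#' @param state optional starting state; defaults to [initial_state()].
#' @return a \code{bn_trace}: integer matrix, rows = nodes in declaration
#'   order, columns = increments \code{0..T}, with attribute
#'   \code{scheme = "synchronous"}.
#' @export
#' @examples
#' tr <- simulate_synchronous(rcp_network(), 50)
#' tr[c("Rac1", "RhoA"), 1:10]
simulate_synchronous <- function(net, T, state = initial_state(net)) {
  stopifnot(T >= 1)
  state <- check_state(net, state)
  tr <- matrix(NA_integer_, nrow = length(state), ncol = T + 1,
               dimnames = list(names(state), 0:T))
  tr[, 1] <- state
  for (t in seq_len(T)) {
    state <- step_synchronous(net, state)
    tr[, t + 1] <- state
  }
  new_trace(tr, "synchronous")
}

#' Random-asynchronous time-course simulation
#'
#' At each increment the set of unstable nodes (rule value differing from
#' the current value) is computed and at most one of them, drawn uniformly
#' with the seeded generator, is updated; when no node is unstable the
#' state carries over. Identical \code{(net, T, seed)} give bit-identical
#' traces; the caller's RNG state is left untouched.
#'
#' @inheritParams simulate_synchronous
#' @param seed integer seed for the update order.
#' @return a \code{bn_trace} with attributes \code{scheme =
#'   "asynchronous"} and \code{seed}.
#' @export
simulate_asynchronous <- function(net, T, seed, state = initial_state(net)) {
  stopifnot(T >= 1)
  state <- check_state(net, state)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  tr <- matrix(NA_integer_, nrow = length(state), ncol = T + 1,
               dimnames = list(names(state), 0:T))
  tr[, 1] <- state
  for (t in seq_len(T)) {
    env <- state_env(state)
    unstable <- character(0)
    vals <- integer(0)
    for (tg in names(net$rules)) {
      v <- as.integer(eval(net$rules[[tg]], env))
      if (v != state[[tg]]) {
        unstable <- c(unstable, tg)
        vals <- c(vals, v)
      }
    }
    if (length(unstable)) {
      k <- if (length(unstable) == 1L) 1L else sample.int(length(unstable), 1L)
      state[[unstable[k]]] <- vals[k]
    }
    tr[, t + 1] <- state
  }
  new_trace(tr, "asynchronous", seed = seed)
}

#' Attractor of the synchronous dynamics
#'
#' Follows the deterministic orbit from the initial condition until a state
#' repeats (guaranteed within \eqn{2^N} steps) and reports the transient
#' length, the cycle, and for each node its dynamic class over the cycle:
#' \code{stable_active} (ON throughout), \code{stable_inactive} (OFF
#' throughout) or \code{cyclic} (ON fraction strictly between 0 and 1).
#'
#' @inheritParams simulate_synchronous
#' @param max_steps safety bound on the orbit length.
#' @return an \code{attractor_report}: list with \code{transient}
#'   (increments before the cycle is entered), \code{cycle} (matrix of
#'   cycle states, one column per state), \code{period}, \code{node_class}
#'   and \code{on_fraction} (named vectors over nodes).
#' @export
find_attractor <- function(net, state = initial_state(net),
                           max_steps = 2^20) {
  state <- check_state(net, state)
  seen <- new.env(parent = emptyenv())
  states <- list()
  t <- 0L
  repeat {
    key <- paste(state, collapse = "")
    hit <- seen[[key]]
    if (!is.null(hit)) {
      cyc <- do.call(cbind, states[(hit + 1L):t])
      rownames(cyc) <- names(state)
      colnames(cyc) <- NULL
      onf <- rowMeans(cyc)
      cls <- ifelse(onf == 1, "stable_active",
                    ifelse(onf == 0, "stable_inactive", "cyclic"))
      return(structure(list(transient = hit, cycle = cyc,
                            period = ncol(cyc),
                            node_class = stats::setNames(cls, names(state)),
                            on_fraction = onf),
                       class = "attractor_report"))
    }
    seen[[key]] <- t
    states[[t + 1L]] <- state
    state <- step_synchronous(net, state)
    t <- t + 1L
    if (t > max_steps) stop("no attractor within max_steps", call. = FALSE)
  }
}

#' @export
print.attractor_report <- function(x, ...) {
  cat(sprintf("<attractor_report> transient %d, period %d\n",
              x$transient, x$period))
  cyc <- names(which(x$node_class == "cyclic"))
  cat("  cyclic nodes:", if (length(cyc)) paste(cyc, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Classify the Rac1/RhoA output dynamics of an attractor
#'
#' Maps an attractor to the output taxonomy: \code{rac_persistent} (Rac1
#' stably ON, RhoA stably OFF), \code{switch} (Rac1 stably OFF, RhoA stably
#' ON), \code{cyclic} (both outputs cycling), or \code{other} for any
#' remaining combination (reachable only under perturbations). For cyclic
#' attractors, \code{rhoa_dominant} records whether RhoA's ON fraction over
#' the cycle strictly exceeds Rac1's.
#'
#' @param report an [find_attractor()] result containing both outputs.
#' @param outputs names of the two output nodes.
#' @return list with \code{category}, \code{rhoa_dominant} (NA unless
#'   cyclic), \code{rac1_class}, \code{rhoa_class} and the two ON
#'   fractions.
#' @export
classify_hierarchy_output <- function(report,
                                      outputs = c("Rac1", "RhoA")) {
  missing <- setdiff(outputs, names(report$node_class))
  if (length(missing))
    stop("attractor report lacks output node: ", missing[1], call. = FALSE)
  rc <- report$node_class[[outputs[1]]]
  hc <- report$node_class[[outputs[2]]]
  category <- if (rc == "stable_active" && hc == "stable_inactive")
    "rac_persistent"
  else if (rc == "stable_inactive" && hc == "stable_active") "switch"
  else if (rc == "cyclic" && hc == "cyclic") "cyclic"
  else "other"
  onf <- report$on_fraction
  list(category = category,
       rhoa_dominant = if (category == "cyclic")
         onf[[outputs[2]]] > onf[[outputs[1]]] else NA,
       rac1_class = rc, rhoa_class = hc,
       rac1_on_fraction = onf[[outputs[1]]],
       rhoa_on_fraction = onf[[outputs[2]]])
}

#' First increment at which a node switches value
#'
#' @param trace a \code{bn_trace}.
#' @param node node name.
#' @param from,to the transition looked for (default OFF to ON).
#' @return the increment (column label) of the first \code{from -> to}
#'   transition, or NA if it never occurs.
#' @export
first_switch <- function(trace, node, from = 0L, to = 1L) {
  x <- trace[node, ]
  w <- which(x[-length(x)] == from & x[-1] == to)
  if (!length(w)) return(NA_integer_)
  as.integer(colnames(trace)[w[1] + 1L])
}

#' Output ON-times after the Rac1-to-RhoA switch
#'
#' Locates the first increment at which Rac1 is OFF while RhoA is ON and
#' counts, for each output, the ON increments from the following increment
#' to the end of the trace. Used to summarise asynchronous robustness runs.
#'
#' @param trace a \code{bn_trace} containing both outputs.
#' @param outputs names of the two output nodes.
#' @return list with \code{switched} (logical), \code{switch_time},
#'   \code{rac_on} and \code{rhoa_on} (increments; NA when the switch never
#'   occurs).
#' @export
on_time_after_switch <- function(trace, outputs = c("Rac1", "RhoA")) {
  missing <- setdiff(outputs, rownames(trace))
  if (length(missing))
    stop("trace lacks output node: ", missing[1], call. = FALSE)
  rac <- trace[outputs[1], ]
  rho <- trace[outputs[2], ]
  w <- which(rac == 0L & rho == 1L)
  if (!length(w))
    return(list(switched = FALSE, switch_time = NA_integer_,
                rac_on = NA_integer_, rhoa_on = NA_integer_))
  k <- w[1]
  idx <- if (k < length(rac)) (k + 1L):length(rac) else integer(0)
  list(switched = TRUE,
       switch_time = as.integer(colnames(trace)[k]),
       rac_on = as.integer(sum(rac[idx])),
       rhoa_on = as.integer(sum(rho[idx])))
}

# ---- exports -----------------------------------------------------------

#' Export a trace as TSV (heatmap layout)
#'
#' Rows are nodes in declaration order, columns are increments 0..T, cells
#' are 0/1 — the layout of the published binary heatmaps.
#'
#' @param trace a \code{bn_trace}.
#' @param file path of the TSV to write.
#' @return \code{file}, invisibly.
#' @export
export_trace_tsv <- function(trace, file) {
  df <- data.frame(node = rownames(trace), unclass(trace)[, , drop = FALSE],
                   check.names = FALSE)
  colnames(df) <- c("node", colnames(trace))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Export an attractor report as JSON
#'
#' @param report an \code{attractor_report}.
#' @param file path of the JSON to write.
#' @return \code{file}, invisibly.
#' @export
export_attractor_json <- function(report, file) {
  obj <- list(transient = report$transient, period = report$period,
              node_class = as.list(report$node_class),
              on_fraction = as.list(report$on_fraction))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
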