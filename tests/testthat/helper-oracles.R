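# Independent oracles used against the implementation.

# Exhaustive synchronous attractor by full 2^N transition-graph
# enumeration. States are encoded as integers with bit i-1 = node i (in
# declaration order); rules are evaluated once, vectorised over all
# states, which shares no code path with the stepwise simulator.
oracle_transition_table <- function(net) {
  nodes <- net$nodes$name
  N <- length(nodes)
  idx <- 0:(2^N - 1)
  bits <- lapply(seq_len(N), function(i) bitwAnd(idx, 2^(i - 1)) > 0L)
  names(bits) <- nodes
  nxt <- bits
  for (tg in nodes) {
    if (!is.null(net$rules[[tg]])) nxt[[tg]] <- eval(net$rules[[tg]], bits)
  }
  enc <- numeric(2^N)
  for (i in seq_len(N)) enc <- enc + as.numeric(nxt[[nodes[i]]]) * 2^(i - 1)
  as.integer(enc)
}

encode_state <- function(state) {
  sum(as.numeric(state) * 2^(seq_along(state) - 1))
}

oracle_attractor <- function(net, state = initial_state(net)) {
  trans <- oracle_transition_table(net)
  cur <- as.integer(encode_state(state))
  seen <- integer(0)          # visit time (1-based) keyed by state string
  names_seen <- character(0)
  t <- 0L
  repeat {
    key <- as.character(cur)
    hit <- match(key, names_seen)
    if (!is.na(hit)) {
      return(list(transient = hit - 1L,
                  cycle = seen[hit:length(seen)],
                  period = length(seen) - hit + 1L))
    }
    names_seen <- c(names_seen, key)
    seen <- c(seen, cur)
    cur <- trans[cur + 1L]
    t <- t + 1L
  }
}

encode_columns <- function(cycle_matrix) {
  apply(cycle_matrix, 2, function(col) encode_state(col))
}

# Brute-force 2-D convolution with mirror (reflect-101) boundary.
conv2_mirror <- function(img, ker) {
  ny <- nrow(img); nx <- ncol(img)
  ky <- (nrow(ker) - 1) / 2; kx <- (ncol(ker) - 1) / 2
  refl <- function(p, n) ifelse(p < 1, 2 - p, ifelse(p > n, 2 * n - p, p))
  out <- matrix(0, ny, nx)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    acc <- 0
    for (a in -ky:ky) for (b in -kx:kx) {
      acc <- acc + ker[a + ky + 1, b + kx + 1] *
        img[refl(i + a, ny), refl(j + b, nx)]
    }
    out[i, j] <- acc
  }
  out
}

# Dilated separable (1,2,1)/4 smoothing kernel as a dense 2-D matrix.
dilated_kernel <- function(step) {
  k1 <- numeric(2 * step + 1)
  k1[c(1, step + 1, 2 * step + 1)] <- c(1, 2, 1) / 4
  outer(k1, k1)
}

# Minimal crescent ROI for direct leading_edge_ratio calls.
fake_roi <- function(front, back = matrix(0L, nrow(front), ncol(front))) {
  structure(list(ring = front | back, front = front, back = back,
                 axis = "x", bbox = NULL, selected = "high"),
            class = "crescent_roi")
}

two_node_chain <- function() {
  parse_network(c("EGF, <input>", "EGFR1, EGF"))
}
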