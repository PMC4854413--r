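# Seed-deterministic generators standing in for the study's raw data:
# random logical networks for property tests of the simulation machinery,
# and two-channel biosensor image stacks with known ground truth for the
# image pipeline.

with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a random Boolean network
#'
#' Each node receives a rule that is an OR of 1--3 conjunctions over
#' regulators drawn independently with probability \code{edge_density};
#' each literal is negated with probability
#' \code{1 / (1 + act_inh_ratio)}. Nodes with no drawn regulator fall back
#' to a self-literal. Initial states are drawn uniformly. The topology and
#' states are reproducible per seed.
#'
#' @param n_nodes number of nodes (>= 1).
#' @param edge_density probability of each potential regulator, in (0, 1].
#' @param act_inh_ratio activator:inhibitor literal ratio.
#' @param seed integer seed.
#' @return a validated [boolean_network()] with nodes \code{n1..nN}.
#' @export
gen_random_network <- function(n_nodes, edge_density = 0.25,
                               act_inh_ratio = 3, seed = 1) {
  stopifnot(n_nodes >= 1, edge_density > 0, edge_density <= 1)
  with_seed(seed, {
    names_ <- paste0("n", seq_len(n_nodes))
    p_neg <- 1 / (1 + act_inh_ratio)
    rules <- list()
    for (nd in names_) {
      regs <- names_[stats::runif(n_nodes) < edge_density]
      if (!length(regs)) regs <- nd
      k <- sample.int(min(3L, length(regs)), 1L)
      groups <- split(regs, sort(rep_len(seq_len(k), length(regs))))
      conj <- lapply(groups, function(g) {
        lits <- lapply(g, function(v) {
          lit <- as.name(v)
          if (stats::runif(1) < p_neg) call("!", lit) else lit
        })
        Reduce(function(x, y) call("&", x, y), lits)
      })
      rules[[nd]] <- or_join(unname(conj))
    }
    nodes <- data.frame(name = names_, kind = "intermediate",
                        initial = sample(0:1, n_nodes, replace = TRUE),
                        constitutive = FALSE, clamped = FALSE)
    boolean_network(nodes, rules,
                    metadata = sprintf("random network (seed %d)", seed))
  })
}

#' Parameters for a synthetic biosensor cell stack
#'
#' Describes a rigidly translating elliptical "cell" on a dark background:
#' the bright masking channel is flat inside the ellipse, the donor channel
#' has a constant base level, and the FRET channel encodes a prescribed
#' front/back ratio split along the long axis. Noise, when enabled, is
#' Poisson-like shot noise (variance \code{noise} times the signal) plus
#' Gaussian read noise.
#'
#' @param size image size \code{c(ny, nx)}; must fit the largest wavelet
#'   kernel used downstream (>= 257 px for scales up to 8).
#' @param frames number of timepoints.
#' @param center0 ellipse centre \code{c(y, x)} at the first frame.
#' @param axes semi-axes \code{c(along_x, along_y)} in pixels.
#' @param theta orientation of the first axis, radians anticlockwise.
#' @param velocity per-frame translation \code{c(dy, dx)}.
#' @param front_ratio,back_ratio true FRET ratio in the front/back half
#'   (the front is the positive end of the first axis).
#' @param donor_level donor channel grey level inside the cell.
#' @param acceptor_level masking channel grey level inside the cell; must
#'   clear the segmentation threshold after band-passing.
#' @param noise shot-noise variance factor (0 = noiseless, exact values).
#' @param read_noise Gaussian read-noise standard deviation.
#' @param channel_shift known misalignment \code{c(dy, dx)} planted on the
#'   non-reference channels (recovered by [register_channels()]).
#' @param seed integer seed.
#' @return a named list of class \code{synthetic_cell_params}.
#' @export
synthetic_cell_params <- function(size = c(288, 288), frames = 5,
                                  center0 = c(144, 120), axes = c(70, 52),
                                  theta = 0, velocity = c(0, 2),
                                  front_ratio = 1.8, back_ratio = 1.1,
                                  donor_level = 1000,
                                  acceptor_level = 8000,
                                  noise = 0, read_noise = 2 * sqrt(noise),
                                  channel_shift = c(0, 0), seed = 1) {
  p <- list(size = size, frames = frames, center0 = center0, axes = axes,
            theta = theta, velocity = velocity, front_ratio = front_ratio,
            back_ratio = back_ratio, donor_level = donor_level,
            acceptor_level = acceptor_level, noise = noise,
            read_noise = read_noise, channel_shift = channel_shift,
            seed = seed)
  stopifnot(p$front_ratio > 0, p$back_ratio > 0, p$frames >= 1)
  class(p) <- "synthetic_cell_params"
  p
}

#' Generate a synthetic FRET stack with ground truth
#'
#' Renders the moving ellipse described by \code{params} into the three
#' biosensor channels, plants the configured channel misalignment and
#' noise, and returns the stack together with the exact ground truth
#' (per-frame mask and centre, true ratios, planted shift) for parameter
#' recovery tests.
#'
#' @param params a [synthetic_cell_params()].
#' @return list with \code{stack} (a [fret_stack()]) and \code{truth}
#'   (list: \code{masks}, \code{centers} (frame x (y, x)),
#'   \code{front_ratio}, \code{back_ratio}, \code{front} direction,
#'   \code{channel_shift}).
#' @export
gen_fret_stack <- function(params = synthetic_cell_params()) {
  stopifnot(inherits(params, "synthetic_cell_params"))
  p <- params
  ny <- p$size[1]; nx <- p$size[2]
  donor <- array(0, c(ny, nx, p$frames))
  fret <- array(0, c(ny, nx, p$frames))
  acc <- array(0, c(ny, nx, p$frames))
  masks <- vector("list", p$frames)
  centers <- matrix(NA_real_, p$frames, 2,
                    dimnames = list(NULL, c("y", "x")))
  xg <- matrix(rep(seq_len(nx), each = ny), ny)
  yg <- matrix(rep(seq_len(ny), nx), ny)
  for (t in seq_len(p$frames)) {
    cy <- p$center0[1] + (t - 1) * p$velocity[1]
    cx <- p$center0[2] + (t - 1) * p$velocity[2]
    centers[t, ] <- c(cy, cx)
    u <- (xg - cx) * cos(p$theta) + (yg - cy) * sin(p$theta)
    v <- -(xg - cx) * sin(p$theta) + (yg - cy) * cos(p$theta)
    if (cx - p$axes[1] < 1 || cx + p$axes[1] > nx ||
        cy - p$axes[2] < 1 || cy + p$axes[2] > ny)
      stop("ellipse leaves the frame at frame ", t, call. = FALSE)
    inside <- (u / p$axes[1])^2 + (v / p$axes[2])^2 <= 1
    ratio_map <- ifelse(u > 0, p$front_ratio, p$back_ratio)
    masks[[t]] <- inside * 1L
    donor[, , t] <- ifelse(inside, p$donor_level, 0)
    fret[, , t] <- ifelse(inside, p$donor_level * ratio_map, 0)
    acc[, , t] <- ifelse(inside, p$acceptor_level, 0)
  }
  if (p$noise > 0) {
    with_seed(p$seed, {
      shot <- function(x) {
        lam <- x / p$noise
        out <- x
        pos <- lam > 0
        out[pos] <- stats::rpois(sum(pos), lam[pos]) * p$noise
        out + stats::rnorm(length(x), 0, p$read_noise)
      }
      donor[] <- pmax(shot(donor), 0)
      fret[] <- pmax(shot(fret), 0)
      acc[] <- pmax(shot(acc), 0)
    })
  }
  if (any(p$channel_shift != 0)) {
    for (t in seq_len(p$frames)) {
      fret[, , t] <- fourier_shift(fret[, , t], p$channel_shift[1],
                                   p$channel_shift[2])
      acc[, , t] <- fourier_shift(acc[, , t], p$channel_shift[1],
                                  p$channel_shift[2])
    }
  }
  list(stack = fret_stack(donor, fret, acc),
       truth = list(masks = masks, centers = centers,
                    front_ratio = p$front_ratio,
                    back_ratio = p$back_ratio,
                    front = if (cos(p$theta) >= 0) "right" else "left",
                    channel_shift = p$channel_shift))
}

#' Write the ground truth of a synthetic stack as JSON
#'
#' @param truth the \code{truth} element of a [gen_fret_stack()] result.
#' @param file path of the JSON sidecar to write.
#' @return \code{file}, invisibly.
#' @export
export_truth_json <- function(truth, file) {
  obj <- truth
  obj$masks <- NULL  # masks are bulky; centres and ratios suffice
  obj$centers <- as.data.frame(truth$centers)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
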