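# Semi-automated leading-edge ratiometric FRET quantification:
# channel registration -> wavelet band-pass -> threshold/largest-object
# segmentation -> ring & crescent ROIs -> mean front-crescent ratio.

#' Construct a three-channel FRET image stack
#'
#' Channels follow ratiometric biosensor imaging: \code{donor_donor}
#' (donor excitation / donor emission, the ratio denominator), \code{fret}
#' (donor excitation / acceptor emission, the numerator) and
#' \code{acceptor_direct} (acceptor excitation / acceptor emission, the
#' bright channel used for masking). Each channel is a \code{ny x nx x T}
#' numeric array; matrices are promoted to single-frame stacks.
#'
#' @param donor_donor,fret,acceptor_direct numeric arrays of identical
#'   dimensions.
#' @return an object of class \code{fret_stack}.
#' @export
fret_stack <- function(donor_donor, fret, acceptor_direct) {
  as3d <- function(x) {
    if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
    stopifnot(length(dim(x)) == 3L)
    x
  }
  chans <- list(donor_donor = as3d(donor_donor), fret = as3d(fret),
                acceptor_direct = as3d(acceptor_direct))
  dims <- lapply(chans, dim)
  if (!all(vapply(dims, identical, NA, dims[[1]])))
    stop("all channels must share dimensions", call. = FALSE)
  if (dims[[1]][3] < 1L) stop("stack needs at least one frame", call. = FALSE)
  structure(chans, class = "fret_stack")
}

#' @export
print.fret_stack <- function(x, ...) {
  d <- dim(x$donor_donor)
  cat(sprintf("<fret_stack> %d x %d px, %d frame(s), 3 channels\n",
              d[1], d[2], d[3]))
  invisible(x)
}

n_frames <- function(stack) dim(stack$donor_donor)[3]

#' Read a three-channel stack from multi-page TIFF files
#'
#' @param donor_donor,fret,acceptor_direct paths to multi-page TIFFs, one
#'   per channel, frames in acquisition order.
#' @param scale multiply pixel values by this factor; \code{tiff::readTIFF}
#'   returns data scaled to \code{[0, 1]}, so the default recovers 16-bit
#'   grey levels.
#' @return a [fret_stack()].
#' @export
read_fret_stack <- function(donor_donor, fret, acceptor_direct,
                            scale = 65535) {
  rd <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
    for (i in seq_along(pages)) arr[, , i] <- pages[[i]][, , drop = TRUE]
    arr * scale
  }
  fret_stack(rd(donor_donor), rd(fret), rd(acceptor_direct))
}

#' Write a stack as one multi-page TIFF per channel
#'
#' @param stack a [fret_stack()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param scale divide pixel values by this factor before writing (inverse
#'   of the [read_fret_stack()] scaling).
#' @return named character vector of the three paths, invisibly.
#' @export
write_fret_stack <- function(stack, dir, prefix = "stack", scale = 65535) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  for (ch in names(stack)) {
    path <- file.path(dir, paste0(prefix, "_", ch, ".tif"))
    frames <- lapply(seq_len(n_frames(stack)), function(t)
      pmin(pmax(stack[[ch]][, , t] / scale, 0), 1))
    tiff::writeTIFF(frames, path, bits.per.sample = 16L)
    out[[ch]] <- path
  }
  invisible(out)
}

# ---- subpixel registration ---------------------------------------------

#' Estimate a subpixel translation by upsampled cross-correlation
#'
#' Single-step DFT registration: the integer-pixel peak of the
#' cross-correlation is located first, then refined by evaluating the
#' cross-correlation on an \code{1/upsample}-pixel grid around it with a
#' matrix-multiply DFT. With the default \code{upsample = 100} the shift is
#' resolved to a hundredth of a pixel.
#'
#' @param ref,img numeric matrices of identical size; \code{img} is modelled
#'   as \code{ref} translated by the returned \code{(dy, dx)}.
#' @param upsample upsampling factor (1 = integer-pixel only).
#' @return list with \code{dy}, \code{dx} (pixels; applying
#'   [fourier_shift()] with \code{-dy, -dx} to \code{img} aligns it onto
#'   \code{ref}), \code{confidence} (normalised correlation peak in
#'   \code{[0, 1]}) and \code{degenerate} (TRUE when either image is
#'   constant, in which case a zero shift is returned with a warning).
#' @export
estimate_shift <- function(ref, img, upsample = 100) {
  stopifnot(is.matrix(ref), is.matrix(img), all(dim(ref) == dim(img)))
  if (stats::sd(ref) == 0 || stats::sd(img) == 0) {
    warning("constant image: returning zero shift")
    return(list(dy = 0, dx = 0, confidence = 0, degenerate = TRUE))
  }
  ny <- nrow(ref); nx <- ncol(ref)
  F1 <- stats::fft(ref - mean(ref))
  F2 <- stats::fft(img - mean(img))
  R <- F2 * Conj(F1)
  cc <- stats::fft(R, inverse = TRUE)
  acc <- Mod(cc)
  peak <- arrayInd(which.max(acc), dim(acc))
  dy <- peak[1] - 1L; dx <- peak[2] - 1L
  if (dy > ny / 2) dy <- dy - ny
  if (dx > nx / 2) dx <- dx - nx
  # Cauchy-Schwarz bound: 1 for a pure translation, ~0 for independent noise
  conf <- max(acc) / sqrt(sum(Mod(F1)^2) * sum(Mod(F2)^2))
  if (upsample > 1) {
    # refine in a 1.5-px neighbourhood of the coarse peak
    us <- upsample
    nr <- ceiling(1.5 * us); nc <- nr
    roff <- floor(nr / 2) - dy * us
    coff <- floor(nc / 2) - dx * us
    ccu <- Mod(dftups(R, nr, nc, us, roff, coff))
    pk <- arrayInd(which.max(ccu), dim(ccu))
    dy <- (pk[1] - 1 - floor(nr / 2)) / us + dy
    dx <- (pk[2] - 1 - floor(nc / 2)) / us + dx
  }
  list(dy = dy, dx = dx, confidence = min(conf, 1), degenerate = FALSE)
}

# Upsampled DFT over a small output window by matrix multiplication.
# Equivalent to zero-padded-FFT upsampling of ifft(R), evaluated only on an
# nor x noc grid with offsets (roff, coff) in upsampled pixels.
dftups <- function(R, nor, noc, usfac, roff, coff) {
  ny <- nrow(R); nx <- ncol(R)
  fy <- c(0:floor((ny - 1) / 2), -(ceiling((ny - 1) / 2):1)) # fftfreq * ny
  fx <- c(0:floor((nx - 1) / 2), -(ceiling((nx - 1) / 2):1))
  kr <- exp(2i * pi / (ny * usfac) * outer((0:(nor - 1)) - roff, fy))
  kc <- exp(2i * pi / (nx * usfac) * outer(fx, (0:(noc - 1)) - coff))
  kr %*% R %*% kc
}

#' Translate an image by a (possibly fractional) shift in the Fourier domain
#'
#' Multiplies the spectrum by the corresponding phase ramp; circular
#' boundary conditions. Used both to resample registered channels and by
#' the synthetic generator to plant known misalignments.
#'
#' @param img numeric matrix.
#' @param dy,dx shift in pixels (positive = towards larger row/column).
#' @return numeric matrix.
#' @export
fourier_shift <- function(img, dy, dx) {
  ny <- nrow(img); nx <- ncol(img)
  fy <- c(0:floor((ny - 1) / 2), -(ceiling((ny - 1) / 2):1)) / ny
  fx <- c(0:floor((nx - 1) / 2), -(ceiling((nx - 1) / 2):1)) / nx
  phase <- exp(-2i * pi * (outer(fy * dy, rep(1, nx)) +
                           outer(rep(1, ny), fx * dx)))
  Re(stats::fft(stats::fft(img) * phase, inverse = TRUE)) / (ny * nx)
}

#' Register the channels of a stack to a hundredth of a pixel
#'
#' For each frame, estimates the translation of every non-reference channel
#' against the reference channel by upsampled cross-correlation
#' ([estimate_shift()]) and resamples the moving channels onto the
#' reference with a Fourier-domain translation.
#'
#' @param stack a [fret_stack()].
#' @param reference name of the fixed channel.
#' @param upsample upsampling factor; 100 resolves 0.01 px.
#' @param min_confidence shifts whose normalised correlation peak falls
#'   below this are flagged \code{low_confidence} (they are still applied).
#' @return the registered [fret_stack()], with a data.frame attribute
#'   \code{"shifts"} (frame, channel, dy, dx, confidence, low_confidence).
#' @export
register_channels <- function(stack, reference = "donor_donor",
                              upsample = 100, min_confidence = 0.3) {
  stopifnot(inherits(stack, "fret_stack"), reference %in% names(stack))
  moving <- setdiff(names(stack), reference)
  rows <- list()
  for (t in seq_len(n_frames(stack))) {
    ref <- stack[[reference]][, , t]
    for (ch in moving) {
      est <- estimate_shift(ref, stack[[ch]][, , t], upsample)
      stack[[ch]][, , t] <- fourier_shift(stack[[ch]][, , t],
                                          -est$dy, -est$dx)
      rows[[length(rows) + 1L]] <- data.frame(
        frame = t, channel = ch, dy = est$dy, dx = est$dx,
        confidence = est$confidence,
        low_confidence = est$degenerate || est$confidence < min_confidence)
    }
  }
  attr(stack, "shifts") <- do.call(rbind, rows)
  stack
}

# ---- a-trous wavelet band-pass -----------------------------------------

# One separable smoothing pass with the 3-tap kernel (1,2,1)/4 dilated by
# `step`, mirror boundary (reflection about the edge pixel).
atrous_smooth <- function(img, step) {
  mirror <- function(p, n) ifelse(p < 1L, 2L - p, ifelse(p > n, 2L * n - p, p))
  ny <- nrow(img); nx <- ncol(img)
  up <- img[mirror(seq_len(ny) - step, ny), , drop = FALSE]
  dn <- img[mirror(seq_len(ny) + step, ny), , drop = FALSE]
  img <- (up + 2 * img + dn) / 4
  lf <- img[, mirror(seq_len(nx) - step, nx), drop = FALSE]
  rt <- img[, mirror(seq_len(nx) + step, nx), drop = FALSE]
  (lf + 2 * img + rt) / 4
}

#' Undecimated (a-trous) wavelet decomposition
#'
#' Computes successive smoothings \eqn{c_j} of the image with the linear
#' 3-tap kernel \eqn{(1,2,1)/4}, dilated by \eqn{2^{j-1}} at scale \eqn{j},
#' and the detail planes \eqn{d_j = c_{j-1} - c_j}. The input is exactly
#' the sum of all detail planes plus the final smooth residual.
#'
#' @param img numeric matrix.
#' @param n_scales number of scales (the largest dilated kernel spans
#'   \eqn{2^{n\_scales} + 1} pixels and must fit in the image).
#' @return list with \code{details} (list of matrices, scales 1..J) and
#'   \code{residual} (matrix \eqn{c_J}).
#' @export
atrous_decompose <- function(img, n_scales = 8) {
  stopifnot(is.matrix(img), n_scales >= 1)
  max_support <- 2^n_scales + 1
  if (min(dim(img)) < max_support)
    stop("image smaller than the largest dilated kernel (",
         max_support, " px)", call. = FALSE)
  details <- vector("list", n_scales)
  c_prev <- img
  for (j in seq_len(n_scales)) {
    c_j <- atrous_smooth(c_prev, 2^(j - 1))
    details[[j]] <- c_prev - c_j
    c_prev <- c_j
  }
  list(details = details, residual = c_prev)
}

#' A-trous wavelet band-pass filter
#'
#' Sums the detail planes of the requested scales; keeping scales 2--8
#' (the default) removes single-pixel noise (scale 1) and stationary
#' background (the smooth residual), the preprocessing used before cell
#' segmentation.
#'
#' @param img numeric matrix.
#' @param keep_scales integer vector of scales to keep.
#' @return numeric matrix of the band-passed image.
#' @export
atrous_bandpass <- function(img, keep_scales = 2:8) {
  stopifnot(length(keep_scales) >= 1, all(keep_scales >= 1))
  dec <- atrous_decompose(img, max(keep_scales))
  Reduce(`+`, dec$details[keep_scales])
}

as_plain_matrix <- function(x) matrix(as.numeric(x), nrow = nrow(x))

# ---- segmentation ------------------------------------------------------

# 8-connected component labelling (frontier BFS). EBImage::bwlabel is
# 4-connected, and diagonal-touching pixels must merge here.
label8 <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  todo <- mask != 0
  cur <- 0L
  repeat {
    seedpos <- which(todo)
    if (!length(seedpos)) break
    cur <- cur + 1L
    frontier <- seedpos[1]
    todo[frontier] <- FALSE
    lab[frontier] <- cur
    while (length(frontier)) {
      r <- (frontier - 1L) %% ny + 1L
      cc <- (frontier - 1L) %/% ny + 1L
      nb <- c(frontier[r > 1L] - 1L,
              frontier[r < ny] + 1L,
              frontier[cc > 1L] - ny,
              frontier[cc < nx] + ny,
              frontier[r > 1L & cc > 1L] - ny - 1L,
              frontier[r < ny & cc > 1L] - ny + 1L,
              frontier[r > 1L & cc < nx] + ny - 1L,
              frontier[r < ny & cc < nx] + ny + 1L)
      nb <- unique(nb[todo[nb]])
      todo[nb] <- FALSE
      lab[nb] <- cur
      frontier <- nb
    }
  }
  lab
}

#' Segment the cell as the largest bright object
#'
#' Thresholds a (band-passed) image at a fixed grey value, labels the
#' result by 8-connected components and keeps only the largest object,
#' defining the binary cell mask.
#'
#' @param img numeric matrix, typically
#'   \code{atrous_bandpass(acceptor_direct_frame)}.
#' @param threshold fixed grey-value threshold (a pixel is foreground when
#'   strictly above it); the default presumes 16-bit acquisition.
#' @return binary (0/1) integer matrix of class \code{cell_mask}; errors
#'   when no pixel exceeds the threshold.
#' @export
segment_cell <- function(img, threshold = 2000) {
  fg <- img > threshold
  if (!any(fg))
    stop("empty mask: no pixel above threshold ", threshold, call. = FALSE)
  lab <- label8(fg)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  structure((lab == keep) * 1L, class = c("cell_mask", "matrix"))
}

# ---- ring and crescent ROIs --------------------------------------------

#' Ring mask and front/back crescents of a cell mask
#'
#' Erodes the mask with a disc of radius \code{width} and subtracts,
#' yielding a boundary ring of isotropic thickness \code{width}. The
#' axis-aligned minimum bounding box of the ring is divided into four
#' equal parts along its longer axis; the two extremal quarters intersected
#' with the ring give the front and back crescents. The front is chosen
#' from \code{front_hint} (an axis end \code{"left"}, \code{"right"},
#' \code{"top"}, \code{"bottom"}, or crescent index 1/2 counting from the
#' low coordinate end) or, for later frames, as the crescent overlapping
#' the previous frame's front crescent most (\code{prev_front}).
#'
#' @param mask binary matrix (a [segment_cell()] result).
#' @param width ring thickness in pixels.
#' @param front_hint direction or index selecting the front at the first
#'   frame; ignored when \code{prev_front} is given.
#' @param prev_front binary matrix: the previous frame's front crescent.
#' @return list of class \code{crescent_roi}: \code{ring}, \code{front},
#'   \code{back} (binary matrices), \code{axis} (\code{"x"} or
#'   \code{"y"}), \code{bbox} and \code{selected} (\code{"low"} or
#'   \code{"high"} coordinate end).
#' @export
ring_and_crescents <- function(mask, width = 40, front_hint = NULL,
                               prev_front = NULL) {
  mask <- (mask != 0) * 1L
  if (!any(mask == 1L)) stop("empty cell mask", call. = FALSE)
  brush <- EBImage::makeBrush(2L * as.integer(width) + 1L, shape = "disc")
  eroded <- matrix(as.integer(EBImage::erode(mask, brush) > 0.5),
                   nrow(mask))
  if (!any(eroded == 1L))
    stop("mask eroded to empty: cell thinner than twice the ring width",
         call. = FALSE)
  ring <- matrix(as.integer(mask == 1L & eroded == 0L), nrow(mask))
  pos <- which(ring == 1L, arr.ind = TRUE)
  r1 <- min(pos[, 1]); r2 <- max(pos[, 1])
  c1 <- min(pos[, 2]); c2 <- max(pos[, 2])
  axis <- if ((c2 - c1) >= (r2 - r1)) "x" else "y"
  coord <- if (axis == "x") pos[, 2] else pos[, 1]
  lo0 <- if (axis == "x") c1 else r1
  hi0 <- if (axis == "x") c2 else r2
  span <- hi0 - lo0 + 1L
  lo_cut <- lo0 + span / 4    # pixels with coord < lo_cut
  hi_cut <- hi0 - span / 4    # pixels with coord > hi_cut
  cres <- function(sel) {
    m <- matrix(0L, nrow(mask), ncol(mask))
    m[pos[sel, , drop = FALSE]] <- 1L
    m
  }
  low <- cres(coord < lo_cut)
  high <- cres(coord > hi_cut)
  selected <- if (!is.null(prev_front)) {
    if (sum(high * (prev_front != 0)) > sum(low * (prev_front != 0)))
      "high" else "low"
  } else if (is.null(front_hint)) {
    "high"
  } else if (is.numeric(front_hint)) {
    if (front_hint == 1) "low" else "high"
  } else {
    switch(front_hint,
      left = if (axis == "x") "low" else
        stop("front_hint 'left' but longer axis is y", call. = FALSE),
      right = if (axis == "x") "high" else
        stop("front_hint 'right' but longer axis is y", call. = FALSE),
      top = if (axis == "y") "low" else
        stop("front_hint 'top' but longer axis is x", call. = FALSE),
      bottom = if (axis == "y") "high" else
        stop("front_hint 'bottom' but longer axis is x", call. = FALSE),
      stop("unknown front_hint: ", front_hint, call. = FALSE))
  }
  structure(list(ring = ring,
                 front = if (selected == "high") high else low,
                 back = if (selected == "high") low else high,
                 axis = axis, bbox = c(r1 = r1, r2 = r2, c1 = c1, c2 = c2),
                 selected = selected),
            class = "crescent_roi")
}

# ---- ratio timecourse --------------------------------------------------

#' Mean leading-edge FRET ratio per frame
#'
#' For every frame the numerator (\code{fret}) and denominator
#' (\code{donor_donor}) images are Gaussian-smoothed (\code{sigma} pixels)
#' \emph{before} the division; the per-pixel ratio is then averaged over
#' the front-crescent pixels whose smoothed denominator is nonzero
#' (division-by-zero pixels are excluded, not clipped). The per-cell
#' summary is the mean of the per-frame means.
#'
#' @param stack a registered [fret_stack()].
#' @param rois list with one [ring_and_crescents()] result per frame.
#' @param sigma Gaussian blur standard deviation in pixels.
#' @return object of class \code{ratio_timecourse}: list with
#'   \code{frames} (data.frame \code{frame}, \code{front_mean},
#'   \code{back_mean}, \code{n_pixels}; means are NA, flagged, when every
#'   crescent pixel has a zero denominator) and \code{summary} (mean of
#'   the valid per-frame front means).
#' @export
leading_edge_ratio <- function(stack, rois, sigma = 1) {
  stopifnot(inherits(stack, "fret_stack"),
            length(rois) == n_frames(stack))
  blur <- function(x) {
    if (sigma <= 0) return(x)
    as_plain_matrix(EBImage::gblur(x, sigma = sigma))
  }
  rows <- lapply(seq_len(n_frames(stack)), function(t) {
    den <- blur(stack$donor_donor[, , t])
    num <- blur(stack$fret[, , t])
    mean_in <- function(region) {
      sel <- region != 0 & den != 0
      if (!any(sel)) return(c(NA_real_, 0))
      c(mean(num[sel] / den[sel]), sum(sel))
    }
    fr <- mean_in(rois[[t]]$front)
    bk <- mean_in(rois[[t]]$back)
    data.frame(frame = t, front_mean = fr[1], back_mean = bk[1],
               n_pixels = as.integer(fr[2]))
  })
  frames <- do.call(rbind, rows)
  structure(list(frames = frames,
                 summary = mean(frames$front_mean, na.rm = TRUE)),
            class = "ratio_timecourse")
}

#' @export
print.ratio_timecourse <- function(x, ...) {
  cat(sprintf("<ratio_timecourse> %d frame(s), summary front ratio %.4f\n",
              nrow(x$frames), x$summary))
  invisible(x)
}

# ---- high-level pipeline -----------------------------------------------

#' Quantify the leading-edge FRET ratio of a stack
#'
#' Runs the full per-frame pipeline: subpixel channel registration,
#' a-trous band-pass of the bright masking channel, fixed-threshold
#' largest-object segmentation, ring/crescent ROI construction with
#' temporal front alignment, and the Gaussian-smoothed mean front-crescent
#' ratio.
#'
#' @param stack a [fret_stack()].
#' @param config list of parameters as produced by [fret_config()].
#' @return list with \code{timecourse} (a \code{ratio_timecourse}),
#'   \code{rois}, \code{masks}, and \code{shifts} (registration table, or
#'   NULL when registration is disabled).
#' @export
quantify_leading_edge <- function(stack, config = fret_config()) {
  if (isTRUE(config$register)) {
    stack <- register_channels(stack, upsample = config$upsample)
    shifts <- attr(stack, "shifts")
  } else shifts <- NULL
  masks <- list(); rois <- list()
  prev_front <- NULL
  for (t in seq_len(n_frames(stack))) {
    bp <- atrous_bandpass(stack$acceptor_direct[, , t],
                          keep_scales = config$keep_scales)
    masks[[t]] <- segment_cell(bp, threshold = config$threshold)
    rois[[t]] <- ring_and_crescents(masks[[t]], width = config$ring_width,
                                    front_hint = config$front_hint,
                                    prev_front = prev_front)
    prev_front <- rois[[t]]$front
  }
  tc <- leading_edge_ratio(stack, rois, sigma = config$sigma)
  list(timecourse = tc, rois = rois, masks = masks, shifts = shifts)
}

#' FRET pipeline configuration
#'
#' Defaults mirror the published analysis: threshold 2000 grey values on
#' the band-passed 16-bit masking channel, a 40-px ring, wavelet scales
#' 2--8, 1.0-px Gaussian blur before the ratio, front selected by a hint at
#' the first frame. \code{path}, when given, is a key-value text file
#' (\code{key = value} lines, \code{#} comments) overriding the defaults;
#' recognised keys are \code{threshold}, \code{ring_width},
#' \code{keep_scales} (e.g. \code{2:8}), \code{sigma}, \code{front_hint},
#' \code{register}, \code{upsample}.
#'
#' @param path optional config file.
#' @param ... named overrides applied after the file.
#' @return a named list of parameters.
#' @export
fret_config <- function(path = NULL, ...) {
  cfg <- list(threshold = 2000, ring_width = 40, keep_scales = 2:8,
              sigma = 1, front_hint = "right", register = TRUE,
              upsample = 100)
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- lines[grepl("=", lines, fixed = TRUE)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
      cfg[[key]] <- switch(key,
        threshold = , ring_width = , sigma = , upsample = as.numeric(val),
        keep_scales = eval(str2lang(val)),
        register = as.logical(val),
        front_hint = if (grepl("^[0-9]+$", val)) as.integer(val) else val,
        val)
    }
  }
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  cfg
}

#' Export a ratio timecourse as CSV
#'
#' @param tc a \code{ratio_timecourse}.
#' @param file path of the CSV to write.
#' @return \code{file}, invisibly.
#' @export
export_timecourse_csv <- function(tc, file) {
  utils::write.csv(tc$frames, file, row.names = FALSE)
  invisible(file)
}
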