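# Leading-edge ratiometric FRET pipeline.

smooth_test_image <- function(n = 128, seed = 1) {
  set.seed(seed)
  img <- matrix(stats::rnorm(n * n), n, n)
  as_smooth <- EBImage::gblur(img, sigma = 4)
  matrix(as.numeric(as_smooth), n, n)
}

test_that("registration: identical channels give a zero shift", {
  img <- smooth_test_image()
  est <- estimate_shift(img, img)
  expect_identical(c(est$dy, est$dx), c(0, 0))
  expect_gt(est$confidence, 0.99)
})

test_that("registration recovers a planted subpixel shift to 0.01 px", {
  img <- smooth_test_image()
  shifted <- fourier_shift(img, -1.50, 3.25)
  est <- estimate_shift(img, shifted)
  expect_lt(abs(est$dy - (-1.50)), 0.01)
  expect_lt(abs(est$dx - 3.25), 0.01)
})

test_that("registration flags degenerate and noise-only inputs", {
  flat <- matrix(5, 64, 64)
  expect_warning(est <- estimate_shift(flat, flat), "constant")
  expect_true(est$degenerate)
  expect_identical(c(est$dy, est$dx), c(0, 0))
  set.seed(9)
  a <- matrix(stats::rnorm(64^2), 64, 64)
  b <- matrix(stats::rnorm(64^2), 64, 64)
  est2 <- estimate_shift(a, b)
  expect_lt(est2$confidence, 0.3)
})

test_that("register_channels aligns a planted channel misalignment", {
  g <- gen_fret_stack(synthetic_cell_params(
    frames = 1, noise = 10, channel_shift = c(2.40, -1.25), seed = 2))
  reg <- register_channels(g$stack)
  sh <- attr(reg, "shifts")
  acc <- sh[sh$channel == "acceptor_direct", ]
  expect_lt(abs(acc$dy - 2.40), 0.01)
  expect_lt(abs(acc$dx - (-1.25)), 0.01)
  expect_false(any(sh$low_confidence))
})

test_that("a-trous details vanish on a constant image", {
  out <- atrous_bandpass(matrix(7, 280, 280), keep_scales = 2:8)
  expect_lt(max(abs(out)), 1e-9)
})

test_that("a-trous decomposition reconstructs the input exactly", {
  set.seed(4)
  img <- matrix(stats::runif(70 * 90, 0, 4096), 70, 90)
  dec <- atrous_decompose(img, n_scales = 5)
  recon <- Reduce(`+`, dec$details) + dec$residual
  expect_lt(max(abs(recon - img)), 1e-9)
})

test_that("a-trous band-pass matches a direct convolution oracle", {
  set.seed(5)
  img <- matrix(0, 33, 33)
  img[17, 17] <- 1          # impulse
  img <- img + matrix(stats::runif(33 * 33), 33, 33) * 0.1
  # oracle: c1 = K1*img, c2 = K2*c1, c3 = K4*c2; band 2..3 = c1 - c3
  c1 <- conv2_mirror(img, dilated_kernel(1))
  c2 <- conv2_mirror(c1, dilated_kernel(2))
  c3 <- conv2_mirror(c2, dilated_kernel(4))
  expect_lt(max(abs(atrous_bandpass(img, keep_scales = 2:3) - (c1 - c3))),
            1e-10)
})

test_that("a-trous errors when the dilated kernel outgrows the image", {
  expect_error(atrous_decompose(matrix(0, 16, 16), n_scales = 4),
               "smaller than the largest dilated kernel")
})

test_that("segmentation keeps only the largest 8-connected object", {
  img <- matrix(0, 100, 100)
  img[20:44, 20:39] <- 3000      # 500 px blob
  img[70:79, 70:77] <- 3000      # 80 px blob
  mask <- segment_cell(img, threshold = 2000)
  expect_identical(sum(mask), 500L)
  expect_true(all(mask[70:79, 70:77] == 0L))
  expect_error(segment_cell(matrix(1500, 50, 50), threshold = 2000),
               "empty mask")
})

test_that("diagonal-touching pixels merge under 8-connectivity", {
  img <- matrix(0, 20, 20)
  img[5, 5] <- 5000; img[6, 6] <- 5000; img[7, 7] <- 5000
  img[15, 15] <- 5000  # separate single pixel
  mask <- segment_cell(img, threshold = 2000)
  expect_identical(sum(mask), 3L)
  expect_identical(mask[5, 5] + mask[6, 6] + mask[7, 7], 3L)
})

test_that("ring and crescents of a disc match analytic geometry", {
  n <- 256
  xg <- matrix(rep(seq_len(n), each = n), n)
  yg <- matrix(rep(seq_len(n), n), n)
  disc <- ((xg - 128)^2 + (yg - 128)^2 <= 100^2) * 1L
  roi <- ring_and_crescents(disc, width = 40, front_hint = 1)
  # ring lies inside the mask and leaves the eroded core
  expect_true(all(disc[roi$ring == 1L] == 1L))
  inner <- (xg - 128)^2 + (yg - 128)^2 <= 59^2
  expect_identical(sum(roi$ring[inner]), 0L)
  # ring area close to the analytic annulus pi*(100^2 - 60^2)
  expect_lt(abs(sum(roi$ring) - pi * (100^2 - 60^2)) / sum(roi$ring), 0.03)
  # crescents are the extremal quarters and symmetric for a disc
  expect_true(all(roi$front[roi$ring == 0L] == 0L))
  expect_lt(abs(sum(roi$front) - sum(roi$back)) / sum(roi$front), 0.02)
  expect_lte(sum(roi$front), sum(roi$ring))
})

test_that("quartering follows the longer axis and erosion can empty", {
  n <- 300
  xg <- matrix(rep(seq_len(n), each = n), n)
  yg <- matrix(rep(seq_len(n), n), n)
  ell <- (((xg - 150) / 120)^2 + ((yg - 150) / 60)^2 <= 1) * 1L
  roi <- ring_and_crescents(ell, width = 40, front_hint = "right")
  expect_identical(roi$axis, "x")
  expect_identical(roi$selected, "high")
  # front crescent pixels sit at large x
  expect_gt(min(which(roi$front == 1L, arr.ind = TRUE)[, 2]), 150)
  sq <- matrix(0L, 120, 120); sq[30:89, 30:89] <- 1L  # 60 px < 2*40
  expect_error(ring_and_crescents(sq, width = 40), "eroded to empty")
  expect_error(ring_and_crescents(matrix(0L, 50, 50), width = 5),
               "empty cell mask")
})

test_that("front crescents stay aligned across frames of a moving cell", {
  g <- gen_fret_stack(synthetic_cell_params(frames = 4, noise = 0,
                                            velocity = c(0, 3)))
  res <- quantify_leading_edge(g$stack, fret_config(register = FALSE,
                                                    front_hint = "right"))
  for (t in 2:4) expect_identical(res$rois[[t]]$selected,
                                  res$rois[[1]]$selected)
  # the front crescent tracks the high-ratio half: all front means near
  # the front ratio, all back means near the back ratio
  expect_true(all(abs(res$timecourse$frames$front_mean - 1.8) < 0.05))
  expect_true(all(abs(res$timecourse$frames$back_mean - 1.1) < 0.05))
})

test_that("uniform ratio fields are recovered exactly and scale-invariantly", {
  g <- gen_fret_stack(synthetic_cell_params(frames = 2, front_ratio = 2,
                                            back_ratio = 2, noise = 0))
  res <- quantify_leading_edge(g$stack, fret_config(register = FALSE))
  expect_lt(abs(res$timecourse$summary - 2), 1e-6)
  # rescaling both ratio channels leaves the means unchanged
  st <- g$stack
  st$donor_donor <- st$donor_donor * 3.7
  st$fret <- st$fret * 3.7
  res2 <- quantify_leading_edge(st, fret_config(register = FALSE))
  expect_lt(abs(res2$timecourse$summary - res$timecourse$summary), 1e-9)
})

test_that("front/back contrast is recovered within the blur tolerance", {
  g <- gen_fret_stack(synthetic_cell_params(frames = 2, front_ratio = 1.8,
                                            back_ratio = 1.1, noise = 0))
  res <- quantify_leading_edge(g$stack, fret_config(register = FALSE,
                                                    front_hint = "right"))
  fr <- res$timecourse$frames
  expect_true(all(abs(fr$front_mean - 1.8) < 0.05))
  expect_true(all(abs(fr$back_mean - 1.1) < 0.05))
})

test_that("zero-denominator pixels are excluded, not divided", {
  den <- matrix(2, 40, 40); num <- matrix(3, 40, 40)
  den[, 1:20] <- 0                       # half the crescent invalid
  front <- matrix(0L, 40, 40); front[15:25, 10:30] <- 1L
  stack <- fret_stack(den, num, matrix(5000, 40, 40))
  tc <- leading_edge_ratio(stack, list(fake_roi(front)), sigma = 0)
  expect_identical(tc$frames$n_pixels, sum(front == 1L & den != 0))
  expect_lt(abs(tc$frames$front_mean - 1.5), 1e-6)
  # crescent entirely zero-denominator -> flagged missing frame
  den0 <- matrix(0, 40, 40)
  st0 <- fret_stack(den0, num, matrix(5000, 40, 40))
  tc0 <- leading_edge_ratio(st0, list(fake_roi(front)), sigma = 0)
  expect_true(is.na(tc0$frames$front_mean))
  expect_identical(tc0$frames$n_pixels, 0L)
})

test_that("smoothing precedes the ratio (order is pinned)", {
  set.seed(11)
  n <- 60
  den <- matrix(rep(seq(1, 5, length.out = n), each = n), n) +
    matrix(stats::runif(n * n), n, n)
  num <- matrix(rep(seq(5, 1, length.out = n), n), n) +
    matrix(stats::runif(n * n), n, n)
  front <- matrix(0L, n, n); front[20:40, 20:40] <- 1L
  stack <- fret_stack(den, num, matrix(5000, n, n))
  tc <- leading_edge_ratio(stack, list(fake_roi(front)), sigma = 1)
  gb <- function(x) matrix(as.numeric(EBImage::gblur(x, sigma = 1)), n)
  sel <- front == 1L & gb(den) != 0
  oracle_pre <- mean(gb(num)[sel] / gb(den)[sel])    # smooth, then divide
  oracle_post <- mean(gb(num / den)[sel])            # divide, then smooth
  expect_lt(abs(tc$frames$front_mean - oracle_pre), 1e-9)
  expect_gt(abs(oracle_pre - oracle_post), 1e-6)     # orders truly differ
})

test_that("stacks round-trip through multi-page TIFF files", {
  g <- gen_fret_stack(synthetic_cell_params(frames = 2, noise = 5,
                                            size = c(64, 64),
                                            center0 = c(32, 32),
                                            axes = c(20, 14)))
  dir <- tempfile()
  paths <- write_fret_stack(g$stack, dir)
  back <- read_fret_stack(paths[["donor_donor"]], paths[["fret"]],
                          paths[["acceptor_direct"]])
  expect_identical(dim(back$fret), dim(g$stack$fret))
  # 16-bit quantisation: agreement within one grey level
  expect_lt(max(abs(back$donor_donor - pmax(g$stack$donor_donor, 0))), 1)
})

test_that("fret_config reads key-value files with overrides", {
  f <- tempfile()
  writeLines(c("# config", "threshold = 1500", "ring_width = 25",
               "keep_scales = 2:5", "front_hint = left",
               "register = FALSE"), f)
  cfg <- fret_config(f, sigma = 2)
  expect_identical(cfg$threshold, 1500)
  expect_identical(cfg$ring_width, 25)
  expect_identical(cfg$keep_scales, 2:5)
  expect_identical(cfg$front_hint, "left")
  expect_false(cfg$register)
  expect_identical(cfg$sigma, 2)
})
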