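test_that("the discretized LoG kernel is zero-mean", {
  for (s in c(0.7, 1, 2, 3.5))
    expect_lt(abs(sum(log_kernel(s))), 1e-6)
})

test_that("a constant frame has zero LoG response and no edges", {
  fr <- new_frame(matrix(0.4, 48, 48), 2, "uv")
  em <- log_edge_map(fr, edge_params(sigma_px = 2))
  expect_lt(max(abs(em$response)), 1e-12)
  expect_false(any(em$edges))
})

test_that("LoG response of an impulse equals the dense convolution oracle", {
  px <- matrix(0, 9, 9); px[5, 5] <- 1
  fr <- new_frame(px, 2, "uv")
  em <- log_edge_map(fr, edge_params(sigma_px = 1))
  expect_lt(max(abs(em$response - conv_oracle(px, log_kernel(1)))), 1e-9)
})

test_that("LoG response matches the oracle on random frames", {
  set.seed(17)
  for (k in 1:6) {
    nr <- sample(12:40, 1); nc <- sample(12:40, 1)
    s <- runif(1, 0.6, 2)
    if (2 * ceiling(3.5 * s) + 1 > min(nr, nc)) s <- 0.8
    px <- matrix(runif(nr * nc), nr, nc)
    em <- log_edge_map(new_frame(px, 1, "uv"), edge_params(sigma_px = s))
    expect_lt(max(abs(em$response - conv_oracle(px, log_kernel(s)))), 1e-9)
  }
})

test_that("a kernel larger than the frame is rejected", {
  fr <- new_frame(matrix(0.2, 10, 10), 2, "uv")
  expect_error(log_edge_map(fr, edge_params(sigma_px = 3)), "kernel")
})

test_that("a centred bright square is segmented at its centre and size", {
  px <- matrix(0.05, 100, 100)
  px[41:60, 41:60] <- 0.9            # 20 x 20 square, centre (49.5, 49.5)
  fr <- new_frame(px, 2, "uv")
  ms <- segment_crystal(fr, log_edge_map(fr))
  expect_equal(unname(ms$centroid_px), c(49.5, 49.5), tolerance = 0.1)
  expect_lte(max(abs(ms$extent_px - c(20, 20))), 1)
  expect_gt(ms$mean_interior_intensity, 0.5)
})

test_that("segmentation on fixtures matches ground truth within tolerance", {
  for (seed in 1:8) {
    sp <- random_spec(seed, snr = Inf)
    rv <- render_scene(sp, 45, "visible"); ru <- render_scene(sp, 45, "uv")
    cl <- remove_loop_model(ru$frame, loop_silhouette(rv$frame))
    ms <- segment_crystal(cl, log_edge_map(cl))
    expect_lte(max(abs(ms$centroid_px - ru$truth$crystal_centre_px)), 1)
    expect_lte(max(abs(ms$extent_um - sp$crystal_dims_um)),
               2 * sp$pixel_size_um)
  }
})

test_that("with two crystals the larger one is selected", {
  px <- matrix(0.05, 120, 120)
  px[31:50, 21:40] <- 0.9            # 20 x 20
  px[81:90, 81:90] <- 0.9            # 10 x 10 (1/4 the area)
  fr <- new_frame(px, 2, "uv")
  ms <- segment_crystal(fr, log_edge_map(fr))
  expect_equal(unname(ms$centroid_px), c(39.5, 29.5), tolerance = 0.2)
})

test_that("loop removal only modifies the holder band, bit-exactly", {
  sp <- random_spec(5, snr = 10)
  rv <- render_scene(sp, 0, "visible")
  ru <- render_scene(sp, 0, "uv", return_masks = TRUE)
  cl <- remove_loop_model(ru$frame, loop_silhouette(rv$frame))
  outside <- !cl$loop_band
  expect_identical(cl$pixels[outside], ru$frame$pixels[outside])
  # the disjoint crystal region is untouched
  expect_identical(cl$pixels[ru$truth$masks$crystal],
                   ru$frame$pixels[ru$truth$masks$crystal])
})

test_that("a loop-only UV scene is cleaned to background and yields no crystal", {
  sp <- noiseless_spec(crystal_dims_um = NULL)
  rv <- render_scene(sp, 0, "visible")
  ru <- render_scene(sp, 0, "uv")
  cl <- remove_loop_model(ru$frame, loop_silhouette(rv$frame))
  bg <- estimate_background(ru$frame)
  expect_lte(max(cl$pixels), bg + 1e-9)
  expect_error(segment_crystal(cl, log_edge_map(cl)),
               class = "uvc_no_crystal")
})

test_that("removal enables segmentation when the loop outshines the crystal", {
  # shiny nylon loop: holder brighter than the crystal under UV
  sp <- noiseless_spec(crystal_dims_um = NULL,
                       levels = list(
                         visible = c(background = 0.75, loop = 0.2,
                                     crystal = 0.7),
                         uv = c(background = 0.05, loop = 0.85,
                                crystal = 0.9)))
  rv <- render_scene(sp, 0, "visible")
  ru <- render_scene(sp, 0, "uv")
  px <- ru$frame$pixels
  px[91:100, 101:112] <- 0.5          # dim crystal inside the loop opening
  fr <- new_frame(px, 2, "uv")
  # without removal the bright loop is the largest qualifying contour
  ms_raw <- segment_crystal(fr, log_edge_map(fr))
  expect_gt(max(abs(ms_raw$centroid_px - c(95, 106))), 2)
  cl <- remove_loop_model(fr, loop_silhouette(rv$frame))
  ms <- segment_crystal(cl, log_edge_map(cl))
  expect_lte(max(abs(ms$centroid_px - c(95, 106))), 1)
})

test_that("missing loop geometry degrades gracefully with a warning", {
  sp <- noiseless_spec()
  ru <- render_scene(sp, 0, "uv")
  expect_warning(out <- remove_loop_model(ru$frame, NULL),
                 class = "uvc_degraded")
  expect_identical(out$pixels, ru$frame$pixels)
})

test_that("line scans return raw profiles with peaks at the crystal", {
  fr <- new_frame(matrix(0.3, 40, 40), 2, "uv")
  ls0 <- line_scans(fr, c(10, 10))
  expect_true(all(ls0$horizontal == 0.3) && all(ls0$vertical == 0.3))
  expect_error(line_scans(fr, c(100, 2)), "outside")

  sp <- noiseless_spec(crystal_offset_um = c(15, -10, 0))
  ru <- render_scene(sp, 0, "uv")
  rv <- render_scene(sp, 0, "visible")
  ctr <- ru$truth$crystal_centre_px
  half_px <- sp$crystal_dims_um / (2 * sp$pixel_size_um)
  lsu <- line_scans(ru$frame, ctr)
  peak_col <- which.max(lsu$horizontal) - 1
  expect_gte(peak_col, floor(ctr[2] - half_px[1]))
  expect_lte(peak_col, ceiling(ctr[2] + half_px[1]))
  # UV peak-to-background dominates the visible one through the same point
  lsv <- line_scans(rv$frame, ctr)
  p2b <- function(x) max(x) / stats::median(x)
  expect_gt(p2b(lsu$horizontal), p2b(lsv$horizontal))
})

test_that("contrast scores behave as ratios and favour UV", {
  # a dummy measure on a uniform frame scores exactly 1
  interior <- matrix(FALSE, 60, 60); interior[21:40, 21:40] <- TRUE
  dummy <- structure(list(interior = interior), class = "uvc_crystal_measure")
  fr <- new_frame(matrix(0.7, 60, 60), 2, "uv")
  expect_equal(contrast_score(fr, dummy), 1)

  sp <- random_spec(9, snr = Inf)
  rv <- render_scene(sp, 0, "visible"); ru <- render_scene(sp, 0, "uv")
  cl <- remove_loop_model(ru$frame, loop_silhouette(rv$frame))
  ms <- segment_crystal(cl, log_edge_map(cl))
  s_uv <- contrast_score(cl, ms)
  s_vis <- contrast_score(rv$frame, ms)
  expect_gt(s_uv, s_vis)
  # oracle: direct mask means
  outside <- !(EBImage::dilate(ms$interior + 0, EBImage::makeBrush(5, "disc")) > 0)
  outside <- outside & !cl$loop_band
  expect_equal(s_uv, mean(cl$pixels[ms$interior]) / mean(cl$pixels[outside]),
               tolerance = 1e-12)
})
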