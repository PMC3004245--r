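test_that("tip of a bright rectangle is its rightmost column, middle row", {
  px <- matrix(0.1, 80, 120)
  px[31:50, 1:60] <- 0.9             # rectangle touching the left edge
  fr <- new_frame(px, 2, "visible")
  tip <- detect_tip(fr)
  expect_lte(abs(tip$tip_px[["col"]] - 59), 1)   # 0-based rightmost col
  expect_lte(abs(tip$tip_px[["row"]] - 39.5), 1) # middle row
  expect_equal(unname(tip$axis_direction), c(0, 1))
})

test_that("tip on a noiseless loop fixture matches the ground truth", {
  for (seed in 1:5) {
    sp <- noiseless_spec(crystal_offset_um = c(10 * seed - 30, 8, 0),
                         seed = seed)
    r <- render_scene(sp, 0, "visible")
    tip <- detect_tip(r$frame)
    expect_lte(max(abs(tip$tip_px - r$truth$loop_tip_px)), 1)
  }
})

test_that("a blank frame raises a no-object error", {
  fr <- new_frame(matrix(0.5, 64, 64), 2, "visible")
  expect_error(detect_tip(fr), class = "uvc_no_object")
})

test_that("a verbatim template embedding is found with score 1", {
  mk <- pattern_mask(loop_width_um = 40, loop_height_um = 32,
                     wire_thickness_um = 8, neck_length_um = 10,
                     shoulder_drop_um = 16, pixel_size_um = 2)
  tm <- mk$template
  px <- matrix(0, 128, 128)
  px[41:(40 + nrow(tm)), 61:(60 + ncol(tm))] <- tm
  fr <- new_frame(px, 2, "uv")
  m <- match_pattern(fr, mk, invert = FALSE)
  expect_equal(unname(m$location_px), c(40, 60))
  expect_equal(m$score, 1, tolerance = 1e-9)
  expect_true(m$accepted)
})

test_that("a noisy embedding is located and scored per the NCC oracle", {
  mk <- pattern_mask(loop_width_um = 40, loop_height_um = 32,
                     wire_thickness_um = 8, neck_length_um = 10,
                     shoulder_drop_um = 16, pixel_size_um = 2)
  tm <- mk$template
  set.seed(7)
  px <- matrix(0, 128, 128)
  px[41:(40 + nrow(tm)), 61:(60 + ncol(tm))] <- tm
  px <- px + rnorm(length(px), 0, 0.05)
  px <- px - min(px)
  fr <- new_frame(px, 2, "uv")
  m <- match_pattern(fr, mk, invert = FALSE)
  expect_lte(max(abs(m$location_px - c(40, 60))), 1)
  oracle <- ncc_oracle(px, tm, m$location_px[["row"]] + 1,
                       m$location_px[["col"]] + 1)
  expect_equal(m$score, oracle, tolerance = 1e-9)
})

test_that("a structureless frame is rejected, enabling the fallback path", {
  mk <- pattern_mask(pixel_size_um = 2)
  fr <- new_frame(matrix(0.5, 128, 128), 2, "visible")
  m <- match_pattern(fr, mk)
  expect_false(m$accepted)
  expect_error(loop_centre(fr, m), "fallback")
})

test_that("NCC scores equal the brute-force oracle at every placement", {
  mk <- pattern_mask(loop_width_um = 20, loop_height_um = 16,
                     wire_thickness_um = 4, neck_length_um = 6,
                     shoulder_drop_um = 8, pixel_size_um = 2)
  tm <- mk$template
  set.seed(21)
  for (rep in 1:3) {
    px <- matrix(runif(44 * 52), 44, 52)
    fr <- new_frame(px, 2, "uv")
    m <- match_pattern(fr, mk, invert = FALSE)
    sm <- m$score_map
    for (i in seq_len(nrow(sm)))
      for (j in seq_len(ncol(sm)))
        expect_equal(sm[i, j], ncc_oracle(px, tm, i, j), tolerance = 1e-9)
  }
})

test_that("template matching also works on a mask of different scale", {
  mk4 <- pattern_mask(pixel_size_um = 4)
  sp <- noiseless_spec()
  r <- render_scene(sp, 0, "visible")     # 2 um/px frame
  m <- match_pattern(r$frame, mk4)
  expect_true(m$accepted)
  expect_equal(m$mask$scale_um_per_px, 2)
})

test_that("loop centre of mass matches the simulator ground truth", {
  for (seed in 1:5) {
    sp <- noiseless_spec(crystal_offset_um = c(6 * seed - 18, -10, 4),
                         seed = seed)
    r <- render_scene(sp, 0, "visible")
    m <- match_pattern(r$frame, pattern_mask(pixel_size_um = 2))
    expect_true(m$accepted)
    lb <- loop_centre(r$frame, m)
    expect_lte(max(abs(lb$centre_of_mass_px - r$truth$loop_centre_px)), 1)
    box <- lb$box_px
    expect_true(all(lb$centre_of_mass_px >= box[c("row_min", "col_min")]))
    expect_true(all(lb$centre_of_mass_px <= box[c("row_max", "col_max")]))
  }
})

test_that("centre of mass is scale-invariant and translation-equivariant", {
  sp <- noiseless_spec(crystal_offset_um = c(5, -8, 0))
  r <- render_scene(sp, 0, "visible")
  mk <- pattern_mask(pixel_size_um = 2)
  m1 <- match_pattern(r$frame, mk)
  c1 <- loop_centre(r$frame, m1)$centre_of_mass_px
  # global intensity scaling leaves the centre unchanged
  fr2 <- new_frame(2 * r$frame$pixels, 2, "visible")
  c2 <- loop_centre(fr2, match_pattern(fr2, mk))$centre_of_mass_px
  expect_equal(c1, c2, tolerance = 1e-9)
  # integer translation of the content shifts the centre exactly
  px <- r$frame$pixels
  shifted <- px
  shifted[] <- px[1, 1]
  shifted[3:nrow(px), 1:(ncol(px) - 2)] <- px[1:(nrow(px) - 2), 3:ncol(px)]
  fr3 <- new_frame(shifted, 2, "visible")
  c3 <- loop_centre(fr3, match_pattern(fr3, mk))$centre_of_mass_px
  expect_equal(unname(c3 - c1), c(2, -2), tolerance = 1e-9)
})

test_that("fallback sphere diameter is exactly 1.5 times the widest dimension", {
  # 100 px wide x 60 px tall dark rectangle at 2 um/px: widest = 200 um
  px <- matrix(0.8, 160, 160)
  px[51:110, 21:120] <- 0.15
  fb <- fallback_sphere(list(new_frame(px, 2, "visible")))
  expect_equal(fb$widest_dimension_um, 200)
  expect_equal(fb$diameter_um, 300)
  # the ratio is exact for arbitrary silhouettes
  for (seed in 1:5) {
    sp <- noiseless_spec(holder_kind = "nonstandard",
                         loop_width_um = 40 + 30 * seed,
                         loop_height_um = 35 + 20 * seed, seed = seed)
    fb <- fallback_sphere(list(render_scene(sp, 0, "visible")$frame))
    expect_identical(fb$diameter_um / fb$widest_dimension_um, 1.5)
  }
  expect_error(fallback_sphere(list(new_frame(matrix(0.5, 32, 32), 2,
                                              "visible"))),
               class = "uvc_no_object")
})

test_that("align_loop recovers the loop position from noiseless fixtures", {
  sp <- noiseless_spec(crystal_offset_um = c(14, -9, 6),
                       loop_offset_um = c(14, -9, 6))
  fs <- generate_fixture_set(sp, c(0, 45, 90), modes = "visible")
  al <- align_loop(fs$frames)
  expect_false(al$used_fallback)
  expect_lte(max(abs(al$fit$position_um - sp$loop_offset_um)),
             sp$pixel_size_um)  # within 1 px-equivalent
  # a loop already on the beam solves to the null move
  sp0 <- noiseless_spec(crystal_offset_um = c(0, 0, 0),
                        loop_offset_um = c(0, 0, 0))
  fs0 <- generate_fixture_set(sp0, c(0, 45, 90), modes = "visible")
  al0 <- align_loop(fs0$frames)
  expect_lte(max(abs(al0$move_um)), sp0$pixel_size_um)
})

test_that("align_loop needs at least two non-degenerate angles", {
  sp <- noiseless_spec()
  fs <- generate_fixture_set(sp, 0, modes = "visible")
  expect_error(align_loop(fs$frames), class = "uvc_insufficient_angles")
})

test_that("align_loop falls back to the sphere model on non-standard holders", {
  sp <- noiseless_spec(holder_kind = "nonstandard",
                       loop_offset_um = c(12, -6, 4),
                       crystal_offset_um = c(12, -6, 4))
  fs <- generate_fixture_set(sp, c(0, 45, 90), modes = "visible")
  al <- align_loop(fs$frames)
  expect_true(al$used_fallback)
  expect_equal(al$fallback$diameter_um / al$fallback$widest_dimension_um, 1.5)
  expect_lte(max(abs(al$fit$position_um - sp$loop_offset_um)),
             sp$pixel_size_um)
})
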