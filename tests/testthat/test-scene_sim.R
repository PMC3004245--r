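test_that("an all-background scene renders a uniform frame", {
  sp <- scene_spec(crystal_dims_um = NULL,
                   levels = list(visible = c(background = 0.5, loop = 0.5,
                                             crystal = 0.5),
                                 uv = c(background = 0.05, loop = 0.35,
                                        crystal = 0.9)),
                   read_sigma = 0, shot_scale = 0)
  r <- render_scene(sp, 0, "visible")
  expect_true(all(r$frame$pixels == 0.5))
})

test_that("an on-axis crystal projects to the beam-centre pixel", {
  sp <- noiseless_spec(crystal_offset_um = c(0, 0, 0))
  for (ang in c(0, 45, 90, 133)) {
    r <- render_scene(sp, ang, "uv")
    expect_equal(unname(r$truth$crystal_centre_px), sp$beam_centre_px,
                 tolerance = 1e-12)
  }
})

test_that("a known 3D offset projects per the forward model", {
  # offset (50, 30, 0) um at 2 um/px, omega = 0: displaced (+15 rows, +25 cols)
  sp <- noiseless_spec(crystal_offset_um = c(50, 30, 0), pixel_size_um = 2)
  r <- render_scene(sp, 0, "uv")
  expect_equal(unname(r$truth$crystal_centre_px - sp$beam_centre_px),
               c(15, 25), tolerance = 1e-12)
  # independent hand computation at omega = 60: dy = (30 cos60 - 0)/2 = 7.5
  r60 <- render_scene(sp, 60, "uv")
  expect_equal(unname(r60$truth$crystal_centre_px - sp$beam_centre_px),
               c(30 * cos(pi / 3) / 2, 25), tolerance = 1e-9)
})

test_that("rendered crystal centroid agrees with the analytic projection", {
  # brute-force intensity centroid over crystal pixels, noiseless scenes
  for (seed in 1:8) {
    set.seed(seed)
    off <- runif(3, -30, 30)
    shape <- sample(c("box", "hexagon", "ellipse"), 1)
    sp <- noiseless_spec(crystal_offset_um = off, crystal_shape = shape,
                         seed = seed)
    r <- render_scene(sp, sample(c(0, 45, 90), 1), "uv", return_masks = TRUE)
    px <- r$frame$pixels
    w <- pmax(px - sp$levels$uv[["background"]], 0) * r$truth$masks$crystal
    idx <- which(w > 0, arr.ind = TRUE)
    ww <- w[w > 0]
    centroid <- c(sum((idx[, 1] - 1) * ww), sum((idx[, 2] - 1) * ww)) / sum(ww)
    expect_lt(max(abs(centroid - r$truth$crystal_centre_px)), 0.5)
  }
})

test_that("a crystal projecting outside the frame raises an error naming omega", {
  sp <- noiseless_spec(crystal_offset_um = c(0, 0, 200),
                       loop_offset_um = c(0, 0, 0))
  expect_no_error(render_scene(sp, 0, "uv"))
  err <- tryCatch(render_scene(sp, 90, "uv"), error = identity)
  expect_s3_class(err, "uvc_out_of_frame")
  expect_match(conditionMessage(err), "90")
})

test_that("fixture sets have one frame per angle per mode with shared truth", {
  sp <- noiseless_spec()
  fs <- generate_fixture_set(sp, c(0, 45, 90), modes = c("visible", "uv"))
  expect_length(fs$frames, 6)
  modes <- vapply(fs$frames, function(f) f$illumination, character(1))
  expect_equal(sum(modes == "uv"), 3)
  expect_length(fs$truth$per_angle, 3)
  expect_error(generate_fixture_set(sp, numeric(0)), "angle")
  expect_error(generate_fixture_set(sp, c(0, 361)), "360")
})

test_that("identical spec and seed give bit-identical frames", {
  sp1 <- scene_spec(crystal_offset_um = c(12, -7, 3), seed = 11)
  sp2 <- scene_spec(crystal_offset_um = c(12, -7, 3), seed = 11)
  f1 <- generate_fixture_set(sp1, c(0, 90))
  f2 <- generate_fixture_set(sp2, c(0, 90))
  for (k in seq_along(f1$frames))
    expect_identical(f1$frames[[k]]$pixels, f2$frames[[k]]$pixels)
  # a different seed must change the noise realisation
  f3 <- generate_fixture_set(scene_spec(crystal_offset_um = c(12, -7, 3),
                                        seed = 12), c(0, 90))
  expect_false(identical(f1$frames[[1]]$pixels, f3$frames[[1]]$pixels))
})

test_that("noiseless frames contain only the rendered intensity levels", {
  sp <- noiseless_spec()
  r <- render_scene(sp, 45, "uv")
  lev <- sp$levels$uv
  expect_gte(min(r$frame$pixels), min(lev))
  expect_lte(max(r$frame$pixels), max(lev))
  # interiors are exactly at the configured levels (edges are blends)
  counts <- table(r$frame$pixels)
  common <- as.numeric(names(sort(counts, decreasing = TRUE)[1:3]))
  expect_setequal(round(common, 10), round(unname(lev), 10))
})

test_that("scene validation rejects inverted contrast and bad lengths", {
  expect_error(scene_spec(loop_width_um = -1), "positive")
  expect_error(scene_spec(levels = list(
    visible = c(background = 0.75, loop = 0.2, crystal = 0.7),
    uv = c(background = 0.5, loop = 0.35, crystal = 0.9))), "crystal > loop")
  expect_error(scene_spec(levels = list(
    visible = c(background = 0.2, loop = 0.2, crystal = 0.7),
    uv = c(background = 0.05, loop = 0.35, crystal = 0.9))), "contrast")
})

test_that("fixture sets round-trip through TIFF files", {
  dir <- withr::local_tempdir()
  sp <- noiseless_spec(crystal_offset_um = c(10, 5, 0))
  fs <- generate_fixture_set(sp, c(0, 90))
  write_fixture_set(fs, dir)
  expect_setequal(list.files(dir),
                  c("visible_000.tif", "uv_000.tif", "visible_090.tif",
                    "uv_090.tif", "ground_truth.json"))
  fr <- read_frame(file.path(dir, "uv_090.tif"), sp$pixel_size_um)
  expect_equal(fr$illumination, "uv")
  expect_equal(fr$omega_deg, 90)
  orig <- fs$frames[["uv_090"]]$pixels
  expect_lt(max(abs(fr$pixels - orig)), 1 / 65535 + 1e-9)  # 16-bit depth
})
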