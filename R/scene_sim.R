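#' Synthetic microscope scenes of loop-mounted crystals
#'
#' Parametric description of a simulated sample: a holder (nylon cryoloop,
#' litholoop paddle, or a non-standard blob) on a pin entering from the left
#' image edge, with a convex crystal at a 3D offset from the rotation-axis /
#' beam intersection. Scenes are rendered in two illumination modes with the
#' contrast relations seen on a beamline camera: under UV the fluorescing
#' crystal is bright over a dark background (hutch lights off), under
#' visible backlight the holder is a dark silhouette on a bright field and
#' the crystal is barely distinguishable from the background.
#'
#' Geometry is rendered with 4x supersampling followed by box downsampling,
#' so sub-pixel positions are represented faithfully (the rendered intensity
#' centroid of a noiseless crystal lands within half a pixel of the analytic
#' projection). The holder silhouette is modelled as rotationally symmetric
#' about the pin axis, so its projected shape does not change with omega;
#' only positions move according to the forward model of [predict_offset()].
#'
#' @param holder_kind `"nylon_loop"`, `"litholoop"` or `"nonstandard"`.
#'   Non-standard holders are rendered as a bare convex blob with the pin
#'   out of frame, the case that defeats pattern matching.
#' @param loop_width_um,loop_height_um outer silhouette extents of the
#'   holder: width along the pin axis (image-horizontal), height across it.
#' @param wire_thickness_um thickness of the loop wire (and of the pin).
#' @param crystal_shape `"box"`, `"hexagon"` or `"ellipse"` (projected
#'   outline).
#' @param crystal_dims_um `(width, height)` of the crystal outline, microns,
#'   or `NULL` for a crystal-free scene (empty loop).
#' @param crystal_offset_um 3-vector `(x, y, z)`, microns: crystal centre
#'   relative to the rotation-axis/beam intersection (see
#'   [gonio_geometry]).
#' @param loop_offset_um 3-vector: holder centre in the same frame. The
#'   default places the crystal slightly off the loop centre (a crystal is
#'   rarely mounted dead-centre), which is what makes the UV stage
#'   necessary after loop centring.
#' @param pixel_size_um camera calibration, microns per pixel.
#' @param frame_shape_px `(rows, cols)` of the rendered frames.
#' @param beam_centre_px 0-based `(row, col)` of the beam position; default
#'   is the frame centre.
#' @param levels named list with `visible` and `uv` components, each a
#'   named vector `c(background=, loop=, crystal=)` of intensities in
#'   `[0, 1]`. UV must satisfy crystal > loop > background; visible must be
#'   low-contrast for the crystal (|crystal - background| <= 0.2).
#' @param read_sigma additive Gaussian read-noise sigma (intensity units).
#' @param shot_scale shot-noise scale: the shot-noise standard deviation at
#'   intensity I is `shot_scale * sqrt(I)`. The default gives SNR ~ 10 at
#'   the UV crystal level. Set `read_sigma = 0, shot_scale = 0` for
#'   noiseless scenes.
#' @param seed integer seed; identical `(spec, omega, seed)` give
#'   bit-identical frames.
#' @param supersample supersampling factor for rendering.
#'
#' @return An object of class `uvc_scene_spec`.
#' @export
scene_spec <- function(holder_kind = c("nylon_loop", "litholoop", "nonstandard"),
                       loop_width_um = 220,
                       loop_height_um = 180,
                       wire_thickness_um = 20,
                       crystal_shape = c("box", "hexagon", "ellipse"),
                       crystal_dims_um = c(60, 40),
                       crystal_offset_um = c(0, 0, 0),
                       loop_offset_um = crystal_offset_um + c(-10, 6, 0),
                       pixel_size_um = 2,
                       frame_shape_px = c(192, 192),
                       beam_centre_px = NULL,
                       levels = list(
                         visible = c(background = 0.75, loop = 0.20, crystal = 0.70),
                         uv      = c(background = 0.05, loop = 0.35, crystal = 0.90)),
                       read_sigma = 0.01,
                       shot_scale = sqrt(levels$uv[["crystal"]]) / 10,
                       seed = 1L,
                       supersample = 4L) {
  holder_kind <- match.arg(holder_kind)
  crystal_shape <- match.arg(crystal_shape)
  lens <- c(loop_width_um, loop_height_um, wire_thickness_um,
            crystal_dims_um, pixel_size_um)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop_uvc("all lengths must be strictly positive")
  if (!is.null(crystal_dims_um) && length(crystal_dims_um) != 2)
    stop_uvc("'crystal_dims_um' must be (width, height) or NULL")
  if (length(crystal_offset_um) != 3 || length(loop_offset_um) != 3)
    stop_uvc("offsets must be 3-vectors (x, y, z) in microns")
  if (holder_kind == "nylon_loop" &&
      wire_thickness_um >= min(loop_width_um, loop_height_um) / 2)
    stop_uvc("wire thicker than the loop semi-axes")
  frame_shape_px <- as.integer(frame_shape_px)
  if (length(frame_shape_px) != 2 || any(frame_shape_px < 16))
    stop_uvc("'frame_shape_px' must be (rows, cols), each >= 16")
  if (is.null(beam_centre_px))
    beam_centre_px <- (frame_shape_px - 1) / 2
  uv <- levels$uv; vis <- levels$visible
  need <- c("background", "loop", "crystal")
  if (!all(need %in% names(uv)) || !all(need %in% names(vis)))
    stop_uvc("levels$visible and levels$uv each need background, loop, crystal")
  if (!(uv[["crystal"]] > uv[["loop"]] && uv[["loop"]] > uv[["background"]]))
    stop_uvc("UV levels must satisfy crystal > loop > background")
  if (abs(vis[["crystal"]] - vis[["background"]]) > 0.2)
    stop_uvc("visible-mode crystal/background contrast must be low (<= 0.2)")
  if (read_sigma < 0 || shot_scale < 0)
    stop_uvc("noise parameters must be non-negative")
  structure(
    list(holder_kind = holder_kind,
         loop_width_um = loop_width_um, loop_height_um = loop_height_um,
         wire_thickness_um = wire_thickness_um,
         crystal_shape = crystal_shape,
         crystal_dims_um = if (is.null(crystal_dims_um)) NULL
                           else as.numeric(crystal_dims_um),
         crystal_offset_um = as.numeric(crystal_offset_um),
         loop_offset_um = as.numeric(loop_offset_um),
         pixel_size_um = pixel_size_um,
         frame_shape_px = frame_shape_px,
         beam_centre_px = as.numeric(beam_centre_px),
         levels = list(visible = vis, uv = uv),
         read_sigma = read_sigma, shot_scale = shot_scale,
         seed = as.integer(seed),
         supersample = as.integer(supersample)),
    class = "uvc_scene_spec"
  )
}

#' @export
print.uvc_scene_spec <- function(x, ...) {
  cat(sprintf("<uvc_scene_spec> %s, crystal %s %g x %g um at (%g, %g, %g) um\n",
              x$holder_kind, x$crystal_shape,
              x$crystal_dims_um[1], x$crystal_dims_um[2],
              x$crystal_offset_um[1], x$crystal_offset_um[2],
              x$crystal_offset_um[3]))
  cat(sprintf("  frame %d x %d px at %g um/px, seed %d\n",
              x$frame_shape_px[1], x$frame_shape_px[2],
              x$pixel_size_um, x$seed))
  invisible(x)
}

# ---- membership functions on micron coordinates (u right, v down) --------

shape_member <- function(shape, du, dv, a, b) {
  switch(shape,
    box = abs(du) <= a & abs(dv) <= b,
    ellipse = (du / a)^2 + (dv / b)^2 <= 1,
    hexagon = abs(dv) <= b & (abs(du) / a + abs(dv) / (2 * b)) <= 1,
    stop_uvc(sprintf("unknown shape '%s'", shape))
  )
}

holder_member <- function(spec, U, V, cu, cv) {
  A <- spec$loop_width_um / 2; B <- spec$loop_height_um / 2
  t <- spec$wire_thickness_um
  du <- U - cu; dv <- V - cv
  switch(spec$holder_kind,
    nylon_loop = {
      outer <- (du / A)^2 + (dv / B)^2 <= 1
      inner <- (du / (A - t))^2 + (dv / (B - t))^2 <= 1
      ring <- outer & !inner
      pin <- U <= cu - (A - t) & abs(dv) <= t / 2
      ring | pin
    },
    litholoop = {
      # flat film loop: rounded-rectangle outline around an elliptical
      # aperture holding the crystal
      r <- min(A, B) * 0.4
      core <- abs(du) <= A & abs(dv) <= B
      incorner <- abs(du) > A - r & abs(dv) > B - r
      rc <- ((abs(du) - (A - r)) / r)^2 + ((abs(dv) - (B - r)) / r)^2 <= 1
      paddle <- core & (!incorner | rc)
      aperture <- (du / (A - t))^2 + (dv / (B - t))^2 <= 1
      pin <- U <= cu - (A - t) & abs(dv) <= t / 2
      (paddle & !aperture) | pin
    },
    nonstandard = (du / A)^2 + (dv / B)^2 <= 1  # bare blob, pin out of frame
  )
}

# Block mean over s x s pixel blocks (supersampled -> native resolution).
block_mean <- function(m, s) {
  if (s == 1) return(m)
  nr2 <- nrow(m) / s; nc2 <- ncol(m) / s
  m <- rowsum(m, rep(seq_len(nr2), each = s))
  t(rowsum(t(m), rep(seq_len(nc2), each = s))) / (s * s)
}

# Deterministic per-(seed, omega, mode) RNG stream; restores caller RNG.
scene_seed <- function(seed, omega, illumination) {
  (abs(seed) + 1009L * (round(omega * 100) %% 36000L) +
     if (illumination == "uv") 7000019L else 0L) %% 2147483647L
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Render one synthetic frame with its ground truth
#'
#' Deterministic for fixed `(spec, omega, seed)`. The returned ground-truth
#' slice carries the analytic (continuous, 0-based pixel) projection of the
#' crystal and holder at this angle, computed with the same forward model
#' the solver inverts.
#'
#' @param spec a [scene_spec()].
#' @param omega_deg rotation angle, degrees.
#' @param illumination `"visible"` or `"uv"`.
#' @param exposure_ms exposure tag for the frame, milliseconds.
#' @param return_masks also return pixel-coverage masks (`holder`,
#'   `crystal`) in the ground truth, for tests that need exact regions.
#' @return A list with elements `frame` ([new_frame()]) and `truth`.
#' @export
render_scene <- function(spec, omega_deg, illumination = c("uv", "visible"),
                         exposure_ms = 300, return_masks = FALSE) {
  if (!inherits(spec, "uvc_scene_spec")) stop_uvc("'spec' must be a scene_spec()")
  illumination <- match.arg(illumination)
  p <- spec$pixel_size_um
  nr <- spec$frame_shape_px[1]; nc <- spec$frame_shape_px[2]
  bc <- spec$beam_centre_px
  s <- spec$supersample

  has_crystal <- !is.null(spec$crystal_dims_um)
  cry <- predict_offset(spec$crystal_offset_um, omega_deg, p)
  loo <- predict_offset(spec$loop_offset_um, omega_deg, p)
  cry_px <- c(bc[1] + cry[["dy_px"]], bc[2] + cry[["dx_px"]])  # (row, col)
  loo_px <- c(bc[1] + loo[["dy_px"]], bc[2] + loo[["dx_px"]])

  half_px <- if (has_crystal) spec$crystal_dims_um / (2 * p) else c(0, 0)
  if (has_crystal &&
      (cry_px[2] - half_px[1] < 0 || cry_px[2] + half_px[1] > nc - 1 ||
       cry_px[1] - half_px[2] < 0 || cry_px[1] + half_px[2] > nr - 1))
    stop_uvc(sprintf("crystal projects outside the frame at omega = %g deg",
                     omega_deg), class = "uvc_out_of_frame")

  # supersampled micron coordinate grids (u right, v down), origin at beam
  sub <- function(n, centre) (((seq_len(n * s) - 0.5) / s) - 0.5 - centre) * p
  u <- sub(nc, bc[2])
  v <- sub(nr, bc[1])
  U <- matrix(u, nrow = nr * s, ncol = nc * s, byrow = TRUE)
  V <- matrix(v, nrow = nr * s, ncol = nc * s)

  lev <- spec$levels[[illumination]]
  img <- matrix(lev[["background"]], nr * s, nc * s)
  hm <- holder_member(spec, U, V,
                      (loo_px[2] - bc[2]) * p, (loo_px[1] - bc[1]) * p)
  img[hm] <- lev[["loop"]]
  if (has_crystal) {
    cm <- shape_member(spec$crystal_shape,
                       U - (cry_px[2] - bc[2]) * p,
                       V - (cry_px[1] - bc[1]) * p,
                       spec$crystal_dims_um[1] / 2, spec$crystal_dims_um[2] / 2)
    img[cm] <- lev[["crystal"]]
  } else cm <- matrix(FALSE, nr * s, nc * s)
  rm(U, V)

  px <- block_mean(img, s)
  if (spec$shot_scale > 0 || spec$read_sigma > 0) {
    px <- with_seed(scene_seed(spec$seed, omega_deg, illumination), {
      n <- length(px)
      px + stats::rnorm(n, 0, spec$shot_scale * sqrt(pmax(px, 0))) +
        stats::rnorm(n, 0, spec$read_sigma)
    })
    px <- pmax(px, 0)
  }

  A <- spec$loop_width_um / 2; B <- spec$loop_height_um / 2
  truth <- list(
    omega_deg = omega_deg,
    crystal_centre_3d_um = if (has_crystal) spec$crystal_offset_um
                           else rep(NA_real_, 3),
    crystal_centre_px = if (has_crystal) cry_px else c(NA_real_, NA_real_),
    crystal_bbox_px = c(cry_px[1] - half_px[2], cry_px[2] - half_px[1],
                        cry_px[1] + half_px[2], cry_px[2] + half_px[1]),
    loop_centre_px = loo_px,
    loop_tip_px = c(loo_px[1], loo_px[2] + A / p),
    loop_box_px = c(loo_px[1] - B / p, loo_px[2] - A / p,
                    loo_px[1] + B / p, loo_px[2] + A / p),
    widest_dimension_um = max(spec$loop_width_um, spec$loop_height_um)
  )
  if (return_masks) {
    truth$masks <- list(holder = block_mean(hm + 0, s) > 0,
                        crystal = block_mean(cm + 0, s) > 0)
  }
  list(frame = new_frame(px, p, illumination, omega_deg, exposure_ms),
       truth = truth)
}

#' Generate a multi-angle fixture set
#'
#' One frame per angle per requested illumination mode, with a shared
#' ground-truth record. Identical `(spec, angles, seed)` give bit-identical
#' frames.
#'
#' @param spec a [scene_spec()].
#' @param angles_deg rotation angles in `[0, 360)`, at least one.
#' @param modes illumination modes to render.
#' @param exposure_ms exposure tag per frame.
#' @return An object of class `uvc_fixture_set`: `frames` (list of
#'   [new_frame()], angle-major, mode within angle), `truth` (per-angle
#'   slices plus scene-level fields), `spec`.
#' @export
generate_fixture_set <- function(spec, angles_deg = c(0, 45, 90),
                                 modes = c("visible", "uv"),
                                 exposure_ms = 300) {
  if (length(angles_deg) < 1) stop_uvc("need at least one angle")
  if (any(angles_deg < 0 | angles_deg >= 360))
    stop_uvc("angles must lie in [0, 360)")
  modes <- match.arg(modes, c("visible", "uv"), several.ok = TRUE)
  frames <- list(); slices <- list()
  for (ang in angles_deg) {
    for (mode in modes) {
      r <- render_scene(spec, ang, mode, exposure_ms = exposure_ms)
      frames[[frame_file_name(mode, ang, "")]] <- r$frame
      slices[[sprintf("omega_%g", ang)]] <- r$truth
    }
  }
  names(frames) <- sub("\\.$", "", names(frames))
  structure(
    list(frames = frames,
         truth = list(per_angle = slices,
                      crystal_centre_3d_um = spec$crystal_offset_um,
                      widest_dimension_um =
                        max(spec$loop_width_um, spec$loop_height_um)),
         spec = spec),
    class = "uvc_fixture_set"
  )
}

#' Write a fixture set to disk
#'
#' Frames as 16-bit grayscale TIFF (or PNG) named `{mode}_{omega}.{ext}`,
#' ground truth as a `ground_truth.json` sidecar.
#'
#' @param fs a [generate_fixture_set()] result.
#' @param dir output directory (created if needed).
#' @param format `"tif"` or `"png"`.
#' @return `dir`, invisibly.
#' @export
write_fixture_set <- function(fs, dir, format = c("tif", "png")) {
  format <- match.arg(format)
  if (!inherits(fs, "uvc_fixture_set")) stop_uvc("'fs' must be a fixture set")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (fr in fs$frames)
    write_frame(fr, file.path(dir, frame_file_name(fr$illumination,
                                                   fr$omega_deg, format)))
  truth <- fs$truth
  truth$pixel_size_um <- fs$spec$pixel_size_um
  truth$beam_centre_px <- fs$spec$beam_centre_px
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
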