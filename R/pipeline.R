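#' Centring pipeline configuration
#'
#' All tunable parameters of the two-stage procedure with their shipped
#' defaults: three acquisition angles (0, 45, 90 degrees), 300 ms exposure
#' per frame, NCC acceptance threshold 0.6, LoG scale 2 px, and the
#' reference dose plan.
#'
#' @param pixel_size_um camera calibration, microns per pixel.
#' @param beam_centre_px 0-based `(row, col)` beam position; `NULL` means
#'   frame centre.
#' @param angles_deg stage-1 acquisition angles, degrees.
#' @param stage2_angles_deg UV-stage angles; default identical to stage 1.
#' @param exposure_ms UV exposure per frame, milliseconds.
#' @param ncc_threshold pattern-match acceptance threshold.
#' @param edge an [edge_params()].
#' @param mask a [pattern_mask()] or `NULL` for the standard template.
#' @param band_px holder-removal dilation radius, pixels.
#' @param loop_model_source `"stage1"` removes the holder using the
#'   visible-frame silhouette at the same angle; `"uv"` uses the UV frame
#'   itself.
#' @param dose an [exposure_plan()]; `NULL` derives one from
#'   `exposure_ms` and the number of stage-2 angles.
#' @param threshold a [safety_threshold()].
#' @param seed integer seed for any stochastic steps.
#' @return An object of class `uvc_centring_config`.
#' @export
centring_config <- function(pixel_size_um = 2,
                            beam_centre_px = NULL,
                            angles_deg = c(0, 45, 90),
                            stage2_angles_deg = NULL,
                            exposure_ms = 300,
                            ncc_threshold = 0.6,
                            edge = edge_params(),
                            mask = NULL,
                            band_px = 3,
                            loop_model_source = c("stage1", "uv"),
                            dose = NULL,
                            threshold = safety_threshold(),
                            seed = 1L) {
  loop_model_source <- match.arg(loop_model_source)
  if (pixel_size_um <= 0) stop_uvc("'pixel_size_um' must be positive")
  if (length(angles_deg) < 1) stop_uvc("need at least one angle")
  if (exposure_ms <= 0) stop_uvc("'exposure_ms' must be positive")
  if (ncc_threshold < -1 || ncc_threshold > 1)
    stop_uvc("'ncc_threshold' must lie in [-1, 1]")
  if (is.null(stage2_angles_deg)) stage2_angles_deg <- angles_deg
  if (is.null(dose))
    dose <- exposure_plan(exposure_ms = exposure_ms,
                          n_angles = length(stage2_angles_deg))
  structure(
    list(pixel_size_um = pixel_size_um, beam_centre_px = beam_centre_px,
         angles_deg = angles_deg, stage2_angles_deg = stage2_angles_deg,
         exposure_ms = exposure_ms, ncc_threshold = ncc_threshold,
         edge = edge, mask = mask, band_px = band_px,
         loop_model_source = loop_model_source,
         dose = dose, threshold = threshold, seed = as.integer(seed)),
    class = "uvc_centring_config"
  )
}

#' Read a centring configuration from a JSON file
#'
#' @param path JSON file of `centring_config()` fields; missing fields take
#'   the defaults.
#' @return A [centring_config()].
#' @export
read_centring_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("pixel_size_um", "beam_centre_px", "angles_deg",
               "stage2_angles_deg", "exposure_ms", "ncc_threshold",
               "band_px", "loop_model_source", "seed")
  bad <- setdiff(names(raw), c(allowed, "sigma_px", "zero_crossing_threshold"))
  if (length(bad))
    stop_uvc(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")))
  args <- raw[intersect(names(raw), allowed)]
  if (!is.null(raw$sigma_px) || !is.null(raw$zero_crossing_threshold))
    args$edge <- edge_params(
      sigma_px = raw$sigma_px %||% 2.0,
      zero_crossing_threshold = raw$zero_crossing_threshold)
  do.call(centring_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Load {mode}_{omega}.{tif|png} frames from a directory into per-mode lists
# keyed by angle.
load_frames_dir <- function(dir, config) {
  files <- list.files(dir, pattern = "\\.(tiff?|png)$", ignore.case = TRUE)
  out <- list(visible = list(), uv = list())
  for (f in files) {
    meta <- parse_frame_name(f, strict = FALSE)
    if (is.null(meta$illumination)) next
    out[[meta$illumination]][[sprintf("%g", meta$omega_deg)]] <-
      read_frame(file.path(dir, f), config$pixel_size_um,
                 exposure_ms = config$exposure_ms)
  }
  out
}

frames_by_mode <- function(frames, config) {
  if (is.character(frames) && length(frames) == 1 && dir.exists(frames))
    return(load_frames_dir(frames, config))
  if (inherits(frames, "uvc_fixture_set")) frames <- frames$frames
  out <- list(visible = list(), uv = list())
  for (fr in frames) {
    assert_frame(fr)
    out[[fr$illumination]][[sprintf("%g", fr$omega_deg)]] <- fr
  }
  out
}

pick_angle <- function(mode_list, ang) mode_list[[sprintf("%g", ang)]]

#' Run the full two-stage centring procedure
#'
#' Stage 1 recognises and centres the sample holder on the visible frames;
#' the solved move is applied virtually (the beam-centre reference is
#' shifted by the forward model, since the frames are static). Stage 2
#' removes the holder from each UV frame, segments the fluorescing crystal
#' and solves the residual move from the crystal centres of mass. The
#' composed move is the translation that puts the crystal on the beam.
#'
#' @param frames a directory of `{mode}_{omega}.tif` frames, a
#'   [generate_fixture_set()] result, or a list of [new_frame()] objects.
#' @param config a [centring_config()].
#' @return An object of class `uvc_centring_report`: `stage1`, `stage2`,
#'   `dose`, `final_move_um`, `status` (one of `"centred"`,
#'   `"fallback_used"`, `"no_crystal"`, `"failed"`) and `log`.
#' @export
run_centring <- function(frames, config = centring_config()) {
  if (!inherits(config, "uvc_centring_config"))
    stop_uvc("'config' must come from centring_config()")
  fm <- frames_by_mode(frames, config)
  logv <- character(0)
  note <- function(...) logv <<- c(logv, sprintf(...))

  missing_vis <- config$angles_deg[vapply(config$angles_deg, function(a)
    is.null(pick_angle(fm$visible, a)), logical(1))]
  missing_uv <- config$stage2_angles_deg[vapply(config$stage2_angles_deg,
    function(a) is.null(pick_angle(fm$uv, a)), logical(1))]
  if (length(missing_vis))
    stop_uvc(sprintf("missing visible frame(s) at omega = %s",
                     paste(missing_vis, collapse = ", ")))
  if (length(missing_uv))
    stop_uvc(sprintf("missing uv frame(s) at omega = %s",
                     paste(missing_uv, collapse = ", ")))

  vis_frames <- lapply(config$angles_deg, pick_angle, mode_list = fm$visible)
  p <- config$pixel_size_um
  bc <- config$beam_centre_px %||% default_beam_centre(vis_frames[[1]])

  # ---- stage 1: holder recognition and centring -------------------------
  stage1 <- align_loop(vis_frames, mask = config$mask, beam_centre_px = bc,
                       ncc_threshold = config$ncc_threshold)
  move1 <- stage1$move_um
  note("stage1: move (%.2f, %.2f, %.2f) um%s", move1[1], move1[2], move1[3],
       if (stage1$used_fallback) " via spherical fallback" else "")

  # ---- stage 2: UV crystal centring -------------------------------------
  ang2 <- config$stage2_angles_deg
  obs_dx <- numeric(0); obs_dy <- numeric(0); obs_w <- numeric(0)
  measures <- list(); contrast <- NULL
  for (a in ang2) {
    uvf <- pick_angle(fm$uv, a)
    lm <- switch(config$loop_model_source,
      stage1 = {
        vf <- pick_angle(fm$visible, a)
        if (is.null(vf)) NULL else loop_silhouette(vf)
      },
      uv = loop_silhouette(uvf))
    cleaned <- withCallingHandlers(
      remove_loop_model(uvf, lm, band_px = config$band_px),
      uvc_degraded = function(w) {
        note("stage2 omega=%g: %s", a, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    # virtual stage-1 move: the beam reference shifts by the forward model
    vc <- bc + rev(predict_offset(-move1, a, p))  # (row, col) = (dy, dx)
    meas <- tryCatch(
      segment_crystal(cleaned, log_edge_map(cleaned, config$edge),
                      beam_centre_px = vc),
      uvc_no_crystal = function(e) {
        note("stage2 omega=%g: %s", a, conditionMessage(e))
        NULL
      })
    if (is.null(meas)) next
    measures[[sprintf("%g", a)]] <- meas
    obs_dx <- c(obs_dx, meas$centroid_px[["col"]] - vc[2])
    obs_dy <- c(obs_dy, meas$centroid_px[["row"]] - vc[1])
    obs_w <- c(obs_w, a)
    if (is.null(contrast)) {
      vf <- pick_angle(fm$visible, a)
      contrast <- list(
        omega_deg = a,
        uv = contrast_score(cleaned, meas),
        visible = if (is.null(vf)) NA_real_ else contrast_score(vf, meas))
    }
  }

  if (length(obs_w) == 0) {
    note("stage2: no crystal found at any angle")
    dose <- safety_check(accumulated_dose(config$dose), config$threshold)
    return(new_centring_report(stage1, NULL, dose, move1, "no_crystal",
                               logv, bc, config))
  }
  if (length(obs_w) < 2 || angles_degenerate(obs_w)) {
    note("stage2: angles degenerate after failures; reporting stage-1 move")
    dose <- safety_check(accumulated_dose(config$dose), config$threshold)
    return(new_centring_report(stage1, list(measures = measures,
                                            contrast = contrast),
                               dose, move1, "failed", logv, bc, config))
  }

  fit2 <- solve_centre(offset_observations(obs_w, obs_dx, obs_dy, p))
  final <- move1 + fit2$move_um
  note("stage2: residual move (%.2f, %.2f, %.2f) um; final (%.2f, %.2f, %.2f) um",
       fit2$move_um[1], fit2$move_um[2], fit2$move_um[3],
       final[1], final[2], final[3])

  plan <- config$dose
  if (plan$n_angles != length(ang2))
    plan <- exposure_plan(plan$exposure_ms, length(ang2),
                          plan$per_exposure_dose_uW, plan$spot_diameter_um)
  dose <- safety_check(accumulated_dose(plan), config$threshold)

  status <- if (stage1$used_fallback) "fallback_used" else "centred"
  new_centring_report(stage1, list(fit = fit2, measures = measures,
                                   contrast = contrast),
                      dose, final, status, logv, bc, config)
}

new_centring_report <- function(stage1, stage2, dose, final_move, status,
                                logv, beam_centre_px, config) {
  structure(
    list(stage1 = stage1, stage2 = stage2, dose = dose,
         final_move_um = final_move, status = status, log = logv,
         beam_centre_px = beam_centre_px, config = config),
    class = "uvc_centring_report"
  )
}

#' @export
print.uvc_centring_report <- function(x, ...) {
  cat(sprintf("<uvc_centring_report> status: %s\n", x$status))
  cat(sprintf("  final move (um): x = %.3f, y = %.3f, z = %.3f\n",
              x$final_move_um[1], x$final_move_um[2], x$final_move_um[3]))
  if (!is.null(x$stage2$contrast))
    cat(sprintf("  contrast (omega %g): uv %.2f vs visible %.2f\n",
                x$stage2$contrast$omega_deg, x$stage2$contrast$uv,
                x$stage2$contrast$visible))
  cat(sprintf("  dose: %g uW accumulated, verdict %s\n",
              x$dose$accumulated_uW, x$dose$verdict))
  for (l in x$log) cat("  - ", l, "\n", sep = "")
  invisible(x)
}

#' Serialize a centring report to JSON
#'
#' Writes the machine-readable subset of the report (moves, scores,
#' measures, dose, status, log); image-sized matrices are omitted.
#'
#' @param report a [run_centring()] report.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "uvc_centring_report"))
    stop_uvc("'report' must come from run_centring()")
  s1 <- report$stage1
  out <- list(
    status = report$status,
    final_move_um = as.list(stats::setNames(report$final_move_um,
                                            c("x", "y", "z"))),
    beam_centre_px = report$beam_centre_px,
    stage1 = list(
      move_um = as.list(stats::setNames(s1$move_um, c("x", "y", "z"))),
      residual_rms_px = s1$fit$residual_rms_px,
      used_fallback = s1$used_fallback,
      tips = lapply(s1$tips, function(t) as.list(t$tip_px)),
      match_scores = lapply(s1$matches, function(m)
        list(score = m$score, accepted = m$accepted,
             location_px = as.list(m$location_px))),
      boxes = if (is.null(s1$boxes)) NULL else lapply(s1$boxes, function(b)
        list(box_px = as.list(b$box_px),
             centre_of_mass_px = as.list(b$centre_of_mass_px))),
      fallback_diameter_um = if (is.null(s1$fallback)) NULL
                             else s1$fallback$diameter_um),
    stage2 = if (is.null(report$stage2)) NULL else list(
      measures = lapply(report$stage2$measures, function(m)
        list(centroid_px = as.list(m$centroid_px),
             extent_um = as.list(m$extent_um),
             area_px = m$area_px,
             mean_interior_intensity = m$mean_interior_intensity)),
      contrast = report$stage2$contrast,
      residual_rms_px = report$stage2$fit$residual_rms_px),
    dose = report$dose[c("per_exposure_uW", "n_angles", "exposure_ms",
                         "accumulated_uW", "alternative_accumulated_uJ",
                         "density_ratio", "verdict")],
    log = report$log
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
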