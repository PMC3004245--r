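#' Measured UV beam profile
#'
#' A grid of power-density values measured at the sample position (the
#' instrument scans a detector behind a 200 um aperture in 200 um steps).
#' Grid point `(i, j)` (1-based) sits at `((j-1)*step, (i-1)*step)` um in
#' `(x, y)` from the first point.
#'
#' @param values numeric matrix of non-negative power densities, uW per
#'   um^2.
#' @param step_um grid step, microns (200 in the reference instrument).
#' @param aperture_diameter_um measurement aperture, microns.
#' @param wavelength_nm LED wavelength tag, informational (e.g. 268.8,
#'   283.7 or 284.3 for the characterized LEDs).
#' @return An object of class `uvc_beam_profile`.
#' @export
beam_profile <- function(values, step_um = 200, aperture_diameter_um = 200,
                         wavelength_nm = NA_real_) {
  if (!is.matrix(values) || length(values) == 0)
    stop_uvc("'values' must be a non-empty numeric matrix")
  if (any(!is.finite(values)) || any(values < 0))
    stop_uvc("power densities must be finite and non-negative")
  if (step_um <= 0 || aperture_diameter_um <= 0)
    stop_uvc("step and aperture must be positive")
  structure(list(values = values, step_um = step_um,
                 aperture_diameter_um = aperture_diameter_um,
                 wavelength_nm = wavelength_nm),
            class = "uvc_beam_profile")
}

# Bilinear interpolation of the profile at (x, y) um; zero outside support.
profile_density <- function(profile, x, y) {
  v <- profile$values; s <- profile$step_um
  nr <- nrow(v); nc <- ncol(v)
  gx <- x / s; gy <- y / s              # 0-based grid coordinates
  out <- numeric(length(x))
  ok <- gx >= 0 & gx <= nc - 1 & gy >= 0 & gy <= nr - 1
  if (any(ok)) {
    j0 <- pmin(floor(gx[ok]), nc - 2); i0 <- pmin(floor(gy[ok]), nr - 2)
    fx <- gx[ok] - j0; fy <- gy[ok] - i0
    v00 <- v[cbind(i0 + 1, j0 + 1)]; v01 <- v[cbind(i0 + 1, j0 + 2)]
    v10 <- v[cbind(i0 + 2, j0 + 1)]; v11 <- v[cbind(i0 + 2, j0 + 2)]
    out[ok] <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
      fy * ((1 - fx) * v10 + fx * v11)
  }
  out
}

#' Power through the aperture at a position in the beam
#'
#' Numerical integral of the measured power density over the circular
#' aperture centred at `centre_um`, by bilinear interpolation on a
#' subdivided grid. Regions outside the measured support contribute zero
#' (with a warning when the aperture is clipped).
#'
#' @param profile a [beam_profile()].
#' @param centre_um `(x, y)` aperture centre, microns, in profile grid
#'   coordinates.
#' @param subdivide integration subdivision per grid step.
#' @return Power in uW.
#' @export
aperture_dose <- function(profile, centre_um = NULL, subdivide = 10L) {
  if (!inherits(profile, "uvc_beam_profile"))
    stop_uvc("'profile' must come from beam_profile()")
  v <- profile$values; s <- profile$step_um
  if (is.null(centre_um))
    centre_um <- c((ncol(v) - 1) * s / 2, (nrow(v) - 1) * s / 2)
  R <- profile$aperture_diameter_um / 2
  h <- s / subdivide
  xs <- seq(centre_um[1] - R + h / 2, centre_um[1] + R, by = h)
  ys <- seq(centre_um[2] - R + h / 2, centre_um[2] + R, by = h)
  X <- rep(xs, times = length(ys)); Y <- rep(ys, each = length(xs))
  inside <- (X - centre_um[1])^2 + (Y - centre_um[2])^2 <= R^2
  X <- X[inside]; Y <- Y[inside]
  support_x <- c(0, (ncol(v) - 1) * s); support_y <- c(0, (nrow(v) - 1) * s)
  if (centre_um[1] + R < support_x[1] || centre_um[1] - R > support_x[2] ||
      centre_um[2] + R < support_y[1] || centre_um[2] - R > support_y[2]) {
    warn_uvc("aperture entirely outside the measured profile support")
    return(0)
  }
  if (centre_um[1] - R < support_x[1] || centre_um[1] + R > support_x[2] ||
      centre_um[2] - R < support_y[1] || centre_um[2] + R > support_y[2])
    warn_uvc("aperture clipped at the edge of the measured profile")
  sum(profile_density(profile, X, Y)) * h^2
}

#' UV exposure plan for the centring protocol
#'
#' Defaults are the reference protocol: a single 300 ms exposure at each of
#' three angles, with a per-exposure reference dose of 16 uW in a 200 um
#' spot (the 1 s reference value for the characterized source).
#'
#' @param exposure_ms exposure per frame, milliseconds.
#' @param n_angles number of exposures (angles); may be 0.
#' @param per_exposure_dose_uW reference dose per exposure, uW.
#' @param spot_diameter_um illuminated spot diameter, microns.
#' @return An object of class `uvc_exposure_plan`.
#' @export
exposure_plan <- function(exposure_ms = 300, n_angles = 3,
                          per_exposure_dose_uW = 16,
                          spot_diameter_um = 200) {
  if (exposure_ms <= 0 || per_exposure_dose_uW <= 0 || spot_diameter_um <= 0)
    stop_uvc("exposure, dose and spot diameter must be positive")
  if (n_angles < 0) stop_uvc("'n_angles' must be >= 0")
  structure(list(exposure_ms = exposure_ms, n_angles = as.integer(n_angles),
                 per_exposure_dose_uW = per_exposure_dose_uW,
                 spot_diameter_um = spot_diameter_um),
            class = "uvc_exposure_plan")
}

#' Damage threshold for UV exposure
#'
#' Default is the published damage observation: about 0.1 mW (100 uW) in a
#' 150 um spot was enough to cause local modifications in protein
#' crystals.
#'
#' @param power_uW threshold power, uW.
#' @param spot_diameter_um spot over which it was delivered, microns.
#' @return An object of class `uvc_safety_threshold`.
#' @export
safety_threshold <- function(power_uW = 100, spot_diameter_um = 150) {
  if (power_uW <= 0 || spot_diameter_um <= 0)
    stop_uvc("threshold power and spot must be positive")
  structure(list(power_uW = power_uW, spot_diameter_um = spot_diameter_um),
            class = "uvc_safety_threshold")
}

spot_area_um2 <- function(diameter_um) pi * (diameter_um / 2)^2

#' Accumulated dose over the centring protocol
#'
#' The primary figure mirrors the protocol's own accounting: the
#' per-exposure dose (in uW) summed over the exposures, so the default
#' plan accumulates 16 x 3 = 48 uW. Because summing powers is physically
#' unconventional, a time-scaled variant (per-exposure uW x exposure
#' seconds x n, i.e. energy in uJ relative to the 1 s reference) is also
#' reported and flagged as alternative accounting.
#'
#' @param plan an [exposure_plan()].
#' @return An object of class `uvc_dose_report`: `per_exposure_uW`,
#'   `n_angles`, `accumulated_uW`, `alternative_accumulated_uJ`,
#'   `spot_diameter_um`, `exposure_ms`, plus `verdict` fields filled by
#'   [safety_check()].
#' @export
accumulated_dose <- function(plan = exposure_plan()) {
  if (!inherits(plan, "uvc_exposure_plan"))
    stop_uvc("'plan' must come from exposure_plan()")
  structure(
    list(per_exposure_uW = plan$per_exposure_dose_uW,
         n_angles = plan$n_angles,
         exposure_ms = plan$exposure_ms,
         spot_diameter_um = plan$spot_diameter_um,
         accumulated_uW = plan$per_exposure_dose_uW * plan$n_angles,
         alternative_accumulated_uJ =
           plan$per_exposure_dose_uW * (plan$exposure_ms / 1000) * plan$n_angles,
         verdict = NA_character_),
    class = "uvc_dose_report"
  )
}

#' Compare the exposure plan against the damage threshold
#'
#' Per-area power density of a single exposure (its dose over its spot
#' area) versus the threshold density (threshold power over its spot
#' area). The verdict is `"pass"` only when the plan density is strictly
#' below the threshold density; reaching the threshold is already unsafe
#' (`"warn"`). A zero-exposure plan passes trivially.
#'
#' @param report an [accumulated_dose()] report.
#' @param threshold a [safety_threshold()].
#' @return The report with `plan_density_uW_um2`,
#'   `threshold_density_uW_um2`, `density_ratio` and `verdict` filled in.
#' @export
safety_check <- function(report, threshold = safety_threshold()) {
  if (!inherits(report, "uvc_dose_report"))
    stop_uvc("'report' must come from accumulated_dose()")
  if (!inherits(threshold, "uvc_safety_threshold"))
    stop_uvc("'threshold' must come from safety_threshold()")
  plan_density <- if (report$n_angles == 0) 0 else
    report$per_exposure_uW / spot_area_um2(report$spot_diameter_um)
  thr_density <- threshold$power_uW / spot_area_um2(threshold$spot_diameter_um)
  report$plan_density_uW_um2 <- plan_density
  report$threshold_density_uW_um2 <- thr_density
  report$density_ratio <- plan_density / thr_density
  report$verdict <- if (plan_density < thr_density) "pass" else "warn"
  report$threshold <- threshold
  report
}

#' @export
print.uvc_dose_report <- function(x, ...) {
  cat("<uvc_dose_report>\n")
  cat(sprintf("  %g uW per exposure x %d angles (%g ms each, %g um spot)\n",
              x$per_exposure_uW, x$n_angles, x$exposure_ms,
              x$spot_diameter_um))
  cat(sprintf("  accumulated dose: %g uW (protocol accounting)\n",
              x$accumulated_uW))
  cat(sprintf("  alternative accounting: %g uJ (time-scaled)\n",
              x$alternative_accumulated_uJ))
  if (!is.na(x$verdict))
    cat(sprintf("  density %.3g vs threshold %.3g uW/um^2 (ratio %.3g): %s\n",
                x$plan_density_uW_um2, x$threshold_density_uW_um2,
                x$density_ratio, toupper(x$verdict)))
  invisible(x)
}
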