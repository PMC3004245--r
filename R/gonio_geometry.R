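#' Goniometer geometry: forward model and multi-angle 3D centring solve
#'
#' The stage frame is `(x, y, z)` in microns: `x` runs along the omega
#' rotation axis (image-horizontal), `y` is image-vertical at omega = 0
#' (positive downward, i.e. row-increasing) and `z` is the viewing direction
#' at omega = 0. A positive omega is a right-handed rotation about the +x
#' image-horizontal axis, so a point at stage position `(x, y, z)` relative
#' to the beam/rotation-axis intersection projects onto the camera at a
#' pixel offset from the beam centre of
#'
#'   dx_px = x / pixel_size
#'   dy_px = (y * cos(omega) - z * sin(omega)) / pixel_size
#'
#' with `dx` along columns and `dy` along rows (downward). The simulator and
#' the solver share exactly this convention.
#'
#' @name gonio_geometry
NULL

deg2rad <- function(deg) deg * pi / 180

#' Predict the image offset of a stage position at a rotation angle
#'
#' @param move_um numeric 3-vector `(x, y, z)` in microns: the position of
#'   the target relative to the beam/rotation-axis intersection.
#' @param omega_deg rotation angle(s), degrees.
#' @param pixel_size_um microns per pixel.
#' @return For one angle, a named vector `c(dx_px, dy_px)`; for several, a
#'   matrix with one row per angle.
#' @export
predict_offset <- function(move_um, omega_deg, pixel_size_um) {
  stopifnot(length(move_um) == 3, all(is.finite(move_um)),
            is.finite(pixel_size_um), pixel_size_um > 0)
  w <- deg2rad(omega_deg)
  dx <- rep(move_um[1] / pixel_size_um, length(w))
  dy <- (move_um[2] * cos(w) - move_um[3] * sin(w)) / pixel_size_um
  out <- cbind(dx_px = dx, dy_px = dy)
  if (length(w) == 1) out[1, ] else out
}

#' Build an offset-observation table
#'
#' @param omega_deg,dx_px,dy_px parallel vectors of rotation angles and
#'   target-minus-beam-centre pixel offsets (dx along columns, dy along
#'   rows, downward positive).
#' @param pixel_size_um microns per pixel.
#' @return A data frame of class `uvc_offset_obs`.
#' @export
offset_observations <- function(omega_deg, dx_px, dy_px, pixel_size_um) {
  n <- length(omega_deg)
  stopifnot(length(dx_px) == n, length(dy_px) == n, n >= 1)
  if (any(!is.finite(dx_px)) || any(!is.finite(dy_px)))
    stop_uvc("offsets must be finite")
  out <- data.frame(omega_deg = as.numeric(omega_deg),
                    dx_px = as.numeric(dx_px),
                    dy_px = as.numeric(dy_px),
                    pixel_size_um = as.numeric(pixel_size_um))
  class(out) <- c("uvc_offset_obs", "data.frame")
  out
}

# Angles are degenerate when all are equal modulo 180 deg: cos/sin columns
# of the design matrix are then collinear and (y, z) cannot be separated.
angles_degenerate <- function(omega_deg, tol = 1e-8) {
  w <- deg2rad(omega_deg)
  A <- cbind(cos(w), -sin(w))
  qr(A)$rank < 2 ||
    abs(det(crossprod(A))) < tol * max(1, sum(A^2))^2
}

#' Solve the 3D stage position from multi-angle image offsets
#'
#' Least-squares inversion of [predict_offset()]: `x` is the mean of the
#' (omega-independent) horizontal offsets, and `(y, z)` solve the
#' cos/sin system over the observed angles. The returned `move_um` is the
#' stage translation that brings the target onto the beam, i.e. the negated
#' solved position.
#'
#' @param observations a [offset_observations()] table (>= 2 rows with
#'   angles distinct modulo 180 degrees).
#' @param residual_threshold_px flag the fit (`flagged = TRUE`) when the
#'   root-mean-square residual of the vertical model exceeds this many
#'   pixels; the solution is still returned.
#' @return An object of class `uvc_gonio_fit` with elements `position_um`,
#'   `move_um`, `residual_rms_px`, `flagged`, `n_obs`.
#' @export
solve_centre <- function(observations, residual_threshold_px = 2) {
  if (!inherits(observations, "uvc_offset_obs"))
    stop_uvc("'observations' must come from offset_observations()")
  if (nrow(observations) < 2)
    stop_uvc("need >= 2 observations at distinct angles (mod 180 deg)",
             class = "uvc_insufficient_angles")
  if (angles_degenerate(observations$omega_deg))
    stop_uvc("rotation angles are degenerate (all equal mod 180 deg)",
             class = "uvc_insufficient_angles")
  p <- observations$pixel_size_um[1]
  w <- deg2rad(observations$omega_deg)

  x_um <- mean(observations$dx_px) * p
  A <- cbind(cos(w), -sin(w))
  b <- observations$dy_px * p
  yz <- qr.solve(A, b)
  res <- A %*% yz - b
  rms_px <- sqrt(mean(res^2)) / p

  position <- c(x = x_um, y = yz[1], z = yz[2])
  flagged <- rms_px > residual_threshold_px
  if (flagged)
    warn_uvc(sprintf(
      "inconsistent offsets: residual RMS %.2f px exceeds %.2f px",
      rms_px, residual_threshold_px), class = "uvc_inconsistent_fit")
  structure(
    list(position_um = position,
         move_um = -position,
         residual_rms_px = rms_px,
         flagged = flagged,
         n_obs = nrow(observations)),
    class = "uvc_gonio_fit"
  )
}

#' @export
print.uvc_gonio_fit <- function(x, ...) {
  cat("<uvc_gonio_fit>\n")
  cat(sprintf("  solved position (um): x = %.3f, y = %.3f, z = %.3f\n",
              x$position_um[1], x$position_um[2], x$position_um[3]))
  cat(sprintf("  centring move   (um): x = %.3f, y = %.3f, z = %.3f\n",
              x$move_um[1], x$move_um[2], x$move_um[3]))
  cat(sprintf("  residual RMS %.4g px over %d observations%s\n",
              x$residual_rms_px, x$n_obs,
              if (x$flagged) "  [FLAGGED: inconsistent]" else ""))
  invisible(x)
}
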