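#' Micrograph frame
#'
#' A single 2D grayscale micrograph of the sample position, tagged with its
#' pixel calibration, illumination mode and goniometer angle. Pixels are a
#' base-R numeric matrix indexed `[row, col]` with row 1 at the image top;
#' all coordinates reported by the package are 0-based `(row, col)` with the
#' origin at the top-left pixel centre, and micron/pixel conversions always
#' go through `pixel_size_um`.
#'
#' @param pixels numeric matrix of non-negative intensities (arbitrary
#'   units; rendered scenes use 0--1).
#' @param pixel_size_um microns per pixel (isotropic).
#' @param illumination `"visible"` (backlight) or `"uv"` (fluorescence).
#' @param omega_deg goniometer rotation angle at acquisition, degrees.
#' @param exposure_ms exposure time of this frame, milliseconds.
#'
#' @return An object of class `uvc_frame`.
#' @export
new_frame <- function(pixels, pixel_size_um, illumination = c("visible", "uv"),
                      omega_deg = 0, exposure_ms = 300) {
  illumination <- match.arg(illumination)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_uvc("'pixels' must be a numeric matrix")
  if (any(!is.finite(pixels)))
    stop_uvc("frame intensities must be finite")
  if (any(pixels < 0))
    stop_uvc("frame intensities must be non-negative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop_uvc("'pixel_size_um' must be a single positive number")
  structure(
    list(pixels = pixels,
         pixel_size_um = as.numeric(pixel_size_um),
         illumination = illumination,
         omega_deg = as.numeric(omega_deg),
         exposure_ms = as.numeric(exposure_ms)),
    class = "uvc_frame"
  )
}

is_frame <- function(x) inherits(x, "uvc_frame")

assert_frame <- function(x, arg = deparse(substitute(x))) {
  if (!is_frame(x)) stop_uvc(sprintf("'%s' must be a uvc_frame", arg))
  invisible(x)
}

#' @export
print.uvc_frame <- function(x, ...) {
  cat(sprintf("<uvc_frame> %d x %d px, %.3g um/px, %s, omega = %g deg, %g ms\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              x$illumination, x$omega_deg, x$exposure_ms))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.uvc_frame <- function(x) dim(x$pixels)

# Default beam-centre pixel: geometric frame centre, 0-based (row, col).
default_beam_centre <- function(frame) {
  d <- dim(frame$pixels)
  c((d[1] - 1) / 2, (d[2] - 1) / 2)
}

#' Read a frame from a TIFF or PNG file
#'
#' File names follow the `{mode}_{omega}.tif` convention used throughout the
#' pipeline (e.g. `visible_045.tif`, `uv_090.png`); mode and angle are parsed
#' from the name unless given explicitly.
#'
#' @param path path to a grayscale TIFF or PNG file.
#' @param pixel_size_um microns per pixel of the camera.
#' @param illumination,omega_deg override the values parsed from the file
#'   name.
#' @param exposure_ms exposure time tag, milliseconds.
#' @return A [new_frame()] object.
#' @export
read_frame <- function(path, pixel_size_um, illumination = NULL,
                       omega_deg = NULL, exposure_ms = 300) {
  if (!file.exists(path)) stop_uvc(sprintf("no such frame file: %s", path))
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop_uvc(sprintf("unsupported image format '.%s' (use TIFF or PNG)", ext))
  )
  if (length(dim(px)) == 3) px <- px[, , 1]  # collapse grayscale-as-RGB
  meta <- parse_frame_name(basename(path), strict = FALSE)
  if (is.null(illumination)) illumination <- meta$illumination
  if (is.null(omega_deg)) omega_deg <- meta$omega_deg
  if (is.null(illumination) || is.null(omega_deg))
    stop_uvc(sprintf(
      "cannot infer mode/angle from '%s'; pass illumination= and omega_deg=",
      basename(path)))
  new_frame(px, pixel_size_um, illumination, omega_deg, exposure_ms)
}

#' Write a frame as 16-bit grayscale TIFF (or PNG)
#'
#' Intensities are clipped to `[0, 1]` for encoding.
#'
#' @param frame a [new_frame()] object.
#' @param path output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  assert_frame(frame)
  px <- pmin(pmax(frame$pixels, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(px, path, bits.per.sample = 16L),
    png = png::writePNG(px, path),
    stop_uvc(sprintf("unsupported image format '.%s' (use TIFF or PNG)", ext))
  )
  invisible(path)
}

# Parse "visible_045.tif" -> list(illumination, omega_deg). Angles may carry
# a decimal part after 'p' (e.g. uv_022p5.tif for 22.5 deg).
parse_frame_name <- function(name, strict = TRUE) {
  base <- sub("\\.(tiff?|png)$", "", name, ignore.case = TRUE)
  m <- regmatches(base, regexec("^(visible|uv)_([0-9]+(?:p[0-9]+)?)$", base))[[1]]
  if (length(m) == 0) {
    if (strict)
      stop_uvc(sprintf("frame name '%s' does not follow {mode}_{omega}.{tif|png}",
                       name))
    return(list(illumination = NULL, omega_deg = NULL))
  }
  list(illumination = m[2],
       omega_deg = as.numeric(sub("p", ".", m[3], fixed = TRUE)))
}

frame_file_name <- function(illumination, omega_deg, ext = "tif") {
  s <- sub("\\.", "p", format(omega_deg, trim = TRUE, scientific = FALSE))
  parts <- strsplit(s, "p", fixed = TRUE)[[1]]
  parts[1] <- formatC(as.integer(parts[1]), width = 3, flag = "0")
  sprintf("%s_%s.%s", illumination, paste(parts, collapse = "p"), ext)
}
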