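#' Laplacian-of-Gaussian edge parameters
#'
#' @param sigma_px spatial scale of the LoG operator, pixels (>= 0.5).
#' @param zero_crossing_threshold minimum absolute response difference
#'   across a zero crossing for it to count as an edge. `NULL` (default)
#'   resolves per frame to 1\% of the dynamic range or, on noisy frames,
#'   6 times the robust spread (MAD) of the LoG response, whichever is
#'   larger; the MAD floor is what rejects noise-induced crossings while
#'   leaving clean frames at the 1\% rule.
#' @return An object of class `uvc_edge_params`.
#' @export
edge_params <- function(sigma_px = 2.0, zero_crossing_threshold = NULL) {
  if (!is.numeric(sigma_px) || sigma_px < 0.5)
    stop_uvc("'sigma_px' must be >= 0.5")
  if (!is.null(zero_crossing_threshold) && zero_crossing_threshold < 0)
    stop_uvc("'zero_crossing_threshold' must be >= 0")
  structure(list(sigma_px = sigma_px,
                 zero_crossing_threshold = zero_crossing_threshold),
            class = "uvc_edge_params")
}

#' Discretized Laplacian-of-Gaussian kernel
#'
#' `LoG(r) = (r^2 - 2 sigma^2) / sigma^4 * exp(-r^2 / (2 sigma^2))`,
#' sampled on a `(2h+1)^2` grid with `h = ceiling(3.5 sigma)`, then
#' DC-corrected so the entries sum to zero (a constant image must give a
#' zero response).
#'
#' @param sigma_px LoG scale in pixels.
#' @return A numeric matrix with zero sum.
#' @export
log_kernel <- function(sigma_px) {
  h <- ceiling(3.5 * sigma_px)
  x <- -h:h
  X <- matrix(x, 2 * h + 1, 2 * h + 1, byrow = TRUE)
  Y <- matrix(x, 2 * h + 1, 2 * h + 1)
  r2 <- X^2 + Y^2
  k <- (r2 - 2 * sigma_px^2) / sigma_px^4 * exp(-r2 / (2 * sigma_px^2))
  k - mean(k)
}

# Correlation of px with kernel k under symmetric (mirror-with-edge)
# boundary padding; k must be odd-sized square (and here is symmetric, so
# correlation equals convolution).
conv_symmetric <- function(px, k) {
  K <- nrow(k); h <- (K - 1) / 2
  nr <- nrow(px); nc <- ncol(px)
  if (K > nr || K > nc) stop_uvc("kernel larger than frame")
  ri <- c(h:1, seq_len(nr), nr:(nr - h + 1))
  ci <- c(h:1, seq_len(nc), nc:(nc - h + 1))
  fp <- px[ri, ci]
  res <- matrix(0, nr, nc)
  for (a in seq_len(K))
    for (b in seq_len(K))
      res <- res + k[a, b] * fp[a:(a + nr - 1), b:(b + nc - 1)]
  res
}

#' Laplacian-of-Gaussian edge map
#'
#' Convolves the frame with the discretized LoG kernel (symmetric boundary
#' handling) and marks zero crossings: a pair of 4-neighbours with opposite
#' response signs whose response difference exceeds the threshold flags
#' both pixels as edge pixels, which keeps contours closed for region
#' filling.
#'
#' @param frame a [new_frame()].
#' @param params an [edge_params()].
#' @return An object of class `uvc_edge_map`: `response` (numeric matrix),
#'   `edges` (logical matrix), `params` (with the resolved threshold).
#' @export
log_edge_map <- function(frame, params = edge_params()) {
  assert_frame(frame)
  if (!inherits(params, "uvc_edge_params"))
    stop_uvc("'params' must come from edge_params()")
  px <- frame$pixels
  resp <- conv_symmetric(px, log_kernel(params$sigma_px))
  thr <- params$zero_crossing_threshold
  if (is.null(thr))
    thr <- max(0.01 * (max(px) - min(px)), 6 * stats::mad(resp))
  nr <- nrow(resp); nc <- ncol(resp)
  edges <- matrix(FALSE, nr, nc)
  # horizontal crossings
  a <- resp[, -nc]; b <- resp[, -1]
  ch <- (sign(a) * sign(b) < 0) & (abs(a - b) >= thr)
  edges[, -nc] <- edges[, -nc] | ch
  edges[, -1] <- edges[, -1] | ch
  # vertical crossings
  a <- resp[-nr, ]; b <- resp[-1, ]
  cv <- (sign(a) * sign(b) < 0) & (abs(a - b) >= thr)
  edges[-nr, ] <- edges[-nr, ] | cv
  edges[-1, ] <- edges[-1, ] | cv
  structure(list(response = resp, edges = edges,
                 params = edge_params(params$sigma_px, thr)),
            class = "uvc_edge_map")
}

#' Global background estimate
#'
#' Median intensity of the pixels below the Otsu threshold — appropriate
#' for UV frames, where the hutch lights are off and the background is a
#' uniform dark field.
#'
#' @param px numeric matrix or [new_frame()].
#' @return Scalar background intensity.
#' @export
estimate_background <- function(px) {
  if (is_frame(px)) px <- px$pixels
  rng <- max(px) - min(px)
  if (rng <= 0) return(px[1])
  w <- (px - min(px)) / rng
  thr <- EBImage::otsu(w, range = c(0, 1))
  below <- px[w <= thr]
  if (length(below) == 0) return(min(px))
  stats::median(below)
}

#' Holder silhouette mask of a frame
#'
#' Foreground of the holder as seen in this frame: inverted intensity above
#' the Otsu threshold on visible backlight frames, direct intensity above
#' Otsu under UV, reduced to the largest connected component (the holder
#' plus its pin) so isolated noise pixels do not enter the loop model.
#' Used as the loop model for [remove_loop_model()].
#'
#' @param frame a [new_frame()].
#' @return Logical matrix, `TRUE` on the silhouette.
#' @export
loop_silhouette <- function(frame) {
  fg <- holder_foreground(frame)$foreground
  lab <- EBImage::bwlabel(fg)
  if (max(lab) <= 1) return(fg)
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  lab == which.max(areas)
}

#' Remove the sample-holder contour from a UV frame
#'
#' Pixels inside the holder silhouette, dilated by `band_px`, are replaced
#' by the frame's background estimate; every pixel outside the band is
#' passed through bit-exactly. Removing the (often brightly reflecting)
#' loop before segmentation is what lets a crystal dimmer than the loop be
#' found at all.
#'
#' @param uv_frame the UV [new_frame()].
#' @param loop_mask logical matrix: the holder silhouette registered to
#'   this frame's angle (e.g. [loop_silhouette()] of the visible frame at
#'   the same omega). `NULL` logs a warning and returns the frame
#'   unchanged (degraded mode).
#' @param band_px dilation radius of the removal band, pixels.
#' @return A [new_frame()] with the holder band replaced.
#' @export
remove_loop_model <- function(uv_frame, loop_mask, band_px = 3) {
  assert_frame(uv_frame)
  if (is.null(loop_mask)) {
    warn_uvc("no loop geometry available: frame returned unchanged",
             class = "uvc_degraded")
    return(uv_frame)
  }
  if (!identical(dim(loop_mask), dim(uv_frame$pixels)))
    stop_uvc("loop mask not congruent with frame")
  band <- EBImage::dilate(loop_mask + 0,
                          EBImage::makeBrush(2 * band_px + 1, "disc")) > 0
  px <- uv_frame$pixels
  px[band] <- estimate_background(px)
  out <- uv_frame
  out$pixels <- px
  out$loop_band <- band
  out
}

# Sub-pixel extent of a component: interpolated zero-crossing span of the
# LoG response along the row (width) and column (height) through the
# intensity centre of mass — the external-edge scans through the centred
# crystal. Exact for the convex crystal outlines the pipeline targets;
# falls back to the component bounding box when a scan finds fewer than
# two qualifying crossings.
subpixel_extent <- function(resp, comp, centroid, thr) {
  nr <- nrow(resp); nc <- ncol(resp)
  near <- EBImage::dilate(comp + 0, EBImage::makeBrush(3, "box")) > 0
  span_at <- function(ix, pos, centre) {
    sel <- abs(ix - centre) <= 1
    if (sum(sel) >= 2) diff(range(pos[sel])) else NA_real_
  }
  a <- resp[, -nc]; b <- resp[, -1]
  ch <- which(sign(a) * sign(b) < 0 & abs(a - b) >= thr &
                (near[, -nc] | near[, -1]), arr.ind = TRUE)
  width <- NA_real_
  if (nrow(ch)) {
    ra <- abs(resp[cbind(ch[, 1], ch[, 2])])
    rb <- abs(resp[cbind(ch[, 1], ch[, 2] + 1)])
    width <- span_at(ch[, 1], (ch[, 2] - 1) + ra / (ra + rb),
                     round(centroid[1]) + 1)
  }
  a <- resp[-nr, ]; b <- resp[-1, ]
  cv <- which(sign(a) * sign(b) < 0 & abs(a - b) >= thr &
                (near[-nr, ] | near[-1, ]), arr.ind = TRUE)
  height <- NA_real_
  if (nrow(cv)) {
    ra <- abs(resp[cbind(cv[, 1], cv[, 2])])
    rb <- abs(resp[cbind(cv[, 1] + 1, cv[, 2])])
    height <- span_at(cv[, 2], (cv[, 1] - 1) + ra / (ra + rb),
                      round(centroid[2]) + 1)
  }
  idx <- which(comp, arr.ind = TRUE)
  if (!is.finite(width)) width <- diff(range(idx[, 2]))
  if (!is.finite(height)) height <- diff(range(idx[, 1]))
  c(width = width, height = height)
}

#' Segment the crystal from a loop-removed UV frame
#'
#' Zero-crossing edge contours are closed curves by construction; they are
#' filled, and among the filled components the largest one whose mean
#' interior intensity exceeds the background estimate is taken as the
#' crystal (ties broken by proximity to the beam centre). The crystal size
#' is delimited by its external edges: the sub-pixel interpolated
#' zero-crossing span along the horizontal and vertical scans through the
#' centre of mass, which is itself the intensity-weighted centroid of the
#' interior pixels.
#'
#' @param frame the UV [new_frame()], after [remove_loop_model()].
#' @param edges a [log_edge_map()] of that frame.
#' @param beam_centre_px 0-based `(row, col)` used only to break ties
#'   between equally-sized candidates; default frame centre.
#' @return An object of class `uvc_crystal_measure`: `contour_px` (closed
#'   0-based row/col polygon), `centroid_px`, `extent_px` and `extent_um`
#'   (width, height), `mean_interior_intensity`, `interior` (logical
#'   mask), `area_px`.
#' @export
segment_crystal <- function(frame, edges, beam_centre_px = NULL) {
  assert_frame(frame)
  if (!inherits(edges, "uvc_edge_map"))
    stop_uvc("'edges' must come from log_edge_map()")
  px <- frame$pixels
  if (!identical(dim(edges$edges), dim(px)))
    stop_uvc("edge map not congruent with frame")
  if (is.null(beam_centre_px)) beam_centre_px <- default_beam_centre(frame)
  bg <- estimate_background(px)
  # robust background spread: a region only qualifies when its mean clears
  # the background by 3 sigma, so flat noise patches enclosed by spurious
  # crossings are not mistaken for a crystal
  bg_sd <- stats::mad(px[px <= stats::quantile(px, 0.5)], center = bg)
  qualify_floor <- bg + 3 * bg_sd

  filled <- EBImage::fillHull(edges$edges + 0) > 0
  lab <- EBImage::bwlabel(filled)
  nlab <- max(lab)
  if (nlab == 0)
    stop_uvc("no closed edge contour found: no crystal detected",
             class = "uvc_no_crystal")

  best <- NULL
  for (l in seq_len(nlab)) {
    comp <- lab == l
    interior <- comp & !edges$edges
    if (!any(interior)) interior <- comp
    m <- mean(px[interior])
    if (m <= qualify_floor) next
    area <- sum(comp)
    idx <- which(interior, arr.ind = TRUE)
    w <- px[interior]
    cen <- c(row = sum((idx[, 1] - 1) * w) / sum(w),
             col = sum((idx[, 2] - 1) * w) / sum(w))
    d2 <- sum((cen - beam_centre_px)^2)
    if (is.null(best) || area > best$area ||
        (area == best$area && d2 < best$d2))
      best <- list(l = l, comp = comp, interior = interior, area = area,
                   mean = m, cen = cen, d2 = d2)
  }
  if (is.null(best))
    stop_uvc("no contour encloses intensity above background: no crystal",
             class = "uvc_no_crystal")

  ext_px <- subpixel_extent(edges$response, best$comp, best$cen,
                            edges$params$zero_crossing_threshold)
  oc <- EBImage::ocontour(best$comp + 0)[[1]]
  structure(
    list(contour_px = cbind(row = oc[, 1], col = oc[, 2]),
         centroid_px = best$cen,
         extent_px = ext_px,
         extent_um = ext_px * frame$pixel_size_um,
         mean_interior_intensity = best$mean,
         interior = best$interior,
         area_px = best$area),
    class = "uvc_crystal_measure"
  )
}

#' @export
print.uvc_crystal_measure <- function(x, ...) {
  cat(sprintf(
    "<uvc_crystal_measure> centroid (row %.2f, col %.2f) px, %.1f x %.1f um\n",
    x$centroid_px[1], x$centroid_px[2], x$extent_um[1], x$extent_um[2]))
  cat(sprintf("  area %d px, mean interior intensity %.4g\n",
              x$area_px, x$mean_interior_intensity))
  invisible(x)
}

#' Horizontal and vertical intensity scans through a point
#'
#' @param frame a [new_frame()].
#' @param point_px 0-based `(row, col)` inside the frame.
#' @return An object of class `uvc_line_scans`: `horizontal` (intensity vs
#'   column through the point's row), `vertical` (intensity vs row),
#'   `point_px`.
#' @export
line_scans <- function(frame, point_px) {
  assert_frame(frame)
  d <- dim(frame$pixels)
  r <- round(point_px[1]) + 1; cc <- round(point_px[2]) + 1
  if (r < 1 || r > d[1] || cc < 1 || cc > d[2])
    stop_uvc("scan point outside frame")
  structure(list(horizontal = frame$pixels[r, ],
                 vertical = frame$pixels[, cc],
                 point_px = c(row = r - 1, col = cc - 1),
                 illumination = frame$illumination),
            class = "uvc_line_scans")
}

#' @export
plot.uvc_line_scans <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(x$horizontal) - 1, x$horizontal, type = "l",
                 xlab = "column (px)", ylab = "intensity",
                 main = sprintf("horizontal scan (%s)", x$illumination), ...)
  graphics::abline(v = x$point_px[2], col = "red", lty = 2)
  graphics::plot(seq_along(x$vertical) - 1, x$vertical, type = "l",
                 xlab = "row (px)", ylab = "intensity",
                 main = "vertical scan", ...)
  graphics::abline(v = x$point_px[1], col = "red", lty = 2)
  invisible(x)
}

#' Crystal/background contrast ratio
#'
#' Mean intensity inside the measured crystal interior divided by the mean
#' background intensity outside the contour (and outside the holder band,
#' when one is recorded on the frame). A zero background mean yields
#' `Inf`.
#'
#' @param frame a [new_frame()] — either the UV frame the measure came
#'   from, or the paired visible frame for comparison.
#' @param measure a [segment_crystal()] result (regions are reused on the
#'   paired frame).
#' @return Non-negative scalar ratio.
#' @export
contrast_score <- function(frame, measure) {
  assert_frame(frame)
  if (!inherits(measure, "uvc_crystal_measure"))
    stop_uvc("'measure' must come from segment_crystal()")
  if (!identical(dim(measure$interior), dim(frame$pixels)))
    stop_uvc("measure not congruent with frame")
  inside <- measure$interior
  outside <- !(EBImage::dilate(inside + 0, EBImage::makeBrush(5, "disc")) > 0)
  if (!is.null(frame$loop_band)) outside <- outside & !frame$loop_band
  mbg <- mean(frame$pixels[outside])
  mint <- mean(frame$pixels[inside])
  if (mbg == 0) return(Inf)
  mint / mbg
}
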