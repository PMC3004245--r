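#' Parametric "neck and shoulders" template mask
#'
#' Binary silhouette template of the feature common to nylon cryoloops and
#' litholoop paddles: the thin mounting-pin neck opening out into the
#' shoulders where the holder widens. The template is generated from the
#' holder parameterization (not from stored images) at a given pixel scale,
#' and can be regenerated at any other scale for matching.
#'
#' @param loop_width_um,loop_height_um,wire_thickness_um holder outer
#'   dimensions, as in [scene_spec()].
#' @param neck_length_um length of pin included before the shoulders.
#' @param shoulder_drop_um how far past the holder's leading edge the
#'   template extends (the "drop" over which the silhouette widens).
#' @param pixel_size_um scale of the template grid.
#' @param supersample rendering supersampling factor.
#' @return An object of class `uvc_pattern_mask`: `template` (0/1 matrix),
#'   `scale_um_per_px`, `params`, `neck_length_px`.
#' @export
pattern_mask <- function(loop_width_um = 220, loop_height_um = 180,
                         wire_thickness_um = 20, neck_length_um = 30,
                         shoulder_drop_um = 60, pixel_size_um = 2,
                         supersample = 4L) {
  stopifnot(loop_width_um > 0, loop_height_um > 0, wire_thickness_um > 0,
            neck_length_um > 0, shoulder_drop_um > 0, pixel_size_um > 0)
  A <- loop_width_um / 2; B <- loop_height_um / 2; t <- wire_thickness_um
  drop <- min(shoulder_drop_um, loop_width_um)
  p <- pixel_size_um; s <- as.integer(supersample)
  w_um <- neck_length_um + drop
  h_um <- loop_height_um + 2 * p          # one-pixel quiet border
  ncpx <- ceiling(w_um / p) + 1L
  nrpx <- ceiling(h_um / p) + 1L
  u <- ((seq_len(ncpx * s) - 0.5) / s - 0.5) * p           # from left edge
  v <- (((seq_len(nrpx * s) - 0.5) / s - 0.5) - (nrpx - 1) / 2) * p
  U <- matrix(u, nrpx * s, ncpx * s, byrow = TRUE)
  V <- matrix(v, nrpx * s, ncpx * s)
  neck <- U <= neck_length_um & abs(V) <= t / 2
  du <- U - neck_length_um - A            # ring centred A past the neck end
  ring <- (du / A)^2 + (V / B)^2 <= 1 &
    (du / (A - t))^2 + (V / (B - t))^2 > 1 &
    U <= neck_length_um + drop
  tmpl <- (block_mean((neck | ring) + 0, s) > 0.5) + 0
  if (sum(tmpl) == 0) stop_uvc("degenerate pattern mask: empty foreground")
  structure(
    list(template = tmpl,
         scale_um_per_px = p,
         neck_length_px = neck_length_um / p,
         params = list(loop_width_um = loop_width_um,
                       loop_height_um = loop_height_um,
                       wire_thickness_um = wire_thickness_um,
                       neck_length_um = neck_length_um,
                       shoulder_drop_um = drop,
                       supersample = s)),
    class = "uvc_pattern_mask"
  )
}

rescale_mask <- function(mask, pixel_size_um) {
  if (isTRUE(all.equal(mask$scale_um_per_px, pixel_size_um))) return(mask)
  do.call(pattern_mask, c(mask$params[setdiff(names(mask$params), "supersample")],
                          list(pixel_size_um = pixel_size_um,
                               supersample = mask$params$supersample)))
}

# Summed-area table; window_sums gives sums of m over all mr x mc windows.
sat <- function(m) {
  P <- rbind(0, cbind(0, m))
  P <- apply(P, 2, cumsum)
  t(apply(P, 1, cumsum))
}

window_sums <- function(m, mr, mc) {
  P <- sat(m)
  nr <- nrow(m) - mr + 1; nc <- ncol(m) - mc + 1
  i <- seq_len(nr); j <- seq_len(nc)
  P[i + mr, j + mc, drop = FALSE] - P[i, j + mc, drop = FALSE] -
    P[i + mr, j, drop = FALSE] + P[i, j, drop = FALSE]
}

# Cross-correlation sums (sum over template support of F * T at every valid
# placement) via zero-padded FFT.
xcorr_sums <- function(f, t) {
  nr <- nrow(f); nc <- ncol(f); mr <- nrow(t); mc <- ncol(t)
  P <- nr + mr - 1; Q <- nc + mc - 1
  fp <- matrix(0, P, Q); fp[1:nr, 1:nc] <- f
  tp <- matrix(0, P, Q); tp[1:mr, 1:mc] <- t
  cc <- Re(stats::fft(stats::fft(fp) * Conj(stats::fft(tp)),
                      inverse = TRUE)) / (P * Q)
  cc[seq_len(nr - mr + 1), seq_len(nc - mc + 1), drop = FALSE]
}

#' Normalized cross-correlation template matching
#'
#' Slides the template over every full placement and scores the normalized
#' cross-correlation (window mean and variance removed on both sides), in
#' `[-1, 1]`. Visible backlight frames are matched on the inverted image so
#' the dark holder silhouette correlates positively with the binary
#' template.
#'
#' @param frame a [new_frame()].
#' @param mask a [pattern_mask()]; regenerated at the frame's pixel scale
#'   if it differs.
#' @param threshold acceptance threshold on the NCC score (default 0.6).
#' @param invert match on `max(frame) - frame`; defaults to `TRUE` for
#'   visible-mode frames.
#' @return An object of class `uvc_match`: `location_px` (0-based row, col
#'   of the best template top-left placement), `score`, `accepted`,
#'   `score_map`, `mask`.
#' @export
match_pattern <- function(frame, mask, threshold = 0.6, invert = NULL) {
  assert_frame(frame)
  if (!inherits(mask, "uvc_pattern_mask"))
    stop_uvc("'mask' must be a pattern_mask()")
  mask <- rescale_mask(mask, frame$pixel_size_um)
  tmpl <- mask$template
  f <- frame$pixels
  if (is.null(invert)) invert <- frame$illumination == "visible"
  if (invert) f <- max(f) - f
  mr <- nrow(tmpl); mc <- ncol(tmpl)
  if (mr > nrow(f) || mc > ncol(f))
    stop_uvc("template larger than frame")
  n <- mr * mc
  tm <- tmpl - mean(tmpl)
  denom_t <- sqrt(sum(tm^2))
  s1 <- window_sums(f, mr, mc)
  s2 <- window_sums(f^2, mr, mc)
  cross <- xcorr_sums(f, tmpl)
  num <- cross - mean(tmpl) * s1
  varw <- pmax(s2 - s1^2 / n, 0)
  denom <- sqrt(varw) * denom_t
  score <- ifelse(denom > 1e-12 * n, num / denom, 0)
  score <- pmin(pmax(score, -1), 1)
  best <- which(score == max(score), arr.ind = TRUE)[1, ]
  structure(
    list(location_px = c(row = unname(best[1]) - 1, col = unname(best[2]) - 1),
         score = max(score),
         accepted = max(score) >= threshold,
         threshold = threshold,
         score_map = score,
         mask = mask),
    class = "uvc_match"
  )
}

#' @export
print.uvc_match <- function(x, ...) {
  cat(sprintf("<uvc_match> score %.4f at (row %g, col %g), %s (threshold %.2f)\n",
              x$score, x$location_px[1], x$location_px[2],
              if (x$accepted) "accepted" else "REJECTED", x$threshold))
  invisible(x)
}

# Gradient magnitude (central differences, replicate borders).
gradient_magnitude <- function(px) {
  nr <- nrow(px); nc <- ncol(px)
  padc <- px[, c(1, seq_len(nc), nc)]
  padr <- px[c(1, seq_len(nr), nr), ]
  gx <- (padc[, 3:(nc + 2)] - padc[, 1:nc]) / 2
  gy <- (padr[3:(nr + 2), ] - padr[1:nr, ]) / 2
  sqrt(gx^2 + gy^2)
}

# Binary edge map from gradient magnitude with an Otsu-selected threshold.
edge_pixels <- function(px, min_dynamic_range = 0.05) {
  g <- gradient_magnitude(px)
  gmax <- max(g)
  if (gmax < min_dynamic_range)
    stop_uvc("no foreground edges above threshold: frame looks empty",
             class = "uvc_no_object")
  thr <- EBImage::otsu(g / gmax, range = c(0, 1)) * gmax
  g > thr
}

#' Detect the sample-holder tip on a visible frame
#'
#' Edge pixels are extracted by gradient-magnitude thresholding with an
#' Otsu-selected threshold; with the pin entering from the image-left edge,
#' the tip lies in the rightmost edge column, at the midpoint of the edge
#' rows found there (the holder is symmetric about its axis, so the
#' midpoint is the axis intersection).
#'
#' @param frame a visible-mode [new_frame()].
#' @param min_dynamic_range gradient floor below which the mount is
#'   declared empty (raises a `uvc_no_object` error).
#' @return An object of class `uvc_tip`: `tip_px` (0-based row, col),
#'   `axis_direction` (unit row/col vector toward the tip),
#'   `edge_pixel_count`.
#' @export
detect_tip <- function(frame, min_dynamic_range = 0.05) {
  assert_frame(frame)
  ed <- edge_pixels(frame$pixels, min_dynamic_range)
  idx <- which(ed, arr.ind = TRUE)
  jmax <- max(idx[, 2])
  rows <- idx[idx[, 2] == jmax, 1]
  structure(
    list(tip_px = c(row = mean(range(rows)) - 1, col = jmax - 1),
         axis_direction = c(row = 0, col = 1),
         edge_pixel_count = nrow(idx)),
    class = "uvc_tip"
  )
}

# Holder silhouette foreground: inverted intensity above Otsu for visible
# backlight, direct intensity above Otsu for UV.
holder_foreground <- function(frame, min_dynamic_range = 0.05) {
  px <- frame$pixels
  if (frame$illumination == "visible") px <- max(px) - px
  rng <- max(px) - min(px)
  if (rng < min_dynamic_range)
    stop_uvc("no foreground: frame looks empty", class = "uvc_no_object")
  w <- (px - min(px)) / rng
  fg <- w > EBImage::otsu(w, range = c(0, 1))
  list(foreground = fg, weight = px)
}

#' Holder bounding box and centre of mass after a pattern match
#'
#' The box spans from the end of the matched neck to the far (tip-side)
#' extent of the holder silhouette component hit by the template; the
#' centre of mass is the intensity-weighted centroid of foreground pixels
#' inside the box (weights are the inverted intensities on visible
#' frames, so the dark silhouette carries the mass).
#'
#' @param frame the matched [new_frame()].
#' @param match an accepted [match_pattern()] result.
#' @return An object of class `uvc_loop_box`: `box_px` 0-based
#'   `(row_min, col_min, row_max, col_max)`, `centre_of_mass_px`,
#'   `n_foreground`.
#' @export
loop_centre <- function(frame, match) {
  assert_frame(frame)
  if (!inherits(match, "uvc_match")) stop_uvc("'match' must be a uvc_match")
  if (!match$accepted)
    stop_uvc("pattern match was not accepted; use fallback_sphere()")
  hf <- holder_foreground(frame)
  fg <- hf$foreground
  lab <- EBImage::bwlabel(fg)
  mr <- nrow(match$mask$template); mc <- ncol(match$mask$template)
  r0 <- match$location_px[["row"]] + 1; c0 <- match$location_px[["col"]] + 1
  patch <- lab[r0:min(r0 + mr - 1, nrow(lab)), c0:min(c0 + mc - 1, ncol(lab))]
  labs <- patch[patch > 0]
  if (length(labs) == 0) stop_uvc("no foreground under the matched template")
  main <- as.integer(names(which.max(table(labs))))
  comp <- lab == main
  col_start <- min(c0 + round(match$mask$neck_length_px), ncol(lab))
  comp[, seq_len(max(col_start - 1, 0))] <- FALSE
  if (!any(comp)) stop_uvc("empty foreground inside the matched box")
  idx <- which(comp, arr.ind = TRUE)
  box <- c(row_min = min(idx[, 1]) - 1, col_min = min(idx[, 2]) - 1,
           row_max = max(idx[, 1]) - 1, col_max = max(idx[, 2]) - 1)
  w <- hf$weight[comp]
  com <- c(row = sum((idx[, 1] - 1) * w) / sum(w),
           col = sum((idx[, 2] - 1) * w) / sum(w))
  structure(list(box_px = box, centre_of_mass_px = com,
                 n_foreground = nrow(idx)),
            class = "uvc_loop_box")
}

#' Spherical fallback model for non-standard holders
#'
#' When no pattern matches (non-standard holders, or a failed match), the
#' sample is assumed spherical with a diameter exactly 1.5 times the widest
#' dimension of the observed foreground, and centred at the foreground
#' centre of mass in each view. The widest dimension is the larger
#' bounding-box extent of the silhouette, maximised over all frames.
#'
#' @param frames list of [new_frame()] objects (>= 1).
#' @param min_dynamic_range empty-frame guard, as in [detect_tip()].
#' @return A list: `diameter_um`, `widest_dimension_um`, `centres_px`
#'   (per-frame 0-based row/col centres of mass), `per_frame_widest_um`.
#' @export
fallback_sphere <- function(frames, min_dynamic_range = 0.05) {
  if (length(frames) < 1) stop_uvc("need at least one frame")
  widest <- numeric(length(frames))
  centres <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    assert_frame(fr)
    hf <- holder_foreground(fr, min_dynamic_range)
    idx <- which(hf$foreground, arr.ind = TRUE)
    if (nrow(idx) == 0)
      stop_uvc("no foreground in frame", class = "uvc_no_object")
    ext_px <- c(diff(range(idx[, 1])) + 1, diff(range(idx[, 2])) + 1)
    widest[k] <- max(ext_px) * fr$pixel_size_um
    w <- hf$weight[hf$foreground]
    centres[[k]] <- c(row = sum((idx[, 1] - 1) * w) / sum(w),
                      col = sum((idx[, 2] - 1) * w) / sum(w))
  }
  W <- max(widest)
  list(diameter_um = 1.5 * W,
       widest_dimension_um = W,
       centres_px = centres,
       per_frame_widest_um = widest)
}

#' Stage-1 alignment: centre the sample holder on the beam
#'
#' Runs tip detection, pattern matching and centre-of-mass extraction on
#' each visible frame, converts the per-angle 2D offsets (holder centre
#' minus beam centre) into observations, and solves the 3D stage move. If
#' the pattern match fails on every frame, the spherical fallback centres
#' are used instead.
#'
#' @param frames list of visible-mode [new_frame()] at >= 2 angles distinct
#'   modulo 180 degrees.
#' @param mask a [pattern_mask()]; default is the standard holder template
#'   at the frames' pixel scale.
#' @param beam_centre_px 0-based `(row, col)`; default frame centre.
#' @param ncc_threshold acceptance threshold for [match_pattern()].
#' @return A list of class `uvc_loop_alignment`: `fit` (a
#'   [solve_centre()] result), `move_um`, `tips`, `matches`, `boxes`,
#'   `used_fallback`, `fallback` (when used).
#' @export
align_loop <- function(frames, mask = NULL, beam_centre_px = NULL,
                       ncc_threshold = 0.6) {
  if (length(frames) < 2)
    stop_uvc("need frames at >= 2 angles", class = "uvc_insufficient_angles")
  angs <- vapply(frames, function(f) f$omega_deg, numeric(1))
  if (angles_degenerate(angs))
    stop_uvc("frame angles are degenerate (all equal mod 180 deg)",
             class = "uvc_insufficient_angles")
  p <- frames[[1]]$pixel_size_um
  if (is.null(beam_centre_px)) beam_centre_px <- default_beam_centre(frames[[1]])
  if (is.null(mask)) mask <- pattern_mask(pixel_size_um = p)

  tips <- lapply(frames, detect_tip)
  matches <- lapply(frames, match_pattern, mask = mask,
                    threshold = ncc_threshold)
  accepted <- vapply(matches, function(m) m$accepted, logical(1))
  used_fallback <- FALSE
  fb <- NULL
  if (!any(accepted) || angles_degenerate(angs[accepted])) {
    used_fallback <- TRUE
    fb <- fallback_sphere(frames)
    centres <- fb$centres_px
    use <- seq_along(frames)
    boxes <- NULL
  } else {
    use <- which(accepted)
    boxes <- lapply(use, function(k) loop_centre(frames[[k]], matches[[k]]))
    centres <- lapply(boxes, function(b) b$centre_of_mass_px)
  }
  dx <- vapply(centres, function(cc) cc[["col"]], numeric(1)) - beam_centre_px[2]
  dy <- vapply(centres, function(cc) cc[["row"]], numeric(1)) - beam_centre_px[1]
  obs <- offset_observations(angs[use], dx, dy, p)
  fit <- solve_centre(obs)
  structure(
    list(fit = fit, move_um = fit$move_um, tips = tips, matches = matches,
         boxes = boxes, used_fallback = used_fallback, fallback = fb,
         beam_centre_px = beam_centre_px),
    class = "uvc_loop_alignment"
  )
}
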