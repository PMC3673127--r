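#' Handwriting kinematics of a decoded response
#'
#' Dynamic aspects of the handwriting captured for later analysis: stroke
#' order and count, per-stroke path length, mean and peak speed, hesitations,
#' lift-offs, and total pen-down time. Speeds are finite-difference arc
#' length over time on the smoothed positions. A hesitation is an in-stroke
#' interval of at least `hesitation_dwell_s` during which the pen stays
#' within one pixel pitch of the interval's first point (the construct is
#' the field's; this dwell/displacement rule is this implementation's
#' operationalization).
#'
#' @param resp A `pad_response` (one element of `decode_stream()$responses`).
#' @param hesitation_dwell_s Minimum dwell duration (default 0.3 s).
#' @return A list of class `stroke_metrics`: `stroke_count`,
#'   `path_length_mm` (per stroke), `mean_speed_mm_s`, `peak_speed_mm_s`,
#'   `hesitations` (data.frame of `t_s`, `duration_s`), `liftoff_count`,
#'   `pen_down_time_s`.
#' @export
compute_metrics <- function(resp, hesitation_dwell_s = 0.3) {
  stopifnot(inherits(resp, "pad_response"), length(resp$strokes) >= 1)
  pitch <- resp$pitch_mm
  path <- numeric(length(resp$strokes))
  peak <- 0
  down_time <- 0
  hes_t <- numeric(0); hes_d <- numeric(0)
  for (s in seq_along(resp$strokes)) {
    st <- resp$strokes[[s]]
    m <- cbind(st$x_mm, st$y_mm)
    nn <- nrow(m)
    if (nn > 1) {
      dseg <- sqrt(rowSums((m[-1, , drop = FALSE] - m[-nn, , drop = FALSE])^2))
      dt <- diff(st$t_s)
      path[s] <- sum(dseg)
      peak <- max(peak, dseg / dt)
      down_time <- down_time + st$t_s[nn] - st$t_s[1]
    }
    # hesitation scan: greedy maximal dwell extents from each anchor
    k <- 1
    while (k <= nn) {
      within <- sqrt((m[, 1] - m[k, 1])^2 + (m[, 2] - m[k, 2])^2) < pitch
      mlim <- k
      while (mlim < nn && within[mlim + 1]) mlim <- mlim + 1
      if (st$t_s[mlim] - st$t_s[k] >= hesitation_dwell_s) {
        hes_t <- c(hes_t, st$t_s[k])
        hes_d <- c(hes_d, st$t_s[mlim] - st$t_s[k])
        k <- mlim + 1
      } else k <- k + 1
    }
  }
  structure(list(
    stroke_count = length(resp$strokes),
    path_length_mm = path,
    mean_speed_mm_s = if (down_time > 0) sum(path) / down_time else 0,
    peak_speed_mm_s = peak,
    hesitations = data.frame(t_s = hes_t, duration_s = hes_d),
    liftoff_count = length(resp$strokes) - 1L,
    pen_down_time_s = down_time),
    class = "stroke_metrics")
}

#' @export
print.stroke_metrics <- function(x, ...) {
  cat(sprintf("%d stroke(s), %d lift-off(s), %.2f s pen-down\n",
              x$stroke_count, x$liftoff_count, x$pen_down_time_s))
  cat(sprintf("  path: %s mm; mean speed %.1f mm/s, peak %.1f mm/s\n",
              paste(sprintf("%.1f", x$path_length_mm), collapse = " + "),
              x$mean_speed_mm_s, x$peak_speed_mm_s))
  cat(sprintf("  hesitations: %d\n", nrow(x$hesitations)))
  invisible(x)
}

# stamp a disc of radius `hw` canvas pixels at (cx, cy) into canvas (0 = ink)
stamp <- function(canvas, cx, cy, hw) {
  n <- nrow(canvas)
  xs <- max(1, floor(cx - hw)):min(n, ceiling(cx + hw))
  ys <- max(1, floor(cy - hw)):min(n, ceiling(cy + hw))
  for (x in xs) for (y in ys)
    if ((x - cx)^2 + (y - cy)^2 <= hw^2) canvas[y, x] <- 0
  canvas
}

#' Rasterize a response to the virtual writing area
#'
#' Draws each stroke as a simple polyline (line width 2 canvas pixels) on a
#' white square canvas, scaled from the usable span. Deterministic: the same
#' record always renders to the same bytes.
#'
#' @param resp A `pad_response` with at least one stroke.
#' @param canvas_px Canvas side in pixels (default 256).
#' @param strokes Which strokes to draw (default all).
#' @return A `canvas_px` x `canvas_px` numeric matrix in \[0, 1\] (1 = white).
#' @export
render_response <- function(resp, canvas_px = 256, strokes = NULL) {
  stopifnot(inherits(resp, "pad_response"), length(resp$strokes) >= 1)
  canvas <- matrix(1, canvas_px, canvas_px)
  span <- resp$usable_span_mm
  org <- resp$origin_mm
  to_px <- function(mm) (mm - org) / span * (canvas_px - 1) + 1
  sel <- if (is.null(strokes)) seq_along(resp$strokes) else strokes
  for (s in sel) {
    st <- resp$strokes[[s]]
    px <- cbind(to_px(st$x_mm), to_px(st$y_mm))
    if (nrow(px) == 1) {
      canvas <- stamp(canvas, px[1, 1], px[1, 2], 1)
      next
    }
    for (k in seq_len(nrow(px) - 1)) {
      d <- sqrt(sum((px[k + 1, ] - px[k, ])^2))
      steps <- max(2, ceiling(d * 2))
      f <- seq(0, 1, length.out = steps)
      for (ff in f)
        canvas <- stamp(canvas, px[k, 1] + ff * (px[k + 1, 1] - px[k, 1]),
                        px[k, 2] + ff * (px[k + 1, 2] - px[k, 2]), 1)
    }
  }
  canvas
}

#' Save a response raster as PNG (lossless) and, when possible, JPEG
#'
#' The deployed system saved the virtual writing area in JPG format; a
#' lossless PNG is written alongside. JPEG writing uses EBImage when
#' installed, otherwise only the PNG is produced.
#'
#' @param resp A `pad_response`.
#' @param basename Output path without extension.
#' @param canvas_px Canvas side in pixels.
#' @return Character vector of files written, invisibly.
#' @export
write_response_images <- function(resp, basename, canvas_px = 256) {
  canvas <- render_response(resp, canvas_px)
  png_path <- paste0(basename, ".png")
  png::writePNG(canvas, png_path)
  written <- png_path
  if (requireNamespace("EBImage", quietly = TRUE)) {
    jpg_path <- paste0(basename, ".jpg")
    EBImage::writeImage(EBImage::Image(t(canvas)), jpg_path, quality = 90)
    written <- c(written, jpg_path)
  }
  invisible(written)
}

#' Straightedge precision experiment
#'
#' Reproduces the system's precision evaluation: the pen is moved along a
#' straightedge across the map at varying positions, and the dispersion
#' (standard deviation) of the decoded coordinate perpendicular to the line
#' is measured, separately for the center-most 50% of the traversal axis and
#' for its outer-most quadrants. Decoding uses raw pixel lookups (no rolling
#' average), so the report reflects quantization plus sensor noise only;
#' zero-noise models report quantization-only dispersion.
#'
#' @param spec A [color_map_spec()].
#' @param model A [sensor_model()] (set its sigmas to 0 for a noiseless run).
#' @param lut An [build_lut()] result for this spec.
#' @param n_lines Traversals per orientation (default 5).
#' @param orientation `"x"` (constant-y lines), `"y"`, or `"both"`.
#' @param traverse_s Duration of each traversal (default 2 s).
#' @param line_offsets Optional explicit perpendicular coordinates of the
#'   lines (mm, frame coordinates); by default `n_lines` evenly spaced
#'   interior positions (the traversals are kept off the exact reachable
#'   limit because the decoded lattice cannot express outward deviations
#'   there, so edge clamping would understate the dispersion).
#' @param seed Base seed; traversal k uses `seed + k`.
#' @return A `straightedge_report`: per-traversal table and pooled
#'   `central_sd_mm` / `outer_sd_mm`.
#' @export
straightedge_experiment <- function(spec, model, lut, n_lines = 5,
                                    orientation = c("both", "x", "y"),
                                    traverse_s = 2, line_offsets = NULL,
                                    seed = 1) {
  orientation <- match.arg(orientation)
  orients <- if (orientation == "both") c("x", "y") else orientation
  lo <- (spec$side_mm - spec$usable_span_mm) / 2
  hi <- lo + spec$usable_span_mm
  span <- spec$usable_span_mm
  offs <- if (is.null(line_offsets))
    seq(lo, hi, length.out = n_lines + 2)[seq_len(n_lines) + 1]
  else line_offsets
  rows <- list()
  res_central <- numeric(0); res_outer <- numeric(0)
  k <- 0
  for (ori in orients) {
    for (off in offs) {
      k <- k + 1
      wp <- if (ori == "x") rbind(c(lo, off), c(hi, off))
            else rbind(c(off, lo), c(off, hi))
      stream <- simulate_stream(spec, model,
                                pen_script(pen_down(wp, traverse_s)),
                                seed = seed + k)
      chroma <- normalize_chroma(
        cbind(stream$r_counts, stream$g_counts, stream$b_counts), on_zero = "na")
      pix <- lut_lookup(lut, chroma)
      mm <- pixel_to_mm(lut, pix)
      truth <- attr(stream, "truth")
      along_true <- if (ori == "x") truth$x_mm else truth$y_mm
      perp_dec <- if (ori == "x") mm[, 2] else mm[, 1]
      keep <- !is.na(perp_dec)
      resid <- perp_dec[keep] - off
      along <- along_true[keep]
      central <- along >= lo + 0.25 * span & along <= lo + 0.75 * span
      rows[[k]] <- data.frame(
        orientation = ori, line_mm = off, n = sum(keep),
        n_offmap = sum(!keep),
        central_sd_mm = if (sum(central) > 1) stats::sd(resid[central]) else NA_real_,
        outer_sd_mm = if (sum(!central) > 1) stats::sd(resid[!central]) else NA_real_)
      res_central <- c(res_central, resid[central])
      res_outer <- c(res_outer, resid[!central])
    }
  }
  structure(list(
    traversals = do.call(rbind, rows),
    central_sd_mm = stats::sd(res_central),
    outer_sd_mm = stats::sd(res_outer),
    pitch_mm = lut$pitch_mm,
    n_central = length(res_central), n_outer = length(res_outer)),
    class = "straightedge_report")
}

#' @export
print.straightedge_report <- function(x, ...) {
  cat("Straightedge precision report\n")
  cat(sprintf("  pixel pitch: %.4g mm\n", x$pitch_mm))
  cat(sprintf("  central 50%%: s.d. %.3g mm over %d samples (%s)\n",
              x$central_sd_mm, x$n_central,
              if (is.finite(x$central_sd_mm) && x$central_sd_mm < x$pitch_mm)
                "sub-pixel" else "not sub-pixel"))
  cat(sprintf("  outer quadrants: s.d. %.3g mm over %d samples\n",
              x$outer_sd_mm, x$n_outer))
  print(x$traversals, digits = 3)
  invisible(x)
}
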