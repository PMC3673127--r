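#' Deterministic fixture trajectory scripts
#'
#' A small library of pen scripts with known ground truth, used for
#' end-to-end testing and demonstration: the letters "H" (three strokes),
#' "T" (two strokes), "c" and "b" (one stroke each), a straightedge set of
#' constant-y traversals spanning the usable area, and a hesitation scenario
#' (a single stroke with a 1 s stationary mid-stroke dwell). Every script's
#' waypoints lie within the usable span; each carries a `truth` attribute
#' with its stroke count and nominal pen-down path length.
#'
#' @param spec A [color_map_spec()]; letter geometry scales with the usable
#'   span.
#' @param speed_mm_s Nominal writing speed (default 70 mm/s).
#' @return A named list: scripts for `H`, `T`, `c`, `b`, `hesitation`, and
#'   `straightedge` (itself a list of single-traversal scripts).
#' @export
fixture_scripts <- function(spec = color_map_spec(), speed_mm_s = 70) {
  lo <- (spec$side_mm - spec$usable_span_mm) / 2
  span <- spec$usable_span_mm
  u <- function(fx, fy) c(lo + fx * span, lo + fy * span)  # fractional coords
  dur <- function(wp) {
    len <- sum(sqrt(rowSums((wp[-1, , drop = FALSE] - wp[-nrow(wp), , drop = FALSE])^2)))
    max(len / speed_mm_s, 0.2)
  }
  seg <- function(...) { wp <- rbind(...); pen_down(wp, dur(wp)) }
  with_truth <- function(script, strokes, path_mm) {
    attr(script, "truth") <- list(strokes = strokes, path_mm = path_mm)
    script
  }

  H <- with_truth(pen_script(
    seg(u(0.30, 0.20), u(0.30, 0.80)),
    pen_up(0.4),
    seg(u(0.70, 0.20), u(0.70, 0.80)),
    pen_up(0.4),
    seg(u(0.30, 0.50), u(0.70, 0.50)),
    pen_up(1.5)),
    strokes = 3, path_mm = (0.6 + 0.6 + 0.4) * span)

  T_ <- with_truth(pen_script(
    seg(u(0.30, 0.20), u(0.70, 0.20)),
    pen_up(0.4),
    seg(u(0.50, 0.20), u(0.50, 0.80)),
    pen_up(1.5)),
    strokes = 2, path_mm = (0.4 + 0.6) * span)

  arc <- function(cx, cy, r, a0, a1, n = 24) {
    a <- seq(a0, a1, length.out = n) * pi / 180
    cbind(cx + r * cos(a), cy + r * sin(a))
  }
  ctr <- u(0.5, 0.5)
  c_wp <- arc(ctr[1], ctr[2], 0.25 * span, 45, 315)
  c_scr <- with_truth(pen_script(pen_down(c_wp, dur(c_wp)), pen_up(1.5)),
                      strokes = 1,
                      path_mm = sum(sqrt(rowSums(diff(c_wp)^2))))

  stem_top <- u(0.35, 0.20); stem_bot <- u(0.35, 0.80)
  bowl <- arc(lo + 0.45 * span, lo + 0.665 * span, 0.135 * span, 120, -120)
  b_wp <- rbind(stem_top, stem_bot, bowl)
  b_scr <- with_truth(pen_script(pen_down(b_wp, dur(b_wp)), pen_up(1.5)),
                      strokes = 1,
                      path_mm = sum(sqrt(rowSums(diff(b_wp)^2))))

  hes_mid <- u(0.50, 0.50)
  hesitation <- with_truth(pen_script(
    pen_down(rbind(u(0.20, 0.50), hes_mid), 0.3 * span / speed_mm_s),
    pen_down(matrix(hes_mid, 1), 1.0),
    pen_down(rbind(hes_mid, u(0.80, 0.50)), 0.3 * span / speed_mm_s),
    pen_up(1.5)),
    strokes = 1, path_mm = 0.6 * span)

  ys <- seq(lo, lo + span, length.out = 5)
  straightedge <- lapply(ys, function(y) {
    scr <- pen_script(pen_down(rbind(c(lo, y), c(lo + span, y)),
                               span / speed_mm_s))
    attr(scr, "truth") <- list(strokes = 1, path_mm = span, line_y_mm = y)
    scr
  })
  names(straightedge) <- sprintf("y_%03.0fmm", ys)

  scripts <- list(H = H, T = T_, c = c_scr, b = b_scr,
                  hesitation = hesitation, straightedge = straightedge)
  for (nm in c("H", "T", "c", "b", "hesitation")) validate_script(spec, scripts[[nm]])
  for (s in straightedge) validate_script(spec, s)
  scripts
}
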