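#' Define a pigment-gradient color map
#'
#' Constructs the specification of the printed color map: a square frame
#' carrying three overlapping linear pigment gradients (cyan, magenta,
#' yellow), one per printer pigment, with gradient axes oriented 120 degrees
#' apart. Each pigment varies linearly along its axis from `low_byte` (at
#' axis projection 0) to `high_byte` (at projection `side_mm`) and is
#' constant perpendicular to the axis. Restricting the gradients to an
#' interior byte sub-range avoids both pigment saturation and the
#' near-white region where channel sensitivity is poor.
#'
#' Coordinates: origin at the map's top-left corner (the frame's marked top
#' edge), x rightward, y downward, units mm; positions are real-valued.
#'
#' @param side_mm Side length of the square frame in mm (default 200, i.e.
#'   a 20 cm frame).
#' @param usable_span_mm Central span reachable by the pen center in mm
#'   (default 140; the guide disc keeps the pen within the central 14 cm).
#' @param angles_deg Gradient axis angles in degrees from the +x axis, one
#'   per pigment in the order cyan, magenta, yellow. Must be pairwise 120
#'   degrees apart (mod 360).
#' @param low_byte,high_byte Per-pigment gradient endpoints, byte values in
#'   0--255 with `low_byte < high_byte`; scalars are recycled to all three
#'   pigments. Defaults `0x20`/`0xD0`.
#' @param off_map_color RGB byte triple returned for positions outside the
#'   frame (default pure white, `c(255, 255, 255)`).
#' @return An object of class `color_map_spec`.
#' @examples
#' spec <- color_map_spec()
#' ideal_color_at(spec, cbind(100, 100))  # neutral gray at the map center
#' @export
color_map_spec <- function(side_mm = 200, usable_span_mm = 140,
                           angles_deg = c(cyan = 0, magenta = 120, yellow = 240),
                           low_byte = 0x20, high_byte = 0xD0,
                           off_map_color = c(255, 255, 255)) {
  stopifnot(is.numeric(side_mm), length(side_mm) == 1, side_mm > 0)
  if (!(usable_span_mm > 0 && usable_span_mm <= side_mm))
    stop("usable_span_mm must satisfy 0 < usable_span_mm <= side_mm")
  if (length(angles_deg) != 3)
    stop("exactly one gradient per pigment: angles_deg must have length 3")
  a <- sort(angles_deg %% 360)
  gaps <- unname(sort(round(diff(c(a, a[1] + 360)), 6)))
  if (!isTRUE(all.equal(gaps, c(120, 120, 120))))
    stop("gradient axis angles must be pairwise 120 degrees apart")
  low_byte <- rep_len(low_byte, 3)
  high_byte <- rep_len(high_byte, 3)
  if (any(low_byte < 0 | high_byte > 255 | low_byte >= high_byte))
    stop("gradient byte ranges must satisfy 0 <= low_byte < high_byte <= 255")
  stopifnot(length(off_map_color) == 3, all(off_map_color >= 0 & off_map_color <= 255))
  gradients <- data.frame(
    pigment = c("cyan", "magenta", "yellow"),
    angle_deg = as.numeric(angles_deg),
    low_byte = as.numeric(low_byte),
    high_byte = as.numeric(high_byte),
    stringsAsFactors = FALSE
  )
  structure(
    list(side_mm = as.numeric(side_mm),
         usable_span_mm = as.numeric(usable_span_mm),
         gradients = gradients,
         off_map_color = as.numeric(off_map_color)),
    class = "color_map_spec"
  )
}

#' @export
print.color_map_spec <- function(x, ...) {
  cat("Color map specification\n")
  cat(sprintf("  frame: %g mm square, usable span %g mm (centered)\n",
              x$side_mm, x$usable_span_mm))
  g <- x$gradients
  for (k in seq_len(3))
    cat(sprintf("  %-7s gradient: axis %g deg, bytes [0x%02X, 0x%02X]\n",
                g$pigment[k], g$angle_deg[k], g$low_byte[k], g$high_byte[k]))
  cat(sprintf("  off-map color: #%02X%02X%02X\n",
              x$off_map_color[1], x$off_map_color[2], x$off_map_color[3]))
  cat(sprintf("  spec hash: %s\n", spec_hash(x)))
  invisible(x)
}

as_xy_matrix <- function(position) {
  if (is.null(dim(position))) {
    if (length(position) != 2) stop("position must be an (x, y) pair or an n x 2 matrix")
    position <- matrix(position, ncol = 2)
  }
  xy <- as.matrix(position)
  if (ncol(xy) != 2) stop("position must have two columns (x_mm, y_mm)")
  storage.mode(xy) <- "double"
  xy
}

in_map <- function(spec, xy) {
  xy[, 1] >= 0 & xy[, 1] <= spec$side_mm & xy[, 2] >= 0 & xy[, 2] <= spec$side_mm
}

#' Continuous pigment field of a color map
#'
#' Evaluates the three pigment gradients at planar positions. Pigment k has
#' unit axis vector u_k = (cos a_k, sin a_k); the scalar axis projection of a
#' position p is `(p - center) . u_k + side_mm/2`, so the projection spans
#' `[0, side_mm]` across the frame along the axis direction. The pigment value
#' ramps linearly from `low_byte` at projection 0 to `high_byte` at projection
#' `side_mm`, clamped at the range ends (clamping can only engage in the frame
#' corners, outside the usable span), and is constant perpendicular to the
#' axis. Values are returned unrounded; byte rounding happens at raster time.
#'
#' Because the three unit axis vectors sum to zero, the three projections sum
#' to a constant, so total pigment (C+M+Y) — and hence total reflected signal
#' — is constant over the unclamped map. This is what makes the channel sum a
#' pure luminance measure and chromaticity an injective function of position.
#'
#' @param spec A [color_map_spec()].
#' @param position An (x, y) pair in mm or an n x 2 matrix of positions.
#' @return An n x 3 numeric matrix of continuous CMY values (byte scale).
#'   Positions outside the frame are an error; use [ideal_color_at()] for
#'   off-map substitution.
#' @export
pigment_field <- function(spec, position) {
  xy <- as_xy_matrix(position)
  if (!all(in_map(spec, xy)))
    stop("position outside the map frame; off-map positions have no pigment value")
  ctr <- spec$side_mm / 2
  a <- spec$gradients$angle_deg * pi / 180
  out <- matrix(NA_real_, nrow(xy), 3,
                dimnames = list(NULL, c("C", "M", "Y")))
  for (k in seq_len(3)) {
    s <- (xy[, 1] - ctr) * cos(a[k]) + (xy[, 2] - ctr) * sin(a[k]) + ctr
    frac <- pmin(pmax(s / spec$side_mm, 0), 1)
    out[, k] <- spec$gradients$low_byte[k] +
      (spec$gradients$high_byte[k] - spec$gradients$low_byte[k]) * frac
  }
  out
}

#' Ideal printed color at a position
#'
#' Converts the pigment field to RGB with the ideal subtractive complement
#' `R = 255 - C`, `G = 255 - M`, `B = 255 - Y`. Any strictly monotone
#' channel-wise printer model would preserve the decoding algorithm; the
#' complement is the simplest invertible choice. Positions outside the frame
#' return the spec's `off_map_color`.
#'
#' @inheritParams pigment_field
#' @return An n x 3 numeric matrix of continuous RGB values (byte scale,
#'   unrounded).
#' @export
ideal_color_at <- function(spec, position) {
  xy <- as_xy_matrix(position)
  ok <- in_map(spec, xy)
  out <- matrix(rep(spec$off_map_color, each = nrow(xy)), nrow(xy), 3)
  colnames(out) <- c("R", "G", "B")
  if (any(ok))
    out[ok, ] <- 255 - pigment_field(spec, xy[ok, , drop = FALSE])
  out
}

round_half_up <- function(x) floor(x + 0.5)

#' Render the color map to a raster
#'
#' Samples [ideal_color_at()] at pixel centers and rounds (half-up) to byte
#' levels, producing the image that would be sent to the printer.
#'
#' @inheritParams pigment_field
#' @param dots_per_mm Raster resolution; default 11.81 (about 300 DPI).
#' @return An integer array of dimension `c(n_px, n_px, 3)` with byte values
#'   in 0--255; rows index y (top edge first), columns x.
#' @export
render_map_raster <- function(spec, dots_per_mm = 11.81) {
  if (!is.numeric(dots_per_mm) || length(dots_per_mm) != 1 || dots_per_mm <= 0)
    stop("dots_per_mm must be a positive number")
  n <- as.integer(round(spec$side_mm * dots_per_mm))
  centers <- (seq_len(n) - 0.5) / dots_per_mm
  xy <- cbind(rep(centers, times = n), rep(centers, each = n))  # x fast, y slow
  rgb <- round_half_up(ideal_color_at(spec, xy))
  arr <- array(0L, c(n, n, 3))
  for (ch in 1:3) arr[, , ch] <- matrix(as.integer(rgb[, ch]), n, n, byrow = TRUE)
  attr(arr, "dots_per_mm") <- dots_per_mm
  arr
}

#' Write a rendered map raster as a PNG with a spec sidecar
#'
#' @param raster Output of [render_map_raster()].
#' @param spec The [color_map_spec()] it was rendered from.
#' @param path Output PNG path; the sidecar is written next to it with
#'   extension `.spec.txt`.
#' @return Invisibly, the sidecar path.
#' @export
write_map_png <- function(raster, spec, path) {
  png::writePNG(raster / 255, path)
  sidecar <- paste0(sub("\\.png$", "", path), ".spec.txt")
  write_map_spec(spec, sidecar)
  invisible(sidecar)
}

#' Reachable pen-center span of the frame
#'
#' The guide disc glued to the pen cannot cross the frame edge, so the pen
#' center can only reach `side_mm - disc_diameter_mm` along each axis.
#' With the 20 cm frame and the 2-inch disc this is 149.2 mm, which is why a
#' central 140 mm usable span is a safe default.
#'
#' @param side_mm Frame side in mm.
#' @param disc_diameter_mm Guide disc diameter in mm (default 50.8 = 2 in).
#' @return Reachable span of the pen center, in mm.
#' @export
reachable_span_mm <- function(side_mm = 200, disc_diameter_mm = 50.8) {
  stopifnot(side_mm > disc_diameter_mm)
  side_mm - disc_diameter_mm
}

#' Pixel pitch of the decoded lattice
#'
#' @param usable_span_mm Usable span in mm.
#' @param pixels_per_axis Number of decoded pixels per axis.
#' @return Physical pixel pitch in mm (span / pixels).
#' @export
pixel_pitch_mm <- function(usable_span_mm = 140, pixels_per_axis = 32) {
  stopifnot(usable_span_mm > 0, pixels_per_axis >= 1)
  usable_span_mm / pixels_per_axis
}

# FNV-1a 32-bit over the canonical spec string; pure-R 32-bit arithmetic.
fnv1a32 <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    h0 <- h %% 65536; h1 <- h %/% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)), sprintf("%04x", as.integer(h %% 65536)))
}

# bitwXor for doubles in [0, 2^32)
bitwXor_dbl <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}

#' Content hash of a color-map spec
#'
#' Chained artifacts (calibration tables, lookup tables, sensor logs) carry
#' this hash so that stages refuse to combine artifacts built against
#' different maps.
#'
#' @param spec A [color_map_spec()].
#' @return An 8-character lowercase hex string.
#' @export
spec_hash <- function(spec) {
  stopifnot(inherits(spec, "color_map_spec"))
  canon <- paste(
    sprintf("%.10g", c(spec$side_mm, spec$usable_span_mm,
                       spec$gradients$angle_deg, spec$gradients$low_byte,
                       spec$gradients$high_byte, spec$off_map_color)),
    collapse = "|")
  fnv1a32(canon)
}

#' Write / read a map spec as a flat key-value text file
#'
#' @param spec A [color_map_spec()].
#' @param path File path.
#' @return `write_map_spec` returns the path invisibly; `read_map_spec`
#'   returns a [color_map_spec()].
#' @export
write_map_spec <- function(spec, path) {
  g <- spec$gradients
  lines <- c(
    sprintf("side_mm = %.10g", spec$side_mm),
    sprintf("usable_span_mm = %.10g", spec$usable_span_mm),
    sprintf("%s_angle_deg = %.10g", g$pigment, g$angle_deg),
    sprintf("%s_low_byte = %.10g", g$pigment, g$low_byte),
    sprintf("%s_high_byte = %.10g", g$pigment, g$high_byte),
    sprintf("off_map_color = %d,%d,%d", spec$off_map_color[1],
            spec$off_map_color[2], spec$off_map_color[3])
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_map_spec
#' @export
read_map_spec <- function(path) {
  kv <- read_key_value(path)
  num <- function(key) as.numeric(kv[[key]])
  color_map_spec(
    side_mm = num("side_mm"),
    usable_span_mm = num("usable_span_mm"),
    angles_deg = c(cyan = num("cyan_angle_deg"),
                   magenta = num("magenta_angle_deg"),
                   yellow = num("yellow_angle_deg")),
    low_byte = c(num("cyan_low_byte"), num("magenta_low_byte"),
                 num("yellow_low_byte")),
    high_byte = c(num("cyan_high_byte"), num("magenta_high_byte"),
                  num("yellow_high_byte")),
    off_map_color = as.numeric(strsplit(kv[["off_map_color"]], ",")[[1]])
  )
}
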