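#' Chromaticity normalization
#'
#' Divides each of the raw (R, G, B) counts by the channel sum, removing the
#' overall luminance so that position decoding is immune to fiber bending,
#' supply variation, map wear, and any other shared multiplicative artifact.
#' The result sums to 1 per sample.
#'
#' @param counts A length-3 vector or n x 3 matrix of non-negative raw counts.
#' @param on_zero What to do with an all-zero sample: `"error"` (default;
#'   an all-zero read is an invalid sample) or `"na"` (return an NA row, used
#'   by the decoder, which treats invalid samples as pen-up).
#' @return A vector/matrix of the same shape with rows summing to 1.
#' @examples
#' normalize_chroma(c(100, 200, 100))  # 0.25 0.50 0.25
#' @export
normalize_chroma <- function(counts, on_zero = c("error", "na")) {
  on_zero <- match.arg(on_zero)
  vec <- is.null(dim(counts))
  m <- if (vec) matrix(counts, ncol = 3) else as.matrix(counts)
  if (ncol(m) != 3) stop("counts must have three channels")
  if (any(m < 0)) stop("counts must be non-negative")
  s <- rowSums(m)
  bad <- s <= 0
  if (any(bad) && on_zero == "error")
    stop("invalid sample: all channels zero (no light reaching the sensor)")
  s[bad] <- NA_real_
  out <- m / s
  colnames(out) <- c("r", "g", "b")
  if (vec) drop(out) else out
}

#' Calibration grid positions
#'
#' The guided calibration prompts the user to place the pen at a regular
#' `grid_n` x `grid_n` lattice of marked positions spanning the usable area
#' (endpoints on the usable-span boundary), in row-major order starting at
#' the top edge. A 5 x 5 grid is the default compromise between exhaustive
#' sampling and quick recalibration; at least 3 points per axis are needed
#' for the quadratic fits.
#'
#' @param spec A [color_map_spec()].
#' @param grid_n Points per axis (default 5, minimum 3).
#' @return A `grid_n^2` x 2 matrix of (x_mm, y_mm) frame coordinates,
#'   row-major, top-left corner first.
#' @export
calibration_grid <- function(spec, grid_n = 5) {
  if (grid_n < 3) stop("grid_n must be >= 3: quadratic fits need 3 points per axis")
  lo <- (spec$side_mm - spec$usable_span_mm) / 2
  ax <- seq(lo, lo + spec$usable_span_mm, length.out = grid_n)
  out <- cbind(x_mm = rep(ax, times = grid_n), y_mm = rep(ax, each = grid_n))
  out
}

#' Collect a calibration table from a sample source
#'
#' For each prompted position, draws `samples_per_point` raw reads from the
#' sample source, discards invalid (all-zero) reads, normalizes each read to
#' chromaticity, averages, and renormalizes the mean to sum 1. Normalizing
#' before averaging makes each point estimate robust to per-sample luminance.
#'
#' @param sampler A function `(position, n)` returning an n x 3 matrix of raw
#'   counts at that position — typically a closure over [read_counts()] for
#'   the simulator, or a replay of a hardware log.
#' @param positions Grid positions from [calibration_grid()].
#' @param samples_per_point Reads averaged per point (default 30, about one
#'   second at 30 samples/s).
#' @param spec Optional [color_map_spec()]; records geometry and the spec
#'   hash in the table so downstream stages can verify provenance.
#' @param grid_n Points per axis (inferred from `positions` if square).
#' @return An object of class `calibration_table`.
#' @export
collect_calibration <- function(sampler, positions, samples_per_point = 30,
                                spec = NULL, grid_n = NULL) {
  positions <- as_xy_matrix(positions)
  n_pts <- nrow(positions)
  if (is.null(grid_n)) {
    grid_n <- as.integer(round(sqrt(n_pts)))
    if (grid_n * grid_n != n_pts)
      stop("positions do not form a square grid; supply grid_n explicitly")
  }
  chroma <- matrix(NA_real_, n_pts, 3, dimnames = list(NULL, c("r", "g", "b")))
  for (p in seq_len(n_pts)) {
    raw <- sampler(positions[p, ], samples_per_point)
    raw <- matrix(as.numeric(raw), ncol = 3)
    valid <- rowSums(raw) > 0
    if (sum(valid) < samples_per_point)
      stop(sprintf(
        "calibration aborted: point %d at (%g, %g) mm yielded %d valid samples (need %d)",
        p, positions[p, 1], positions[p, 2], sum(valid), samples_per_point))
    ch <- normalize_chroma(raw[valid, , drop = FALSE][seq_len(samples_per_point), ,
                                                      drop = FALSE])
    m <- colMeans(ch)
    chroma[p, ] <- m / sum(m)
  }
  structure(
    list(positions = positions, chroma = chroma, grid_n = grid_n,
         samples_per_point = samples_per_point,
         side_mm = if (!is.null(spec)) spec$side_mm else NA_real_,
         usable_span_mm = if (!is.null(spec)) spec$usable_span_mm else NA_real_,
         map_spec_hash = if (!is.null(spec)) spec_hash(spec) else NA_character_),
    class = "calibration_table")
}

#' Run a simulated guided calibration
#'
#' Convenience wrapper: builds the [calibration_grid()], simulates stationary
#' reads at each prompted point with the given sensor model (shared luminance
#' walk and per-sample noise, as in [simulate_stream()]), and collects the
#' table.
#'
#' @inheritParams read_counts
#' @inheritParams collect_calibration
#' @param grid_n Points per axis.
#' @param seed Seed for the simulated sensor noise.
#' @return A `calibration_table`.
#' @export
simulate_calibration <- function(spec, model, grid_n = 5, samples_per_point = 30,
                                 seed = 1) {
  positions <- calibration_grid(spec, grid_n)
  with_seed(seed, {
    sampler <- function(position, n) {
      base <- spot_color(spec, model, matrix(position, 1))
      lum <- if (model$luminance_walk_sigma > 0)
        exp(cumsum(stats::rnorm(n, 0, model$luminance_walk_sigma)))
      else rep(1, n)
      eps <- if (model$rel_noise_sigma > 0)
        matrix(stats::rnorm(3 * n, 0, model$rel_noise_sigma), n, 3)
      else matrix(0, n, 3)
      pmax(base[rep(1, n), ] * rep(model$gain, each = n) * lum * (1 + eps), 0)
    }
    collect_calibration(sampler, positions, samples_per_point,
                        spec = spec, grid_n = grid_n)
  })
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf("Calibration table: %d x %d grid, %d samples/point\n",
              x$grid_n, x$grid_n, x$samples_per_point))
  if (!is.na(x$map_spec_hash))
    cat(sprintf("  map spec hash: %s\n", x$map_spec_hash))
  cat(sprintf("  x range: [%g, %g] mm; y range: [%g, %g] mm\n",
              min(x$positions[, 1]), max(x$positions[, 1]),
              min(x$positions[, 2]), max(x$positions[, 2])))
  invisible(x)
}

# least-squares quadratic through (x, y), evaluated at xout
quad_fit_eval <- function(x, y, xout) {
  # center/scale x for conditioning; exact for polynomials of degree <= 2
  xc <- (x - mean(x)) / max(diff(range(x)) / 2, 1)
  xo <- (xout - mean(x)) / max(diff(range(x)) / 2, 1)
  co <- stats::lm.fit(cbind(1, xc, xc^2), y)$coefficients
  co[is.na(co)] <- 0
  co[1] + co[2] * xo + co[3] * xo^2
}

#' Interpolate a calibration table to a full pixel lattice
#'
#' Separable second-order polynomial interpolation: for each color channel
#' independently, (pass 1) a least-squares quadratic is fitted along each
#' calibration row and evaluated at all pixel-center coordinates of the first
#' axis; (pass 2) a quadratic is fitted through the intermediate values along
#' each pixel column and evaluated at pixel centers of the second axis.
#' Finally each pixel's three channels are renormalized to sum 1. Fields that
#' are per-axis polynomials of degree <= 2 are reproduced exactly.
#'
#' Pixel i (1-based) covers `[(i-1) * pitch, i * pitch)` of the usable span;
#' polynomials are evaluated at pixel centers `(i - 0.5) * pitch`.
#'
#' @param table A [collect_calibration()] table.
#' @param N Pixels per axis of the output lattice (default 32; must be >=
#'   the calibration grid size).
#' @param axis_order `"xy"` (default: fit along x first, then y) or `"yx"`.
#'   For the default map the chromaticity field is affine and the two orders
#'   agree to numerical precision.
#' @return An object of class `forward_map` with fields `N`, `pitch_mm`,
#'   `origin_mm`, and `chroma`, an `N x N x 3` array indexed
#'   `[i_x, j_y, channel]`.
#' @export
interpolate_forward <- function(table, N = 32, axis_order = c("xy", "yx")) {
  axis_order <- match.arg(axis_order)
  stopifnot(inherits(table, "calibration_table"))
  if (any(!is.finite(table$chroma))) stop("calibration table has non-finite values")
  g <- table$grid_n
  if (N < g) stop("N must be at least the calibration grid size")
  xs <- sort(unique(table$positions[, 1]))
  ys <- sort(unique(table$positions[, 2]))
  if (length(xs) != g || length(ys) != g)
    stop("positions do not form a complete regular grid")
  span <- max(xs) - min(xs)
  origin <- min(xs)
  pitch <- span / N
  centers <- origin + (seq_len(N) - 0.5) * pitch
  chroma <- array(NA_real_, c(N, N, 3))
  for (ch in 1:3) {
    vals <- matrix(table$chroma[, ch], g, g, byrow = TRUE)  # [row_y, col_x]
    if (axis_order == "xy") {
      inter <- matrix(NA_real_, g, N)            # [row_y, pixel_x]
      for (r in seq_len(g))
        inter[r, ] <- quad_fit_eval(xs, vals[r, ], centers)
      for (i in seq_len(N))
        chroma[i, , ch] <- quad_fit_eval(ys, inter[, i], centers)
    } else {
      inter <- matrix(NA_real_, N, g)            # [pixel_y, col_x]
      for (cidx in seq_len(g))
        inter[, cidx] <- quad_fit_eval(ys, vals[, cidx], centers)
      for (j in seq_len(N))
        chroma[, j, ch] <- quad_fit_eval(xs, inter[j, ], centers)
    }
  }
  tot <- chroma[, , 1] + chroma[, , 2] + chroma[, , 3]
  for (ch in 1:3) chroma[, , ch] <- chroma[, , ch] / tot
  structure(list(N = as.integer(N), pitch_mm = pitch, origin_mm = origin,
                 chroma = chroma, axis_order = axis_order,
                 map_spec_hash = table$map_spec_hash),
            class = "forward_map")
}

#' @export
print.forward_map <- function(x, ...) {
  cat(sprintf("Forward map: %d x %d pixels, pitch %.4g mm (span %.4g mm)\n",
              x$N, x$N, x$pitch_mm, x$pitch_mm * x$N))
  cat(sprintf("  fit order: %s; map spec hash: %s\n", x$axis_order,
              x$map_spec_hash))
  invisible(x)
}

#' Pixel-center coordinates of a forward map
#'
#' @param fwd A [interpolate_forward()] result.
#' @return Numeric vector of length N: the frame coordinate (mm) of pixel
#'   centers along either axis.
#' @export
pixel_centers_mm <- function(fwd) {
  fwd$origin_mm + (seq_len(fwd$N) - 0.5) * fwd$pitch_mm
}

#' Predicted chromaticity at pixel indices
#'
#' @param object A `forward_map`.
#' @param pixel An n x 2 matrix of 1-based (i, j) pixel indices (i = x
#'   column, j = y row).
#' @param ... Unused.
#' @return An n x 3 matrix of chromaticities.
#' @export
predict.forward_map <- function(object, pixel, ...) {
  px <- matrix(as.integer(pixel), ncol = 2)
  stopifnot(all(px >= 1 & px <= object$N))
  out <- cbind(r = object$chroma[cbind(px[, 1], px[, 2], 1)],
               g = object$chroma[cbind(px[, 1], px[, 2], 2)],
               b = object$chroma[cbind(px[, 1], px[, 2], 3)])
  out
}

#' Write / read a calibration table (TSV with '#' metadata lines)
#'
#' Columns `x_mm`, `y_mm`, `r`, `g`, `b` (normalized chromaticities) with
#' metadata lines for grid size, samples per point, and the map-spec hash.
#'
#' @param table A `calibration_table`.
#' @param path File path.
#' @export
write_calibration <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# grid_n=%d", table$grid_n), con)
  writeLines(sprintf("# samples_per_point=%d", table$samples_per_point), con)
  if (!is.na(table$map_spec_hash))
    writeLines(sprintf("# map_spec_hash=%s", table$map_spec_hash), con)
  if (!is.na(table$side_mm)) {
    writeLines(sprintf("# side_mm=%.10g", table$side_mm), con)
    writeLines(sprintf("# usable_span_mm=%.10g", table$usable_span_mm), con)
  }
  writeLines("x_mm\ty_mm\tr\tg\tb", con)
  df <- data.frame(table$positions, table$chroma)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  meta <- read_hash_meta(path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  structure(
    list(positions = as.matrix(df[, c("x_mm", "y_mm")]),
         chroma = as.matrix(df[, c("r", "g", "b")]),
         grid_n = as.integer(meta[["grid_n"]]),
         samples_per_point = as.integer(meta[["samples_per_point"]]),
         side_mm = if (!is.null(meta[["side_mm"]])) as.numeric(meta[["side_mm"]]) else NA_real_,
         usable_span_mm = if (!is.null(meta[["usable_span_mm"]]))
           as.numeric(meta[["usable_span_mm"]]) else NA_real_,
         map_spec_hash = if (!is.null(meta[["map_spec_hash"]]))
           meta[["map_spec_hash"]] else NA_character_),
    class = "calibration_table")
}
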