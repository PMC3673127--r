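#' Define the pen/LED/color-sensor model
#'
#' Parameters of the simulated optical chain. The sensor reads the average
#' color of a small illuminated spot under the pen tip; each channel is scaled
#' by a gain (counts per byte level) and by a shared luminance factor that
#' drifts as a slow random walk in log space (emulating fiber bending, supply
#' variation and map wear); per-sample multiplicative Gaussian noise is added
#' per channel. Lifting the pen collapses all channels to `liftoff_floor`
#' of the in-contact signal within one sample interval, which is what the
#' decoder's >50%-drop rule detects.
#'
#' Multiplicative forms are used throughout because chromaticity
#' normalization (division by the channel sum) is designed to cancel exactly
#' shared multiplicative disturbances.
#'
#' @param gain Positive per-channel gain, counts per byte level (length 1 or 3).
#' @param spot_radius_mm Radius of the illuminated/collected spot (default
#'   1.0, from the 2 mm fibers).
#' @param rel_noise_sigma Per-sample, per-channel multiplicative noise s.d.
#'   (default 0.02).
#' @param luminance_walk_sigma Per-sample s.d. of the shared log-luminance
#'   random walk (default 0.002).
#' @param sample_rate_hz Sampling rate (default 30).
#' @param liftoff_floor Fraction of in-contact signal remaining when the pen
#'   is lifted (default 0.05; must be < 0.5 so a lift always trips the drop
#'   rule).
#' @return An object of class `sensor_model`.
#' @export
sensor_model <- function(gain = c(1, 1, 1), spot_radius_mm = 1.0,
                         rel_noise_sigma = 0.02, luminance_walk_sigma = 0.002,
                         sample_rate_hz = 30, liftoff_floor = 0.05) {
  gain <- rep_len(as.numeric(gain), 3)
  stopifnot(all(gain > 0), spot_radius_mm > 0, rel_noise_sigma >= 0,
            luminance_walk_sigma >= 0, sample_rate_hz > 0, liftoff_floor > 0)
  if (liftoff_floor >= 0.5)
    stop("liftoff_floor must be < 0.5 so lift-off trips the >50% drop rule")
  structure(list(gain = gain, spot_radius_mm = spot_radius_mm,
                 rel_noise_sigma = rel_noise_sigma,
                 luminance_walk_sigma = luminance_walk_sigma,
                 sample_rate_hz = sample_rate_hz,
                 liftoff_floor = liftoff_floor),
            class = "sensor_model")
}

#' @export
print.sensor_model <- function(x, ...) {
  cat("Sensor model\n")
  cat(sprintf("  gain (counts/byte): %s\n", paste(x$gain, collapse = ", ")))
  cat(sprintf("  spot radius: %g mm; sample rate: %g Hz\n",
              x$spot_radius_mm, x$sample_rate_hz))
  cat(sprintf("  rel. noise sd: %g; log-luminance walk sd: %g; lift-off floor: %g\n",
              x$rel_noise_sigma, x$luminance_walk_sigma, x$liftoff_floor))
  invisible(x)
}

# 37-point hexagonal quadrature over the unit disc: hex lattice with spacing
# 1/3, all points with norm <= 1. Point-symmetric, so linear fields average
# exactly to the disc-center value.
disc_quadrature <- local({
  ij <- expand.grid(i = -6:6, j = -6:6)
  x <- (ij$i + ij$j / 2) / 3
  y <- (ij$j * sqrt(3) / 2) / 3
  keep <- x^2 + y^2 <= 1 + 1e-12
  pts <- cbind(x[keep], y[keep])
  stopifnot(nrow(pts) == 37)
  function() pts
})

# Mean ideal color over the illuminated spot at each position (n x 2 -> n x 3).
spot_color <- function(spec, model, xy) {
  pts <- disc_quadrature() * model$spot_radius_mm
  n <- nrow(xy); m <- nrow(pts)
  big <- cbind(rep(xy[, 1], each = m) + rep(pts[, 1], n),
               rep(xy[, 2], each = m) + rep(pts[, 2], n))
  col <- ideal_color_at(spec, big)
  grp <- rep(seq_len(n), each = m)
  rowsum(col, grp) / m
}

#' Simulate one raw sensor read
#'
#' counts = gain * (spot-averaged map color) * luminance * (1 + noise), with
#' an additional `liftoff_floor` factor when the pen is not in contact. Noise
#' is drawn from the current RNG state; with `rel_noise_sigma = 0` the read is
#' deterministic.
#'
#' @param spec A [color_map_spec()].
#' @param model A [sensor_model()].
#' @param position (x, y) position of the pen center in mm.
#' @param in_contact Logical; is the pen touching the map?
#' @param luminance Current shared luminance factor (default 1).
#' @return A length-3 numeric vector of raw (R, G, B) counts.
#' @export
read_counts <- function(spec, model, position, in_contact = TRUE, luminance = 1) {
  xy <- as_xy_matrix(position)
  base <- spot_color(spec, model, xy)
  eps <- if (model$rel_noise_sigma > 0)
    matrix(stats::rnorm(3 * nrow(xy), 0, model$rel_noise_sigma), nrow(xy), 3)
  else 0
  counts <- base * rep(model$gain, each = nrow(xy)) * luminance * (1 + eps)
  counts <- counts * ifelse(rep_len(in_contact, nrow(xy)), 1, model$liftoff_floor)
  counts <- pmax(counts, 0)
  colnames(counts) <- c("r_counts", "g_counts", "b_counts")
  if (nrow(counts) == 1) drop(counts) else counts
}

#' Build a pen trajectory script
#'
#' A script is an ordered list of segments: pen-down paths (polyline
#' waypoints traversed at constant speed over `duration_s`) and pen-up dwells
#' (the pen hovers over its last position). Waypoints are frame coordinates
#' in mm and must lie within the usable span.
#'
#' @param ... Segments created by [pen_down()] and [pen_up()].
#' @return An object of class `pen_script`.
#' @export
pen_script <- function(...) {
  segs <- list(...)
  if (length(segs) == 1 && is.list(segs[[1]]) && !inherits(segs[[1]], "pen_segment"))
    segs <- segs[[1]]
  stopifnot(all(vapply(segs, inherits, logical(1), "pen_segment")))
  structure(segs, class = "pen_script")
}

#' @rdname pen_script
#' @param waypoints An m x 2 matrix of (x, y) mm waypoints (m >= 1).
#' @param duration_s Positive segment duration in seconds.
#' @export
pen_down <- function(waypoints, duration_s) {
  wp <- as_xy_matrix(waypoints)
  stopifnot(duration_s > 0)
  structure(list(type = "down", waypoints = wp, duration_s = duration_s),
            class = "pen_segment")
}

#' @rdname pen_script
#' @export
pen_up <- function(duration_s) {
  stopifnot(duration_s > 0)
  structure(list(type = "up", duration_s = duration_s), class = "pen_segment")
}

script_duration <- function(script) sum(vapply(script, `[[`, numeric(1), "duration_s"))

# position along a polyline at arc-length fraction f in [0, 1]
polyline_point <- function(wp, f) {
  if (nrow(wp) == 1) return(wp[1, ])
  seglen <- sqrt(rowSums((wp[-1, , drop = FALSE] - wp[-nrow(wp), , drop = FALSE])^2))
  total <- sum(seglen)
  if (total == 0) return(wp[1, ])
  target <- f * total
  cum <- c(0, cumsum(seglen))
  k <- findInterval(target, cum, rightmost.closed = TRUE)
  k <- min(max(k, 1), nrow(wp) - 1)
  local_f <- if (seglen[k] > 0) (target - cum[k]) / seglen[k] else 0
  wp[k, ] + local_f * (wp[k + 1, ] - wp[k, ])
}

# Evaluate a script at sample times: positions + contact flags.
script_pose <- function(script, t, fallback_xy) {
  starts <- cumsum(c(0, vapply(script, `[[`, numeric(1), "duration_s")))
  n <- length(t)
  xy <- matrix(NA_real_, n, 2)
  contact <- logical(n)
  last_xy <- fallback_xy
  for (si in seq_along(script)) {
    seg <- script[[si]]
    sel <- t >= starts[si] & t < starts[si + 1]
    if (si == length(script)) sel <- sel | t >= starts[si + 1]  # include end
    if (!any(sel)) {
      if (seg$type == "down") last_xy <- seg$waypoints[nrow(seg$waypoints), ]
      next
    }
    if (seg$type == "down") {
      f <- (t[sel] - starts[si]) / seg$duration_s
      xy[sel, ] <- t(vapply(f, function(ff) polyline_point(seg$waypoints, ff),
                            numeric(2)))
      contact[sel] <- TRUE
      last_xy <- seg$waypoints[nrow(seg$waypoints), ]
    } else {
      xy[sel, ] <- matrix(last_xy, sum(sel), 2, byrow = TRUE)
      contact[sel] <- FALSE
    }
  }
  list(xy = xy, contact = contact)
}

validate_script <- function(spec, script) {
  lo <- (spec$side_mm - spec$usable_span_mm) / 2
  hi <- lo + spec$usable_span_mm
  for (seg in script) {
    if (seg$type != "down") next
    wp <- seg$waypoints
    if (any(wp < lo - 1e-9) || any(wp > hi + 1e-9))
      stop("pen-down waypoints must lie within the usable span [",
           lo, ", ", hi, "] mm")
  }
  invisible(TRUE)
}

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

#' Simulate a time-stamped sensor sample stream
#'
#' Clocks the pen along a [pen_script()] at the model's sample rate
#' (samples at t = 0, 1/rate, ..., covering `[0, total_duration)`), reading
#' raw counts at each sample. Pen-up segments collapse counts by
#' `liftoff_floor` in a single sample interval, satisfying the premise of the
#' >50%-in-<250 ms lift-off rule. The stream is a deterministic function of
#' (spec, model, script, seed).
#'
#' @inheritParams read_counts
#' @param script A [pen_script()].
#' @param seed Integer seed for the noise generator; recorded in the stream's
#'   metadata.
#' @return A `sensor_stream`: a data.frame with columns `t_s`, `r_counts`,
#'   `g_counts`, `b_counts` and attributes `map_spec_hash`, `seed`, `model`,
#'   and `truth` (a data.frame of ground-truth `x_mm`, `y_mm`, `in_contact`).
#' @export
simulate_stream <- function(spec, model, script, seed = 1) {
  stopifnot(inherits(spec, "color_map_spec"), inherits(model, "sensor_model"),
            inherits(script, "pen_script"))
  validate_script(spec, script)
  total <- script_duration(script)
  n <- floor(total * model$sample_rate_hz + 1e-9)
  if (length(script) == 0 || n == 0) {
    out <- data.frame(t_s = numeric(0), r_counts = numeric(0),
                      g_counts = numeric(0), b_counts = numeric(0))
    attr(out, "map_spec_hash") <- spec_hash(spec)
    attr(out, "seed") <- seed
    class(out) <- c("sensor_stream", "data.frame")
    return(out)
  }
  t <- (seq_len(n) - 1) / model$sample_rate_hz
  first_down <- Find(function(s) s$type == "down", script)
  fallback <- if (!is.null(first_down)) first_down$waypoints[1, ]
              else rep(spec$side_mm / 2, 2)
  pose <- script_pose(script, t, fallback)
  base <- spot_color(spec, model, pose$xy)
  with_seed(seed, {
    lum <- if (model$luminance_walk_sigma > 0)
      exp(cumsum(stats::rnorm(n, 0, model$luminance_walk_sigma)))
    else rep(1, n)
    eps <- if (model$rel_noise_sigma > 0)
      matrix(stats::rnorm(3 * n, 0, model$rel_noise_sigma), n, 3)
    else matrix(0, n, 3)
    counts <- base * rep(model$gain, each = n) * lum * (1 + eps)
  })
  counts <- counts * ifelse(pose$contact, 1, model$liftoff_floor)
  counts <- pmax(counts, 0)
  out <- data.frame(t_s = t, r_counts = counts[, 1], g_counts = counts[, 2],
                    b_counts = counts[, 3])
  attr(out, "map_spec_hash") <- spec_hash(spec)
  attr(out, "seed") <- seed
  attr(out, "model") <- model
  attr(out, "truth") <- data.frame(x_mm = pose$xy[, 1], y_mm = pose$xy[, 2],
                                   in_contact = pose$contact)
  class(out) <- c("sensor_stream", "data.frame")
  out
}

#' Write / read a sensor log (TSV with '#' metadata lines)
#'
#' The log format is also the accepted input format for real hardware logs:
#' a header line `t_s r_counts g_counts b_counts` (tab-separated) preceded by
#' `#` comment lines carrying `key=value` metadata (map spec hash, seed).
#'
#' @param stream A `sensor_stream` (or any data.frame with the four columns).
#' @param path File path.
#' @return `write_sensor_log` returns the path invisibly; `read_sensor_log`
#'   returns a `sensor_stream`.
#' @export
write_sensor_log <- function(stream, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(map_spec_hash = attr(stream, "map_spec_hash"),
            seed = attr(stream, "seed"))
  for (k in names(meta))
    if (!is.null(meta[[k]]) && !is.na(meta[[k]]))
      writeLines(sprintf("# %s=%s", k, meta[[k]]), con)
  writeLines(paste(c("t_s", "r_counts", "g_counts", "b_counts"),
                   collapse = "\t"), con)
  utils::write.table(format(stream[, c("t_s", "r_counts", "g_counts", "b_counts")],
                            digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_sensor_log
#' @export
read_sensor_log <- function(path) {
  meta <- read_hash_meta(path)
  out <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  stopifnot(identical(names(out), c("t_s", "r_counts", "g_counts", "b_counts")))
  attr(out, "map_spec_hash") <- meta[["map_spec_hash"]]
  if (!is.null(meta[["seed"]])) attr(out, "seed") <- as.integer(meta[["seed"]])
  class(out) <- c("sensor_stream", "data.frame")
  out
}
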