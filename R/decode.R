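#' Lift-off detection configuration
#'
#' A sudden, precipitous drop in total signal (more than `drop_fraction`
#' within `drop_window_s`) is interpreted as loss of pen contact; an off-map
#' color lookup can be used as a redundant confirmation channel. A pen-up
#' period of at least `completion_dwell_s` marks the response as complete.
#'
#' @param drop_fraction Fractional signal drop that triggers lift-off
#'   (default 0.5, i.e. a >50% change).
#' @param drop_window_s Time window within which the drop must occur
#'   (default 0.25 s).
#' @param completion_dwell_s Pen-up duration that completes a response
#'   (default 1.0 s; the deployed value is operator-specified).
#' @param require_offmap_confirmation If `TRUE` (default) an off-map color
#'   inside the drop window also raises the lift-off flag.
#' @return An object of class `liftoff_config`.
#' @export
liftoff_config <- function(drop_fraction = 0.5, drop_window_s = 0.25,
                           completion_dwell_s = 1.0,
                           require_offmap_confirmation = TRUE) {
  stopifnot(drop_fraction > 0, drop_fraction < 1, drop_window_s > 0,
            completion_dwell_s > 0, is.logical(require_offmap_confirmation))
  structure(list(drop_fraction = drop_fraction, drop_window_s = drop_window_s,
                 completion_dwell_s = completion_dwell_s,
                 require_offmap_confirmation = require_offmap_confirmation),
            class = "liftoff_config")
}

#' Detect lift-off events in a summed-signal window
#'
#' Flags sample k when the summed counts fall by more than `drop_fraction`
#' of the value at the start of any sub-interval of length at most
#' `drop_window_s` ending at k (the reference is the sliding window's start;
#' windows are evaluated at every sample). When
#' `require_offmap_confirmation` is set and `offmap` flags are supplied, an
#' off-map lookup inside the trailing window also raises the flag.
#'
#' @param t Sample times in seconds (strictly increasing).
#' @param sums Summed (R+G+B) raw counts at each sample.
#' @param cfg A [liftoff_config()].
#' @param offmap Optional logical vector: TRUE where the sample's color
#'   looked up off-map.
#' @return A logical vector, one flag per sample.
#' @export
detect_liftoff <- function(t, sums, cfg = liftoff_config(), offmap = NULL) {
  n <- length(t)
  stopifnot(length(sums) == n, n == 0 || !is.unsorted(t, strictly = TRUE))
  flag <- logical(n)
  j0 <- 1
  for (k in seq_len(n)) {
    while (t[k] - t[j0] > cfg$drop_window_s) j0 <- j0 + 1
    win <- j0:k
    if (any(sums[k] < (1 - cfg$drop_fraction) * sums[win[win < k]])) flag[k] <- TRUE
    if (cfg$require_offmap_confirmation && !is.null(offmap) &&
        any(offmap[win], na.rm = TRUE)) flag[k] <- TRUE
  }
  flag
}

# symmetric re-contact rule: signal rises back above 1/(1 - f) of a value
# seen within the trailing window
detect_recontact <- function(t, sums, cfg) {
  n <- length(t)
  flag <- logical(n)
  j0 <- 1
  for (k in seq_len(n)) {
    while (t[k] - t[j0] > cfg$drop_window_s) j0 <- j0 + 1
    win <- j0:k
    prev <- win[win < k]
    if (length(prev) && any(sums[k] * (1 - cfg$drop_fraction) > sums[prev]))
      flag[k] <- TRUE
  }
  flag
}

#' Causal rolling-average smoothing
#'
#' A rolling mean of a modest number of points greatly reduces the blocky
#' look of polylines bridging a discrete pixel grid. Smoothing is causal
#' (real-time display cannot see the future): each output is the mean of the
#' last `min(window, available)` inputs. The decoder resets the window at
#' stroke boundaries so positions are never averaged across a lift-off.
#'
#' @param xy A numeric vector or an n x 2 matrix of positions.
#' @param window Odd window length >= 1 (default 5).
#' @return Smoothed positions of the same shape.
#' @export
smooth_positions <- function(xy, window = 5) {
  stopifnot(window >= 1, window %% 2 == 1)
  vec <- is.null(dim(xy))
  m <- if (vec) matrix(xy, ncol = 1) else as.matrix(xy)
  n <- nrow(m)
  if (n == 0 || window == 1) return(xy)
  cs <- apply(m, 2, function(col) cumsum(col))
  cs <- rbind(0, matrix(cs, ncol = ncol(m)))
  lo <- pmax(seq_len(n) - window, 0)
  out <- (cs[seq_len(n) + 1, , drop = FALSE] - cs[lo + 1, , drop = FALSE]) /
    (seq_len(n) - lo)
  if (vec) drop(out) else out
}

#' Decode a sensor stream into segmented, smoothed responses
#'
#' The real-time pipeline: each raw sample is chromaticity-normalized and
#' looked up in the inverse LUT; lift-off (luminance-drop rule, off-map
#' color, or an invalid all-zero read) closes the current stroke; a pen-up
#' period of at least `completion_dwell_s` closes the response (clearing the
#' virtual writing area and emitting a trial-advance event, the software
#' stand-in for the serial cue to the stimulus computer). Within strokes,
#' pixel-center positions are smoothed with a causal rolling average.
#'
#' Contact state starts as "in contact": a stream is expected to begin with
#' the pen on the map (or with an explicit signal drop). Because the lift-off
#' collapse is multiplicative, chromaticity alone cannot distinguish a lifted
#' pen hovering over the map; the drop rule carries that burden.
#'
#' @param stream A `sensor_stream` (from [simulate_stream()] or
#'   [read_sensor_log()]).
#' @param lut An [build_lut()] result built against the same map spec
#'   (hashes are checked when both sides carry one).
#' @param cfg A [liftoff_config()].
#' @param smooth_window Causal rolling-average window (odd, default 5; the
#'   induced display latency is `(window - 1) / 2` sample periods).
#' @param hesitation_dwell_s In-stroke dwell duration that counts as a
#'   hesitation (default 0.3 s; displacement must stay under one pixel pitch).
#' @return An object of class `pad_decoding`: per-sample decode table
#'   (`$samples`), a list of `pad_response` records (`$responses`, each with
#'   strokes, completion time and [compute_metrics()] output), trial-advance
#'   events (`$events`), and the measured per-sample processing time
#'   (`$per_sample_s`).
#' @export
decode_stream <- function(stream, lut, cfg = liftoff_config(),
                          smooth_window = 5, hesitation_dwell_s = 0.3) {
  stopifnot(inherits(lut, "inverse_lut"))
  sh <- attr(stream, "map_spec_hash")
  if (!is.null(sh) && !is.na(sh) && !is.null(lut$map_spec_hash) &&
      !is.na(lut$map_spec_hash) && !identical(sh, lut$map_spec_hash))
    stop(sprintf("map spec hash mismatch: stream %s vs LUT %s", sh,
                 lut$map_spec_hash))
  t0 <- proc.time()[3]
  n <- nrow(stream)
  empty <- structure(list(
    samples = data.frame(t_s = numeric(0), x_mm = numeric(0), y_mm = numeric(0),
                         pen_down = integer(0), stroke_id = integer(0),
                         response_id = integer(0)),
    responses = list(),
    events = data.frame(response_id = integer(0), completed_at = numeric(0)),
    cfg = cfg, smooth_window = smooth_window, per_sample_s = NA_real_),
    class = "pad_decoding")
  if (n == 0) return(empty)

  t <- stream$t_s
  counts <- cbind(stream$r_counts, stream$g_counts, stream$b_counts)
  sums <- rowSums(counts)
  valid <- is.finite(sums) & sums > 0
  chroma <- normalize_chroma(counts, on_zero = "na")
  pix <- lut_lookup(lut, chroma)
  offmap <- valid & is.na(pix[, 1])
  # The sum-drop rule drives the latched contact state; off-map samples are
  # pen-up individually (they cannot be assigned a pixel) but do not latch,
  # so an isolated off-map noise spike cannot swallow the rest of a stroke.
  drop_flag <- detect_liftoff(t, sums, cfg, offmap = NULL)
  rise_flag <- detect_recontact(t, sums, cfg)

  lifted <- FALSE
  pen_down <- logical(n)
  for (k in seq_len(n)) {
    if (rise_flag[k]) lifted <- FALSE
    if (drop_flag[k]) lifted <- TRUE
    pen_down[k] <- valid[k] && !offmap[k] && !is.na(pix[k, 1]) && !lifted
  }

  # stroke runs
  r <- rle(pen_down)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  stroke_runs <- which(r$values)
  stroke_id <- integer(n)
  for (s in seq_along(stroke_runs))
    stroke_id[starts[stroke_runs[s]]:ends[stroke_runs[s]]] <- s
  n_strokes <- length(stroke_runs)

  # group strokes into responses: a pen-up gap >= completion_dwell_s splits
  response_of_stroke <- integer(n_strokes)
  resp_completed <- numeric(0)
  if (n_strokes > 0) {
    rid <- 1
    response_of_stroke[1] <- 1
    if (n_strokes > 1) {
      for (s in 2:n_strokes) {
        gap_start <- t[ends[stroke_runs[s - 1]]]
        gap_end <- t[starts[stroke_runs[s]]]
        if (gap_end - gap_start >= cfg$completion_dwell_s) {
          resp_completed[rid] <- gap_start + cfg$completion_dwell_s
          rid <- rid + 1
        }
        response_of_stroke[s] <- rid
      }
    }
    last_stroke_end <- t[ends[stroke_runs[n_strokes]]]
    tail_up <- t[n] - last_stroke_end
    resp_completed[rid] <- if (tail_up >= cfg$completion_dwell_s)
      last_stroke_end + cfg$completion_dwell_s else t[n]
  }

  # build responses with smoothed strokes
  pitch <- lut$pitch_mm
  responses <- vector("list", length(resp_completed))
  x_mm <- rep(NA_real_, n); y_mm <- rep(NA_real_, n)
  response_id <- integer(n)
  for (rid in seq_along(responses)) {
    sids <- which(response_of_stroke == rid)
    strokes <- vector("list", length(sids))
    for (kk in seq_along(sids)) {
      s <- sids[kk]
      idx <- starts[stroke_runs[s]]:ends[stroke_runs[s]]
      mm <- pixel_to_mm(lut, pix[idx, , drop = FALSE])
      sm <- smooth_positions(mm, smooth_window)
      sm <- matrix(sm, ncol = 2)
      strokes[[kk]] <- data.frame(t_s = t[idx], i = pix[idx, 1], j = pix[idx, 2],
                                  x_mm = sm[, 1], y_mm = sm[, 2])
      x_mm[idx] <- sm[, 1]; y_mm[idx] <- sm[, 2]
      response_id[idx] <- rid
    }
    resp <- structure(list(strokes = strokes, completed_at = resp_completed[rid],
                           pitch_mm = pitch, usable_span_mm = pitch * lut$N,
                           origin_mm = lut$origin_mm, N = lut$N),
                      class = "pad_response")
    resp$metrics <- compute_metrics(resp, hesitation_dwell_s = hesitation_dwell_s)
    responses[[rid]] <- resp
  }

  elapsed <- proc.time()[3] - t0
  structure(list(
    samples = data.frame(t_s = t, x_mm = x_mm, y_mm = y_mm,
                         pen_down = as.integer(pen_down),
                         stroke_id = stroke_id, response_id = response_id),
    responses = responses,
    events = data.frame(response_id = seq_along(resp_completed),
                        completed_at = resp_completed),
    cfg = cfg, smooth_window = smooth_window,
    smoothing_delay_s = if (n > 1) (smooth_window - 1) / 2 * stats::median(diff(t)) else NA_real_,
    per_sample_s = elapsed / n),
    class = "pad_decoding")
}

#' @export
print.pad_decoding <- function(x, ...) {
  cat(sprintf("Decoded stream: %d samples, %d response(s)\n",
              nrow(x$samples), length(x$responses)))
  for (rid in seq_along(x$responses)) {
    m <- x$responses[[rid]]$metrics
    cat(sprintf("  response %d: %d stroke(s), %d lift-off(s), completed at %.3f s\n",
                rid, m$stroke_count, m$liftoff_count,
                x$responses[[rid]]$completed_at))
  }
  invisible(x)
}

#' @export
summary.pad_decoding <- function(object, ...) {
  cat(sprintf("Samples: %d (%d pen-down)\n", nrow(object$samples),
              sum(object$samples$pen_down)))
  cat(sprintf("Causal smoothing delay: %.0f ms; per-sample processing: %.3f ms\n",
              1000 * object$smoothing_delay_s, 1000 * object$per_sample_s))
  for (rid in seq_along(object$responses)) {
    m <- object$responses[[rid]]$metrics
    cat(sprintf(
      "Response %d: %d strokes, path %.1f mm, mean speed %.1f mm/s, peak %.1f mm/s, %d hesitation(s), %d lift-off(s)\n",
      rid, m$stroke_count, sum(m$path_length_mm), m$mean_speed_mm_s,
      m$peak_speed_mm_s, nrow(m$hesitations), m$liftoff_count))
  }
  invisible(object)
}

#' Write a decoded stream as TSV
#'
#' Columns `t_s`, `x_mm`, `y_mm`, `pen_down`, `stroke_id`, `response_id`
#' with `#` metadata lines; one trial-advance event line per response is
#' written to `events_path` when given.
#'
#' @param decoding A [decode_stream()] result.
#' @param path Output TSV path.
#' @param lut_hash Optional LUT/map hash recorded in the metadata.
#' @param events_path Optional path for trial-advance events.
#' @export
write_decoded <- function(decoding, path, lut_hash = NULL, events_path = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(lut_hash)) writeLines(sprintf("# map_spec_hash=%s", lut_hash), con)
  writeLines(sprintf("# smooth_window=%d", decoding$smooth_window), con)
  writeLines(sprintf("# completion_dwell_s=%.10g",
                     decoding$cfg$completion_dwell_s), con)
  writeLines("t_s\tx_mm\ty_mm\tpen_down\tstroke_id\tresponse_id", con)
  utils::write.table(format(decoding$samples, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  if (!is.null(events_path))
    utils::write.table(decoding$events, events_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
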