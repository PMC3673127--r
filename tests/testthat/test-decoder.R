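test_that("the drop rule flags >50% falls within the window and nothing slower", {
  cfg <- liftoff_config()
  # 60% drop across 0.2 s -> flagged
  t <- c(0, 0.1, 0.2)
  expect_true(any(detect_liftoff(t, c(300, 300, 120), cfg)))
  # 40% drop -> not flagged
  expect_false(any(detect_liftoff(t, c(300, 300, 180), cfg)))
  # 60% drop spread linearly over 1 s -> no window contains a >50% change
  t2 <- seq(0, 1, length.out = 31)
  sums2 <- seq(300, 120, length.out = 31)
  expect_false(any(detect_liftoff(t2, sums2, cfg)))
  # brute-force sliding-window oracle over random signals
  set.seed(21)
  for (rep in 1:10) {
    tt <- (0:59) / 30
    ss <- exp(cumsum(rnorm(60, 0, 0.25))) * 200
    got <- detect_liftoff(tt, ss, cfg)
    want <- sapply(seq_along(tt), function(k) {
      js <- which(tt[k] - tt <= cfg$drop_window_s & seq_along(tt) < k)
      any(ss[k] < (1 - cfg$drop_fraction) * ss[js])
    })
    expect_equal(got, want)
  }
})

test_that("an off-map color raises the lift-off flag only when confirmation is enabled", {
  t <- c(0, 0.1, 0.2)
  sums <- c(300, 300, 290)
  offmap <- c(FALSE, TRUE, FALSE)
  expect_true(any(detect_liftoff(t, sums, liftoff_config(), offmap)))
  expect_false(any(detect_liftoff(t, sums,
                                  liftoff_config(require_offmap_confirmation = FALSE),
                                  offmap)))
})

test_that("causal rolling averaging keeps constants fixed and averages the tail", {
  expect_equal(smooth_positions(rep(3.2, 10), 5), rep(3.2, 10))
  expect_equal(smooth_positions(c(0, 0, 0, 0, 5), 5)[5], 1)
  m <- smooth_positions(cbind(c(0, 0, 0, 0, 5), c(10, 10, 10, 10, 10)), 5)
  expect_equal(m[5, ], c(1, 10))
  # warm-up: first samples average over what is available
  expect_equal(smooth_positions(c(2, 4), 5), c(2, 3))
  expect_error(smooth_positions(1:5, 4), "window")
})

test_that("a two-stroke letter decodes into ordered strokes of one response", {
  pipe <- default_pipeline()
  scripts <- fixture_scripts(pipe$spec)
  st <- simulate_stream(pipe$spec, pipe$model, scripts$T, seed = 2)
  dec <- decode_stream(st, pipe$lut)
  expect_length(dec$responses, 1)
  m <- dec$responses[[1]]$metrics
  expect_equal(m$stroke_count, 2)
  expect_equal(m$liftoff_count, 1)  # pen-up gap below the completion dwell merges
  s1 <- dec$responses[[1]]$strokes[[1]]
  s2 <- dec$responses[[1]]$strokes[[2]]
  # stroke order follows the script: crossbar (constant y, moving x) first
  expect_lt(diff(range(s1$j)), 2)
  expect_gt(diff(range(s1$i)), 10)
  expect_lt(diff(range(s2$i)), 2)
  expect_gt(diff(range(s2$j)), 10)
  # segmentation conserves samples: every sample is in exactly one stroke
  # or accounted as pen-up/invalid
  stroke_samples <- sum(vapply(dec$responses, function(r)
    sum(vapply(r$strokes, nrow, integer(1))), numeric(1)))
  expect_equal(stroke_samples + sum(dec$samples$pen_down == 0), nrow(st))
  expect_equal(stroke_samples, nrow(s1) + nrow(s2))
})

test_that("a pen-up dwell of at least the completion dwell splits responses", {
  pipe <- default_pipeline()
  lo <- 30
  scr <- pen_script(
    pen_down(rbind(c(lo + 10, 100), c(lo + 60, 100)), 0.8),
    pen_up(1.3),
    pen_down(rbind(c(lo + 80, 100), c(lo + 130, 100)), 0.8),
    pen_up(1.3))
  dec <- decode_stream(simulate_stream(pipe$spec, pipe$model, scr, seed = 3),
                       pipe$lut)
  expect_length(dec$responses, 2)
  expect_equal(dec$responses[[1]]$metrics$stroke_count, 1)
  expect_equal(dec$responses[[2]]$metrics$liftoff_count, 0)
  expect_equal(nrow(dec$events), 2)
  # completion is stamped one dwell after the closing lift-off
  up1 <- dec$responses[[1]]$strokes[[1]]$t_s
  expect_equal(dec$events$completed_at[1],
               max(up1) + dec$cfg$completion_dwell_s,
               tolerance = 0.05)
})

test_that("an empty stream decodes to an empty response list", {
  pipe <- default_pipeline()
  st <- simulate_stream(pipe$spec, pipe$model, pen_script(list()), seed = 1)
  dec <- decode_stream(st, pipe$lut)
  expect_length(dec$responses, 0)
  expect_equal(nrow(dec$samples), 0)
})

test_that("streams and LUTs from different maps refuse to combine", {
  pipe <- default_pipeline()
  other <- color_map_spec(side_mm = 100, usable_span_mm = 70)
  st <- simulate_stream(other, pipe$model,
                        pen_script(pen_down(matrix(c(50, 50), 1), 0.5)), seed = 1)
  expect_error(decode_stream(st, pipe$lut), "hash mismatch")
})

test_that("stroke speed matches an independent quantization-plus-smoothing oracle", {
  pipe <- default_pipeline()
  scr <- pen_script(pen_down(rbind(c(30, 100), c(170, 100)), 2), pen_up(1.2))
  dec <- decode_stream(simulate_stream(pipe$spec, pipe$model, scr, seed = 4),
                       pipe$lut)
  m <- dec$responses[[1]]$metrics
  # oracle: positions sampled from the script, snapped to nearest pixel
  # centers, causally smoothed, finite-differenced — plain arithmetic
  tt <- (0:59) / 30
  x <- 30 + 140 * tt / 2
  idx <- pmin(pmax(floor((x - 30) / 4.375), 0), 31)
  cx <- 30 + (idx + 0.5) * 4.375
  sm <- sapply(seq_along(cx), function(k) mean(cx[max(1, k - 4):k]))
  oracle_speed <- sum(abs(diff(sm))) / (tt[60] - tt[1])
  expect_equal(m$mean_speed_mm_s, oracle_speed, tolerance = 0.02)
  # consistent with the nominal script speed (140 mm in 2 s) once the
  # deterministic quantization and causal-lag losses are accounted for
  expect_gt(m$mean_speed_mm_s, 0.9 * 70)
  expect_lt(m$mean_speed_mm_s, 1.05 * 70)
  expect_gt(m$peak_speed_mm_s, m$mean_speed_mm_s)
})

test_that("a stationary mid-stroke dwell is reported as exactly one hesitation", {
  pipe <- default_pipeline()
  scripts <- fixture_scripts(pipe$spec)
  dec <- decode_stream(simulate_stream(pipe$spec, pipe$model,
                                       scripts$hesitation, seed = 5),
                       pipe$lut)
  expect_length(dec$responses, 1)
  m <- dec$responses[[1]]$metrics
  expect_equal(m$stroke_count, 1)
  expect_equal(nrow(m$hesitations), 1)
  expect_gt(m$hesitations$duration_s, 0.8)
  expect_lt(m$hesitations$duration_s, 1.4)
})

test_that("decoded position error grows monotonically with sensor noise", {
  pipe <- default_pipeline()
  spec <- pipe$spec
  rmse_for <- function(sig) {
    m <- sensor_model(rel_noise_sigma = sig, luminance_walk_sigma = 0.002)
    vals <- sapply(1:20, function(s) {
      scr <- pen_script(pen_down(rbind(c(40, 100), c(160, 100)), 2))
      st <- simulate_stream(spec, m, scr, seed = s)
      mm <- pixel_to_mm(pipe$lut, lut_lookup(pipe$lut, stream_chroma(st)))
      tr <- attr(st, "truth")
      keep <- !is.na(mm[, 1])
      sqrt(mean((mm[keep, 1] - tr$x_mm[keep])^2 + (mm[keep, 2] - tr$y_mm[keep])^2))
    })
    mean(vals)
  }
  r <- sapply(c(0, 0.01, 0.02, 0.05), rmse_for)
  expect_true(all(diff(r) >= 0))
})

test_that("the decoder accounts for its smoothing latency and processing budget", {
  pipe <- default_pipeline()
  scr <- pen_script(pen_down(rbind(c(40, 100), c(160, 100)), 2))
  dec <- decode_stream(simulate_stream(pipe$spec, pipe$model, scr, seed = 6),
                       pipe$lut)
  expect_equal(dec$smoothing_delay_s, (5 - 1) / 2 / 30, tolerance = 1e-6)
  expect_true(is.finite(dec$per_sample_s) && dec$per_sample_s >= 0)
})

test_that("responses render deterministically with connected strokes", {
  pipe <- default_pipeline()
  scripts <- fixture_scripts(pipe$spec)
  dec <- decode_stream(simulate_stream(pipe$spec, pipe$model, scripts$H, seed = 7),
                       pipe$lut)
  resp <- dec$responses[[1]]
  expect_equal(resp$metrics$stroke_count, 3)
  r1 <- render_response(resp, canvas_px = 96)
  r2 <- render_response(resp, canvas_px = 96)
  expect_identical(r1, r2)
  expect_gt(sum(r1 < 0.5), 0)
  # each stroke is one connected ink component; the assembled letter has at
  # most two (the causal smoothing lag can pull the crossbar's trailing end
  # just short of the second vertical)
  for (s in 1:3)
    expect_equal(count_components(render_response(resp, 96, strokes = s) < 0.5), 1)
  expect_lte(count_components(r1 < 0.5), 2)
  # single two-point stroke renders a single segment
  mini <- resp
  mini$strokes <- list(data.frame(t_s = c(0, 1), i = c(2, 20), j = c(2, 2),
                                  x_mm = c(36, 115), y_mm = c(36, 36)))
  expect_equal(count_components(render_response(mini, 96) < 0.5), 1)
})
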