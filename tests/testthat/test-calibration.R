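test_that("chromaticity normalization divides by the channel sum", {
  expect_equal(normalize_chroma(c(100, 200, 100)), c(r = 0.25, g = 0.50, b = 0.25))
  for (k in c(0.01, 1, 7, 1e6))
    expect_equal(unname(normalize_chroma(k * c(100, 200, 100))),
                 c(0.25, 0.50, 0.25))
  expect_error(normalize_chroma(c(0, 0, 0)), "invalid sample")
  expect_true(all(is.na(normalize_chroma(rbind(c(0, 0, 0), c(1, 1, 1)),
                                         on_zero = "na")[1, ])))
  # idempotence: normalize(normalize(c) * s) = normalize(c) for any s > 0
  set.seed(3)
  for (rep in 1:20) {
    c0 <- runif(3, 0.01, 1)
    n1 <- normalize_chroma(c0)
    expect_equal(normalize_chroma(n1 * runif(1, 0.1, 10)), n1, tolerance = 1e-12)
  }
})

test_that("the calibration grid spans the usable area in row-major order", {
  spec <- default_spec()
  g <- calibration_grid(spec, 5)
  expect_equal(sort(unique(g[, 1])), c(30, 65, 100, 135, 170))
  expect_equal(sort(unique(g[, 2])), c(30, 65, 100, 135, 170))
  expect_equal(unname(g[1, ]), c(30, 30))         # top-left usable corner first
  expect_equal(unname(g[2, ]), c(65, 30))         # x varies fastest (top edge first)
  expect_equal(nrow(calibration_grid(spec, 3)), 9)
  expect_error(calibration_grid(spec, 2), "grid_n")
})

test_that("a zero-noise calibration reproduces the ideal chromaticities exactly", {
  spec <- default_spec()
  tab <- simulate_calibration(spec, noiseless_model(), samples_per_point = 3,
                              seed = 1)
  want <- normalize_chroma(ideal_color_at(spec, tab$positions))
  expect_equal(unname(tab$chroma), unname(want), tolerance = 1e-12)
  # single-sample degenerate averaging works
  tab1 <- simulate_calibration(spec, noiseless_model(), samples_per_point = 1,
                               seed = 1)
  expect_equal(tab1$chroma, tab$chroma, tolerance = 1e-12)
})

test_that("calibration aborts identifying the point when a position yields no valid samples", {
  spec <- default_spec()
  positions <- calibration_grid(spec, 3)
  dead_at_5 <- function(position, n) {
    if (all(position == positions[5, ])) matrix(0, n, 3)
    else matrix(rep(ideal_color_at(spec, position), each = n), n, 3)
  }
  expect_error(collect_calibration(dead_at_5, positions, samples_per_point = 4),
               "point 5")
})

test_that("noisy calibration means land within CLT bounds of the noiseless values", {
  spec <- default_spec()
  model <- sensor_model()  # rel_noise_sigma 0.02, shared luminance walk
  tab <- simulate_calibration(spec, model, samples_per_point = 100, seed = 42)
  ideal <- normalize_chroma(ideal_color_at(spec, tab$positions))
  # delta-method s.e. of a normalized channel under multiplicative noise
  se <- ideal * model$rel_noise_sigma *
    sqrt((1 - ideal)^2 + (rowSums(ideal^2) - ideal^2)) / sqrt(100)
  z <- abs(tab$chroma - ideal) / se
  expect_gte(mean(z < 3), 0.90)   # CLT: the bulk within 3 s.e.
  expect_lt(max(z), 6)            # and nothing wildly outside
})

test_that("separable quadratic interpolation reproduces per-axis quadratic fields exactly", {
  # synthetic table: channels are bi-quadratic polynomials; includes the
  # classic check (x/35)^2 over {0,35,70,105,140} -> {0,1,4,9,16}
  xs <- c(30, 65, 100, 135, 170)
  pos <- cbind(rep(xs, times = 5), rep(xs, each = 5))
  u <- (pos[, 1] - 30) / 35; v <- (pos[, 2] - 30) / 35
  r <- 0.20 + 0.01 * u^2                         # {0,1,4,9,16}/100 along x
  g <- 0.30 - 0.004 * v^2 + 0.002 * u * v
  tab <- structure(list(positions = pos, chroma = cbind(r = r, g = g, b = 1 - r - g),
                        grid_n = 5L, samples_per_point = 1L,
                        side_mm = 200, usable_span_mm = 140,
                        map_spec_hash = NA_character_),
                   class = "calibration_table")
  N <- 28  # pitch 5 mm -> pixel centers 32.5, 37.5, ...; span 52.5 is frame 82.5
  fwd <- interpolate_forward(tab, N = N)
  ctr <- pixel_centers_mm(fwd)
  expect_equal(ctr[11], 82.5)
  uc <- (ctr - 30) / 35
  want_r <- outer(0.20 + 0.01 * uc^2, rep(1, N))          # [i_x, j_y]
  want_g <- 0.30 - 0.004 * outer(rep(1, N), uc^2) + 0.002 * outer(uc, uc)
  expect_lt(max(abs(fwd$chroma[, , 1] - want_r)), 1e-9)
  expect_lt(max(abs(fwd$chroma[, , 2] - want_g)), 1e-9)
  # the embedded 1-D oracle value: 52.5 mm into the span is 1.5 grid
  # spacings, 1.5^2 = 2.25, so the r channel at that pixel column is
  # 0.20 + 0.01 * 2.25
  expect_equal(fwd$chroma[11, 14, 1], 0.20 + 0.01 * 2.25, tolerance = 1e-9)
  # independent normal-equations oracle for the same column fit
  z <- (xs - 100) / 70
  X <- cbind(1, z, z^2)
  beta <- solve(crossprod(X), crossprod(X, 0.20 + 0.01 * ((xs - 30) / 35)^2))
  z0 <- (82.5 - 100) / 70
  expect_equal(drop(cbind(1, z0, z0^2) %*% beta), 0.20 + 0.01 * 2.25,
               tolerance = 1e-9)
})

test_that("x-then-y and y-then-x passes agree for the (affine) default map", {
  spec <- default_spec()
  tab <- simulate_calibration(spec, noiseless_model(), samples_per_point = 3,
                              seed = 1)
  fxy <- interpolate_forward(tab, N = 16, axis_order = "xy")
  fyx <- interpolate_forward(tab, N = 16, axis_order = "yx")
  expect_lt(max(abs(fxy$chroma - fyx$chroma)), 1e-9)
})

test_that("forward interpolation of the real map agrees with the table at the grid points", {
  pipe <- default_pipeline()
  fwd <- pipe$fwd
  ctr <- pixel_centers_mm(fwd)
  # per-channel chromaticity gradient of the default map (for the geometric
  # offset between a grid point and its nearest pixel center)
  grad <- (0xD0 - 0x20) / 200 / 405
  max_err <- 0; max_grid_err <- 0; max_bound <- 0
  for (p in seq_len(nrow(pipe$tab$positions))) {
    pos <- pipe$tab$positions[p, ]
    i <- which.min(abs(ctr - pos[1])); j <- which.min(abs(ctr - pos[2]))
    got <- predict(fwd, cbind(i, j))
    # the fitted lattice value equals the ideal chromaticity at the pixel
    # center itself (the calibration was noiseless and the field affine)
    ideal <- normalize_chroma(ideal_color_at(pipe$spec, c(ctr[i], ctr[j])))
    max_err <- max(max_err, abs(got - ideal))
    # and matches the grid chromaticity up to the center-to-grid offset
    dist <- sqrt((ctr[i] - pos[1])^2 + (ctr[j] - pos[2])^2)
    max_grid_err <- max(max_grid_err, max(abs(got - pipe$tab$chroma[p, ])))
    max_bound <- max(max_bound, 2 * grad * dist + 1 / 255)
  }
  expect_lt(max_err, 1e-9)
  expect_lt(max_grid_err, max_bound)
})

test_that("interpolation rejects bad inputs", {
  spec <- default_spec()
  tab <- simulate_calibration(spec, noiseless_model(), samples_per_point = 1,
                              seed = 1)
  expect_error(interpolate_forward(tab, N = 3), "at least")
  tab$chroma[3, 2] <- NaN
  expect_error(interpolate_forward(tab, N = 8), "non-finite")
})

test_that("calibration tables round-trip through the TSV format", {
  spec <- default_spec()
  tab <- simulate_calibration(spec, sensor_model(), samples_per_point = 5,
                              seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_calibration(tab, path)
  back <- read_calibration(path)
  expect_equal(back$chroma, tab$chroma, tolerance = 1e-12)
  expect_equal(back$positions, tab$positions)
  expect_identical(back$map_spec_hash, tab$map_spec_hash)
  expect_equal(back$grid_n, tab$grid_n)
})
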