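# Shared fixtures. Expensive objects (full-size LUTs) are built once per
# test run and cached.

.pipeline_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .pipeline_cache))
    assign(name, force(expr), envir = .pipeline_cache)
  get(name, envir = .pipeline_cache)
}

default_spec <- function() cached("spec", color_map_spec())

noiseless_model <- function()
  sensor_model(rel_noise_sigma = 0, luminance_walk_sigma = 0)

# zero-noise full-size pipeline (5x5 calibration, N = 32, B = 256)
default_pipeline <- function() cached("pipe0", {
  spec <- default_spec()
  model <- noiseless_model()
  tab <- simulate_calibration(spec, model, grid_n = 5, samples_per_point = 30,
                              seed = 1)
  fwd <- interpolate_forward(tab, N = 32)
  lut <- build_lut(fwd, B = 256, projection_depth = 0.05)
  list(spec = spec, model = model, tab = tab, fwd = fwd, lut = lut)
})

# full noisy pipeline: calibration collected with the default noisy sensor
noisy_pipeline <- function() cached("pipen", {
  spec <- default_spec()
  model <- sensor_model()
  tab <- simulate_calibration(spec, model, grid_n = 5, samples_per_point = 30,
                              seed = 1)
  fwd <- interpolate_forward(tab, N = 32)
  lut <- build_lut(fwd, B = 256, projection_depth = 0.05)
  list(spec = spec, model = model, tab = tab, fwd = fwd, lut = lut)
})

# reduced instance for exhaustive oracle comparison (N = 8, B = 32)
small_pipeline <- function() cached("pipe8", {
  spec <- default_spec()
  model <- noiseless_model()
  tab <- simulate_calibration(spec, model, grid_n = 5, samples_per_point = 5,
                              seed = 1)
  fwd <- interpolate_forward(tab, N = 8)
  lut <- build_lut(fwd, B = 32, projection_depth = 0.05)
  list(spec = spec, model = model, tab = tab, fwd = fwd, lut = lut)
})

stream_chroma <- function(stream)
  normalize_chroma(cbind(stream$r_counts, stream$g_counts, stream$b_counts),
                   on_zero = "na")

# Brute-force inverse-LUT construction straight from the definition: every
# possible quantized triple is scanned against every seed.
bf_build_lut <- function(fwd, B, projection_depth) {
  N <- fwd$N
  ij <- cbind(rep(seq_len(N), times = N), rep(seq_len(N), each = N))
  ch <- cbind(fwd$chroma[cbind(ij[, 1], ij[, 2], 1)],
              fwd$chroma[cbind(ij[, 1], ij[, 2], 2)],
              fwd$chroma[cbind(ij[, 1], ij[, 2], 3)])
  q <- quantize_chroma(ch, B)
  ord <- order(ij[, 2], ij[, 1])          # (j, i) priority
  q <- q[ord, , drop = FALSE]; ij <- ij[ord, , drop = FALSE]
  keys <- (as.numeric(q[, 1]) * B + q[, 2]) * B + q[, 3]
  first <- !duplicated(keys)
  sk <- keys[first]; sq <- q[first, , drop = FALSE]; sij <- ij[first, , drop = FALSE]
  all_t <- as.matrix(expand.grid(qr = 0:(B - 1), qg = 0:(B - 1), qb = 0:(B - 1)))
  all_k <- (as.numeric(all_t[, 1]) * B + all_t[, 2]) * B + all_t[, 3]
  non <- !(all_k %in% sk)
  C <- all_t[non, , drop = FALSE]
  D2 <- outer(rowSums(C^2), rowSums(sq^2), "+") - 2 * tcrossprod(C, sq)
  best <- max.col(-D2, ties.method = "first")
  cheb <- pmax(abs(C[, 1] - sq[best, 1]), abs(C[, 2] - sq[best, 2]),
               abs(C[, 3] - sq[best, 3]))
  keep <- cheb <= projection_depth * (B - 1)
  keys_all <- c(sk, all_k[non][keep])
  ij_all <- rbind(sij, sij[best[keep], , drop = FALSE])
  prov <- rep(c("SEED", "PROJECTED"), c(length(sk), sum(keep)))
  o <- order(keys_all)
  list(keys = keys_all[o], ij = ij_all[o, , drop = FALSE], provenance = prov[o])
}

# 8-connected component count of an ink mask (TRUE = ink); plain BFS.
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    nr <- nrow(mask)
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      r <- (p - 1) %% nr + 1; cc <- (p - 1) %/% nr + 1
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- r + dr; c2 <- cc + dc
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= ncol(mask)) {
          p2 <- (c2 - 1) * nr + r2
          if (mask[p2] && lab[p2] == 0L) { lab[p2] <- cur; queue <- c(queue, p2) }
        }
      }
    }
  }
  cur
}

# a long meandering pen-down script with n_samples samples at the model rate
meander_script <- function(spec, n_samples, rate = 30) {
  lo <- (spec$side_mm - spec$usable_span_mm) / 2
  hi <- lo + spec$usable_span_mm
  m <- 0.1 * spec$usable_span_mm
  wp <- rbind(c(lo + m, lo + m), c(hi - m, lo + m), c(lo + m, hi - m),
              c(hi - m, hi - m), c(lo + m, lo + m), c(hi - m, hi - m))
  pen_script(pen_down(wp, n_samples / rate))
}
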