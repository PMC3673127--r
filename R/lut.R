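#' Quantize a chromaticity to a byte-like grid
#'
#' Each channel is mapped to `floor(channel * (B - 1) + 0.5)`, an integer in
#' `[0, B - 1]`. With the default B = 256 this preserves the byte-space
#' semantics of the +/-5% projection tolerance.
#'
#' @param chroma A length-3 chromaticity or n x 3 matrix.
#' @param B Quantization levels per channel (default 256).
#' @return Integer vector/matrix of quantized levels.
#' @export
quantize_chroma <- function(chroma, B = 256) {
  vec <- is.null(dim(chroma))
  m <- if (vec) matrix(chroma, ncol = 3) else as.matrix(chroma)
  q <- floor(m * (B - 1) + 0.5)
  q[!is.na(q) & q < 0] <- 0; q[!is.na(q) & q > B - 1] <- B - 1
  storage.mode(q) <- "integer"
  if (vec) drop(q) else q
}

#' @rdname quantize_chroma
#' @param q Quantized triple(s) from [quantize_chroma()].
#' @export
dequantize_chroma <- function(q, B = 256) {
  vec <- is.null(dim(q))
  m <- if (vec) matrix(q, ncol = 3) else as.matrix(q)
  out <- m / (B - 1)
  if (vec) drop(out) else out
}

encode_key <- function(q, B) (as.numeric(q[, 1]) * B + q[, 2]) * B + q[, 3]

decode_key <- function(key, B) {
  qb <- key %% B
  qg <- (key %/% B) %% B
  qr <- key %/% (B * B)
  cbind(qr, qg, qb)
}

#' Build the inverse lookup table (quantized chromaticity to pixel)
#'
#' The calibrated color surface is approximately a planar cut through
#' chromaticity space; measured colors scatter around it. The LUT is built in
#' two stages. Seeding: each pixel's forward-map chromaticity is quantized
#' and assigned to that pixel (collisions resolved to the pixel with the
#' lexicographically smaller (j, i); a build with more than 1% colliding
#' pixels fails — the map is not injective enough at this quantization).
#' Projection ("fleshing out"): every unassigned quantized triple whose
#' per-channel (Chebyshev) distance to its nearest seed — nearest by
#' Euclidean distance in quantized space, ties broken by smaller (j, i) — is
#' at most `projection_depth * (B - 1)` in every channel receives that seed's
#' pixel. All other triples stay unassigned and read as off-map, which is
#' used redundantly with the luminance-drop rule to detect pen lift-off.
#' The depth trades strict off-map rejection against noise tolerance; the
#' default 0.05 mirrors the +/-5%-of-byte-range balance.
#'
#' @param fwd A [interpolate_forward()] result.
#' @param B Quantization levels per channel (default 256).
#' @param projection_depth Per-channel projection depth as a fraction of the
#'   channel range (default 0.05).
#' @return An object of class `inverse_lut`: sorted sparse entries mapping
#'   quantized triples to 1-based pixel indices, with per-entry provenance
#'   (`"SEED"` or `"PROJECTED"`).
#' @export
build_lut <- function(fwd, B = 256, projection_depth = 0.05) {
  stopifnot(inherits(fwd, "forward_map"), B >= 2,
            projection_depth >= 0, projection_depth < 1)
  N <- fwd$N
  ij <- cbind(i = rep(seq_len(N), times = N), j = rep(seq_len(N), each = N))
  chroma <- cbind(fwd$chroma[cbind(ij[, 1], ij[, 2], 1)],
                  fwd$chroma[cbind(ij[, 1], ij[, 2], 2)],
                  fwd$chroma[cbind(ij[, 1], ij[, 2], 3)])
  q <- quantize_chroma(chroma, B)
  keys <- encode_key(q, B)
  # seed priority: lexicographically smaller (j, i) wins collisions
  prio <- order(ij[, 2], ij[, 1])
  keys_p <- keys[prio]; q_p <- q[prio, , drop = FALSE]; ij_p <- ij[prio, , drop = FALSE]
  first <- !duplicated(keys_p)
  n_coll <- sum(!first)
  if (n_coll > 0.01 * N * N)
    stop(sprintf(
      "LUT build failed: %d of %d pixels collide in quantized chromaticity (> 1%%); map not injective enough at B = %d",
      n_coll, N * N, B))
  seed_keys <- keys_p[first]
  seed_q <- q_p[first, , drop = FALSE]
  seed_ij <- ij_p[first, , drop = FALSE]
  n_seed <- length(seed_keys)

  d <- projection_depth * (B - 1)
  rad <- floor(d)
  proj_keys <- numeric(0)
  proj_ij <- matrix(integer(0), 0, 2)
  if (rad >= 1 && n_seed > 0) {
    off <- as.matrix(expand.grid(-rad:rad, -rad:rad, -rad:rad))
    storage.mode(off) <- "integer"
    k_off <- nrow(off)
    # candidate triples: union of Chebyshev boxes around seeds (chunked)
    chunks <- split(seq_len(n_seed), ceiling(seq_len(n_seed) / 32))
    cand_keys <- unique(unlist(lapply(chunks, function(ix) {
      m <- length(ix)
      cand <- off[rep(seq_len(k_off), m), , drop = FALSE] +
        seed_q[rep(ix, each = k_off), , drop = FALSE]
      ok <- cand[, 1] >= 0L & cand[, 1] < B & cand[, 2] >= 0L & cand[, 2] < B &
        cand[, 3] >= 0L & cand[, 3] < B
      unique(encode_key(cand[ok, , drop = FALSE], B))
    })))
    cand_keys <- setdiff(cand_keys, seed_keys)
    if (length(cand_keys)) {
      C <- decode_key(cand_keys, B)
      s2 <- rowSums(seed_q^2)
      best <- integer(length(cand_keys))
      idx <- split(seq_along(cand_keys), ceiling(seq_along(cand_keys) / 20000))
      for (ix in idx) {
        D2 <- outer(rowSums(C[ix, , drop = FALSE]^2), s2, "+") -
          2 * tcrossprod(C[ix, , drop = FALSE], seed_q)
        best[ix] <- max.col(-D2, ties.method = "first")  # ties: smaller (j, i)
      }
      cheb <- pmax(abs(C[, 1] - seed_q[best, 1]),
                   abs(C[, 2] - seed_q[best, 2]),
                   abs(C[, 3] - seed_q[best, 3]))
      eligible <- cheb <= d
      proj_keys <- cand_keys[eligible]
      proj_ij <- seed_ij[best[eligible], , drop = FALSE]
    }
  }
  all_keys <- c(seed_keys, proj_keys)
  all_ij <- rbind(seed_ij, proj_ij)
  prov <- rep(c("SEED", "PROJECTED"), c(length(seed_keys), length(proj_keys)))
  o <- order(all_keys)
  structure(
    list(B = as.integer(B), projection_depth = projection_depth,
         N = N, pitch_mm = fwd$pitch_mm, origin_mm = fwd$origin_mm,
         keys = all_keys[o], ij = all_ij[o, , drop = FALSE],
         provenance = prov[o], n_seed = length(seed_keys),
         n_projected = length(proj_keys), n_collisions = n_coll,
         map_spec_hash = fwd$map_spec_hash),
    class = "inverse_lut")
}

#' @export
print.inverse_lut <- function(x, ...) {
  cat(sprintf("Inverse LUT: B = %d levels/channel, projection depth %.3g (%.3g levels)\n",
              x$B, x$projection_depth, x$projection_depth * (x$B - 1)))
  cat(sprintf("  lattice: %d x %d pixels, pitch %.4g mm\n", x$N, x$N, x$pitch_mm))
  cat(sprintf("  entries: %d seed + %d projected (%d seed collisions)\n",
              x$n_seed, x$n_projected, x$n_collisions))
  cat(sprintf("  map spec hash: %s\n", x$map_spec_hash))
  invisible(x)
}

#' Look up pixel positions for chromaticities
#'
#' Quantizes each chromaticity and returns the LUT entry, or off-map (NA)
#' when the quantized triple has no entry — i.e. the color lies farther from
#' the calibrated color surface than the projection depth.
#'
#' @param lut An [build_lut()] result.
#' @param chroma A length-3 chromaticity or n x 3 matrix.
#' @return An n x 2 integer matrix of 1-based (i, j) pixel indices; NA rows
#'   mark off-map colors.
#' @export
lut_lookup <- function(lut, chroma) {
  vec <- is.null(dim(chroma))
  q <- quantize_chroma(chroma, lut$B)
  if (is.null(dim(q))) q <- matrix(q, ncol = 3)
  keys <- encode_key(q, lut$B)
  pos <- match(keys, lut$keys)
  out <- cbind(i = lut$ij[pos, 1], j = lut$ij[pos, 2])
  out
}

#' @export
#' @rdname lut_lookup
#' @param object An `inverse_lut`.
#' @param ... Unused.
predict.inverse_lut <- function(object, chroma, ...) lut_lookup(object, chroma)

#' Pixel-center mm coordinates for looked-up pixels
#'
#' @param lut An `inverse_lut`.
#' @param ij An n x 2 matrix of 1-based pixel indices (NA rows allowed).
#' @return An n x 2 matrix of (x_mm, y_mm) pixel-center frame coordinates.
#' @export
pixel_to_mm <- function(lut, ij) {
  ij <- matrix(as.numeric(ij), ncol = 2)
  cbind(x_mm = lut$origin_mm + (ij[, 1] - 0.5) * lut$pitch_mm,
        y_mm = lut$origin_mm + (ij[, 2] - 0.5) * lut$pitch_mm)
}

#' Write / read an inverse LUT file
#'
#' Header `#` lines record B, depth, N, geometry, the map-spec hash and entry
#' counts; then one row per entry (`qr qg qb i j provenance`, tab-separated,
#' 0-based pixel indices) sorted by (qr, qg, qb) for bit-exact
#' reproducibility.
#'
#' @param lut An `inverse_lut`.
#' @param path File path.
#' @export
write_lut <- function(lut, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# B=%d", lut$B),
               sprintf("# projection_depth=%.10g", lut$projection_depth),
               sprintf("# N=%d", lut$N),
               sprintf("# pitch_mm=%.10g", lut$pitch_mm),
               sprintf("# origin_mm=%.10g", lut$origin_mm),
               sprintf("# map_spec_hash=%s", lut$map_spec_hash),
               sprintf("# n_seed=%d", lut$n_seed),
               sprintf("# n_projected=%d", lut$n_projected)), con)
  writeLines("qr\tqg\tqb\ti\tj\tprovenance", con)
  trip <- decode_key(lut$keys, lut$B)
  df <- data.frame(trip[, 1], trip[, 2], trip[, 3],
                   lut$ij[, 1] - 1L, lut$ij[, 2] - 1L, lut$provenance)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_lut
#' @export
read_lut <- function(path) {
  meta <- read_hash_meta(path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  B <- as.integer(meta[["B"]])
  keys <- encode_key(as.matrix(df[, c("qr", "qg", "qb")]), B)
  o <- order(keys)
  structure(
    list(B = B, projection_depth = as.numeric(meta[["projection_depth"]]),
         N = as.integer(meta[["N"]]), pitch_mm = as.numeric(meta[["pitch_mm"]]),
         origin_mm = as.numeric(meta[["origin_mm"]]),
         keys = keys[o],
         ij = cbind(i = df$i + 1L, j = df$j + 1L)[o, , drop = FALSE],
         provenance = as.character(df$provenance)[o],
         n_seed = as.integer(meta[["n_seed"]]),
         n_projected = as.integer(meta[["n_projected"]]),
         n_collisions = NA_integer_,
         map_spec_hash = meta[["map_spec_hash"]]),
    class = "inverse_lut")
}
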