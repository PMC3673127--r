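---
title: "Color-map position decoding: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Color-map position decoding: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the encoding model,
the calibration and inverse-lookup procedure, what the sensor simulator
does and does not emulate, the numerical choices, and the known
limitations. Nothing here states an empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## The encoding model

The tablet surface is a square color map of side $L$ (200 mm) carrying
three overlapping linear pigment gradients, one per printer pigment
(cyan, magenta, yellow), with unit axis vectors $u_k$ at 0°, 120° and 240°
from the map's $+x$ axis. With $c$ the map center, pigment $k$ at position
$p$ is

$$P_k(p) = \mathrm{low}_k + (\mathrm{high}_k - \mathrm{low}_k)\,
           \frac{(p - c)\cdot u_k + L/2}{L},$$

clamped to its byte range (clamping can engage only in the frame corners,
outside the usable span). The byte sub-range $[\mathrm{0x20},
\mathrm{0xD0}]$ is a configurable stand-in: the deployed map kept only the
interior byte range in which channel response is most sensitive, without
publishing the numbers. Printed color is taken as the ideal subtractive
complement, $R = 255 - C$ and so on; any strictly monotone channel-wise
printer model preserves the decoding algorithm, and the complement is the
simplest invertible choice.

Two structural facts follow from the 120° geometry and drive everything
downstream:

* $\sum_k u_k = 0$, so total pigment $C + M + Y$ — and hence total
  reflected signal $R + G + B$ — is constant across the (unclamped) map.
  The channel sum is therefore a pure luminance measure, and dividing each
  channel by it (chromaticity normalization) discards exactly the
  nuisance factors (fiber bending, supply drift, map wear) while keeping
  all the position information.
* Chromaticity is an **affine, injective** function of position over the
  usable area, so a 5 × 5 calibration and quadratic interpolation can
  represent it essentially exactly.

A consequence worth stating plainly: position information lives in
chromaticity *differences*, and the whole usable area spans only about 30%
of the chromaticity scale per channel (about 77 of 255 quantization
levels). Neighboring positions 1 mm apart move chromaticity by roughly
half a quantization level, so after quantization the map is injective at
the decoded pixel pitch (4.375 mm; the seed table has zero collisions,
which the tests check exhaustively), but *not* on a 1 mm grid — a
pigeonhole fact of the geometry, not an implementation defect.

## Calibration and forward interpolation

Calibration prompts the pen to a `grid_n` × `grid_n` lattice (default
5 × 5, endpoints on the usable-span boundary) and records the mean
chromaticity of `samples_per_point` reads (default 30, about 1 s at 30
samples/s). Each read is normalized first, then averaged, then the mean is
renormalized: normalizing before averaging makes the point estimate
indifferent to per-sample luminance. The alternative order (average raw
counts, then normalize) is equivalent in the noiseless limit; the
normalized-first order was fixed because it is the one that inherits the
luminance-cancellation guarantee sample by sample.

The forward map fits, per color channel independently, a least-squares
quadratic along each calibration row, evaluates it at the $N$ pixel-center
abscissae (default $N = 32$), then fits a quadratic down each pixel column
of the intermediate lattice and evaluates at pixel-center ordinates;
finally each pixel's triple is renormalized to sum 1. Pixel $i$ (0-based)
covers $[i\,\delta, (i{+}1)\,\delta)$ of the span, $\delta =
\mathrm{span}/N$, and polynomials are evaluated at centers
$(i{+}0.5)\,\delta$. Fits use a centered, scaled basis (exactness for
degree ≤ 2 is unaffected; conditioning is). Fields that are per-axis
polynomials of degree ≤ 2 are reproduced to numerical precision (the
suite asserts ≤ 1e−9), and for the affine default map the x-then-y and
y-then-x pass orders agree to the same tolerance; the pass order is still
exposed as a flag because for non-quadratic real-world fields the two
orders genuinely differ, and that discrepancy should be visible rather
than hidden.

## The inverse lookup table

Decoding needs position as a function of color. The calibrated color
surface is (approximately) a planar cut through chromaticity space, so the
table is built sparsely in two stages over a $B^3$ quantized chromaticity
grid ($B = 256$ levels per channel, `floor(c (B-1) + 0.5)`):

1. **Seeding.** Each pixel's forward-map chromaticity quantizes to a
   triple assigned to that pixel. Collisions keep the pixel with the
   lexicographically smaller $(j, i)$; a build in which more than 1% of
   pixels collide aborts loudly (the map is not injective enough at that
   quantization).
2. **Projection.** Every unassigned triple whose per-channel (Chebyshev)
   distance to its *nearest* seed — nearest by Euclidean distance in
   quantized space, ties broken by smaller Euclidean then smaller
   $(j, i)$ — is at most $d = \mathrm{depth}\,(B{-}1)$ in every channel
   receives that seed's pixel. Everything else stays unassigned and reads
   **off-map**.

The envelope is per-channel (a Chebyshev box) while "nearest" is
Euclidean, because the tolerance is stated per channel but the notion of
nearest assigned color is metric; the two are deliberately distinct. The
default depth 0.05 preserves the ±5%-of-byte-range balance between strict
off-map rejection (robust lift-off detection) and acceptance of noisy
near-surface colors. The implementation enumerates candidate boxes around
seeds and resolves nearest seeds by blocked distance computation; the test
suite proves it equal, entry for entry, to a brute-force scan of every
possible triple against every seed on a reduced instance ($N = 8$,
$B = 32$), and audits the depth envelope exhaustively.

The table is built over *normalized chromaticity*, not raw RGB bytes:
normalized values are what position determination uses, and building the
inverse in the same space keeps the whole decode path luminance-invariant
by construction (scaling every raw count by any constant changes no
decoded pixel — asserted exactly in the tests). The cost of this choice is
a real degeneracy: pure white has chromaticity $(1/3, 1/3, 1/3)$, which is
exactly the chromaticity of the map's neutral center. A white, off-map
read therefore does *not* read off-map — it projects to a near-center
pixel. Saturated off-surface colors (e.g. chromaticity $(1, 0, 0)$) do
read off-map. Lift-off detection consequently cannot rely on the off-map
channel alone and is anchored on the luminance-drop rule below.

## Lift-off, segmentation, and kinematics

The pen's lift collapses the returned signal; a fall of the summed counts
by more than `drop_fraction` (default 0.5) of a value seen within the
trailing `drop_window_s` (default 0.25 s) raises the lift-off flag, with
"signal" taken as the sum of the three raw channels (the natural luminance
proxy — the same quantity normalization divides by). The reference is the
sliding window's start, evaluated at every sample, so a 60% drop in
200 ms flags while the same drop spread over a second does not. An
off-map color inside the window is a redundant lift-off channel,
controlled by `require_offmap_confirmation`.

The decoder keeps a latched contact state: the sum-drop rule sets it, a
symmetric rise rule (signal recovering past $1/(1-\mathrm{drop\_fraction})$
of a recent value) clears it. Off-map or all-zero samples are pen-up
individually but do not latch — an isolated off-map noise spike must not
swallow the rest of a stroke. The state starts as "in contact": a purely
relative detector cannot bootstrap from an absolute threshold without
breaking luminance invariance, so streams are expected to begin with the
pen down or with an explicit drop. Because the simulated lift is
multiplicative, chromaticity alone cannot see it — which is precisely the
situation the drop rule exists for.

Contiguous pen-down runs are strokes; a pen-up run of at least
`completion_dwell_s` (default 1.0 s; the deployed value was
operator-specified) completes the response, stamps `completed_at`, clears
the virtual writing area and emits a trial-advance event (the software
stand-in for the serial cue that advanced the stimulus computer).

Within strokes, pixel-center positions are smoothed by a causal rolling
mean of `smooth_window` points (default 5), reset at stroke boundaries.
Causality is a real-time display constraint; its price is a delay of
$(w-1)/2$ sample periods (67 ms at 30 Hz) and a shortened stroke tail,
both of which the decoder reports. Metrics: per-stroke path length and
finite-difference speeds on the smoothed positions; a hesitation is an
in-stroke interval of at least `hesitation_dwell_s` (default 0.3 s) in
which the pen stays within one pixel pitch of the interval's first point
(the construct is standard; this dwell/displacement operationalization is
this package's); lift-off count within a response is strokes − 1.

Quantization and the causal tail bias speed estimates low by a few
percent: a 140 mm straightedge stroke traversed in 2 s (nominal 70 mm/s)
decodes to ≈ 66 mm/s, and the test suite pins that value against an
independent arithmetic oracle rather than the nominal figure.

## The sensor simulator

`read_counts()` models counts = gain ⊙ (spot-averaged map color) ×
luminance × (1 + ε), with an extra `liftoff_floor` factor (default 0.05,
well under the 0.5 the drop rule needs) when the pen is up. The spot
average uses a fixed 37-point hexagonal quadrature over the illuminated
disc (radius 1 mm, from the 2 mm fibers): deterministic, and exact for
linear fields by point symmetry (a Monte-Carlo disc average is used as a
test oracle only). ε is independent multiplicative Gaussian noise per
channel (`rel_noise_sigma`, default 0.02) and luminance follows a slow
random walk in log space (`luminance_walk_sigma`, default 0.002 per
sample) shared across channels. The artifact classes are the documented
ones (fiber bending, supply variation, wear); their distributions and
magnitudes are not published, so these defaults are chosen once as
plausible placeholders — multiplicative forms, because they are exactly
what sum-normalization is designed to cancel. Streams are clocked at
`sample_rate_hz` (default 30), and a stream is a deterministic function of
(map, model, script, seed).

What the simulator deliberately does **not** emulate: printer ink
saturation and dot gain, specular reflection, stray room light, sensor
frequency-output details, and any channel nonlinearity. Consequences for
interpretation: passing tests show the *algorithms* are correct under the
stated noise model, not that a physical build achieves any particular
precision. One concrete gap: in the real system, position dispersion
roughly doubled from map center to edges, driven by sensitivity
compression near the gradient range ends; with an exactly affine
simulated chroma field that mechanism is absent, and the remaining ones
(chromaticity-noise magnitude growing toward extremal positions;
quadratic-fit leverage error from a noisy calibration) are weak. The
straightedge experiment therefore reproduces sub-pixel central dispersion
(≈ 2.7 mm at the default noise) robustly, but the center-to-edge
*increase* only weakly.

## The straightedge experiment

Traversals of constant y (and constant x) are simulated at `traverse_s`
(default 2 s) per line, decoded without smoothing, and the standard
deviation of the decoded perpendicular coordinate is pooled separately
over the central 50% of the traversal axis and over the outer quadrants.
Default line positions are `n_lines` evenly spaced *interior* offsets:
a line at the exact reachable limit is a degenerate measurement, since the
decoded lattice cannot express outward deviations and edge clamping
truncates the dispersion toward zero. For the precision evaluation the
calibration is taken with the *noisy* sensor model — that is the deployed
condition; the zero-noise calibration is reserved for the exactness
checks (pixel round-trip), where it is the stated condition.

## Numerical choices and degenerate inputs

* Byte rounding is half-up (`floor(x + 0.5)`) at raster and quantization
  time; the continuous field is kept unrounded for simulation.
* Quadratic fits are ordinary least squares on a centered/scaled basis;
  rank-deficient fits fall back to zero coefficients for the dropped
  terms (constant data along a row is legal); non-finite calibration
  values are rejected.
* Seed collisions and projection ties are resolved by lexicographic
  $(j, i)$, making LUT builds bit-reproducible; LUT files are sorted by
  quantized triple for byte-identical reruns.
* All-zero sensor reads are invalid samples, treated as pen-up by the
  decoder and rejected during calibration (with the offending grid point
  named).
* Chromaticity tolerance for the sum-to-one invariant is 1e−9; quadratic
  reproduction is asserted at 1e−9; file round-trips at 1e−12.
* Problem sizes in the tests and acceptance script — full pipeline at
  N = 32, B = 256 (one zero-noise and one noisy build), the exhaustive
  oracle at N = 8, B = 32, 10 straightedge traversals, 500-sample
  invariance streams, 10⁴-sample smoothing experiments, 20-seed noise
  curves — were chosen as the smallest sizes at which each property is
  meaningfully exercised.

## Known limitations

* The white/neutral-gray chromaticity degeneracy described above: pen
  removal over white surroundings is detected by the luminance drop, not
  by color.
* The byte sub-range, noise magnitudes and per-channel gains of the
  deployed hardware are unpublished; the defaults here are stand-ins, and
  quantitative dispersion figures from the simulator characterize the
  simulator, not the hardware.
* Quantized injectivity holds at the pixel pitch, not at 1 mm; finer
  lattices (larger N) would need either a larger chromaticity footprint
  (wider byte ranges) or finer quantization (larger B).
* The causal smoothing tail can leave a rendered letter's final stroke
  visually short of its target (the assembled "H" can render as two ink
  components), which is the latency the decoder reports, made visible.
* No GUI, no serial-port hardware triggering, no handwriting recognition:
  responses are rasters plus kinematics, graded by humans.
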