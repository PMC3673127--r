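Package: chromapad
Title: Color-Map Position Decoding for an MRI-Compatible Writing Pad
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements the software side of a fiber-optic writing pad that
    encodes pen position in a printed color map built from three overlapping
    pigment gradients oriented 120 degrees apart. Provides the continuous
    color-map model and raster export, a simulator for the pen/LED/color-sensor
    chain (spot averaging, channel gains, luminance drift, sampling noise, and
    lift-off signal collapse), chromaticity normalization, guided 5x5 grid
    calibration with separable second-order polynomial interpolation to a pixel
    lattice, construction and querying of an inverse lookup table from
    quantized chromaticity to pixel position with a bounded projection depth,
    and a real-time stroke decoder with lift-off detection, response
    segmentation, rolling-average smoothing, letter rasterization, handwriting
    kinematics (stroke order, speed, hesitations, lift-offs), and a
    straightedge precision experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    jsonlite
Config/testthat/edition: 3
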