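Package: krawmark
Title: Krawtchouk Moment Watermarking as a Black-Box Adversarial Attack
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Local, moment-domain digital watermarking of grayscale images by
    dither modulation (quantization index modulation) of discrete orthogonal
    Krawtchouk moments, and a black-box attack harness that sweeps the
    embedding parameters (locality p1/p2, message length L, quantization step
    delta) against an arbitrary image classifier, scoring distortion with the
    structural similarity index (SSIM). Includes a synthetic medical-like
    phantom generator and a deterministic nearest-centroid toy classifier so
    the whole pipeline runs without external data, plus PNG/PGM/TIFF image
    I/O, CSV sweep reports, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
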