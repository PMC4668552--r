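Package: mrcomplete
Title: Low-Rank Matrix Completion for Accelerated 2D Magnetic Resonance
    Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs full 2D time-domain magnetic-resonance signal
    matrices from a small random subset of their entries by singular value
    thresholding (SVT), the iterative proximal solver for trace-norm
    minimizing matrix completion.  Includes a density-matrix simulator of
    three-pulse (stimulated-echo) ESEEM experiments on the nitrogen-vacancy
    centre in diamond, a generic low-rank damped-cosine signal generator,
    uniform random sampling masks, Fourier-domain evaluation metrics
    (spectra, peak detection, signal-to-noise ratio, fidelity, singular
    value profiles) and seeded sampling-fraction and threshold sweep
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
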