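Package: RLDeconv
Title: Block-Wise Richardson-Lucy Deconvolution of 3-D Microscopy Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Richardson-Lucy (RL) deconvolution for 3-D fluorescence
    volumes (z-stacks) with an FFT circular-convolution core, a
    memory-bounded overlapping-block engine that splits a volume into
    padded blocks, deconvolves each independently and merges the central
    cores, a valid-region calculus quantifying how edge effects shrink
    the trustworthy region per iteration, and the 1-D Gaussian
    closed-form variance recursion used as an analytic oracle. Includes
    a synthetic-data module (bead and filament phantoms, Gaussian and
    astigmatic point spread functions, Poisson forward model), TIFF/MRC
    volume I/O and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tiff,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
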