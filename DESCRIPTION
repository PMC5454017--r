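Package: fluorospec
Title: Label-Free Tissue Fluorescence Spectroscopy Analysis and Simulation
Version: 0.1.0
Authors@R:
    person("fluorospec", "developers", email = "fluorospec@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing label-free (autofluorescence) emission scans of
    brain tissue: replicate averaging with standard deviations, normalization to
    the maximum of the diseased-group average, windowed fluorophore peak
    extraction (tryptophan, NADH, FAD), peak intensity ratios and fold changes,
    first-derivative spectral profiles with ascending/descending extrema, and
    Welch group comparison. Includes a forward simulator of tissue emission
    spectra built on a simple photophysical model (radiative/nonradiative rates,
    quantum yield, collection solid angle, Forster resonance energy transfer
    between a tryptophan donor and an NADH acceptor), calibrated presets that
    emulate spectrofluorometer scans of Alzheimer's-model and normal brain
    tissue, and a command-line interface for simulate/analyze/reproduce
    workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
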