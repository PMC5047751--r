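Package: crossact
Title: Cross-Environment Activation of Hippocampal Place-Cell Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for quantifying cross-environment activation of
    hippocampal CA1 place-cell ensembles between lap running on a linear track
    and head-rotation events in a small box. Provides a synthetic session
    generator (tuned cell populations with configurable overlap, Poisson
    spiking, theta/ripple field potentials, optional injected replay),
    behavioural and electrophysiological event detection (rotation events,
    laps, stop periods, sharp-wave ripples, LFP spectra), firing-rate curves
    and tuning statistics (spatial information, Rayleigh head-direction test,
    rotation- and lap-consistency with shuffle nulls), common-cell and
    proportion-difference-index accounting, and rank-order sequence matching
    of rotation and ripple sequences against track templates with
    permutation-based significance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
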