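Package: hippoblink
Title: Dissociating Spatial Tuning and Brain State from Stimulus-Evoked
    Hippocampal Firing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for dorsal CA1 recordings during trace
    eyeblink conditioning on a linear track. Builds occupancy-normalized
    directional place-field maps, quantifies stimulus-evoked firing with a
    Poisson trial-reliability statistic and spatial-tuning correlations,
    detects hippocampal ripples on multi-channel LFP, and analyses theta
    phase resets versus phase shifts with a locality-guaranteed short-time
    Fourier transform. Includes a synthetic-session generator implementing
    the arousal-gated place-cell model (and the CS-cell and CS-place-cell
    alternatives) so every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
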