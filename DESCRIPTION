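Package: titinIso
Title: Mechanochemistry of Disulfide Isomerization in Titin Ig Domains
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models and simulation tools for single-molecule force
    spectroscopy of titin immunoglobulin (Ig) domains carrying the conserved
    CysB/CysF/CysG cysteine triad. Provides worm-like-chain and
    freely-jointed-chain polymer elasticity with contour-length bookkeeping
    that converts unfolding, disulfide isomerization and reduction events
    into extension steps in nanometers; an exact stochastic simulator of the
    domain state machine under constant-force, force-ramp and three-pulse
    protocols with Bell force-dependent rates; maximum-likelihood dwell-time
    fitting of the sequential unfolding/isomerization scheme with censoring
    and bootstrap errors; synthesis and analysis of noisy staircase AFM
    traces (change-point step detection, Gaussian mixture histogram fits,
    refolding fractions, fingerprint filters); kinetic Monte Carlo of the
    whole titin I-band under cyclic force comparing redox scenarios and
    isoforms; and a sequence scanner classifying Ig domains by their
    CysB/CysF/CysG content against the I91 reference numbering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    pracma,
    minpack.lm,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, Proteomics, StructuralPrediction
RoxygenNote: 7.3.3
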