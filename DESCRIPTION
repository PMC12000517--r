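Package: fibrilscape
Title: Quantitative Analysis of Polyglutamine Fibril Formation and Morphology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis backbone for studies of huntingtin exon-1 (polyQ)
    amyloid fibril formation and its modulation by small molecules such as
    curcumin. Implements a small-angle X-ray scattering (SAXS) model for
    bundled long rod-like fibrils (orientation-averaged cylinder form factor
    with log-normal cross-section polydispersity, a PRISM-style structure
    factor for inter-fibrillar correlation, and a power-law background),
    multi-start least-squares fitting of measured or simulated 1D profiles,
    power-law, correlation-peak and cross-sectional Guinier analyses, polyQ
    fibril-core geometry models (extended strand versus beta-hairpin,
    single versus multi-filament), Thioflavin-T aggregation-kinetics
    preprocessing with lag-phase extraction, 1D solid-state NMR window
    integration for glutamine/proline ratio analysis, and TEM fibril-width
    morphometrics. A seeded synthetic-data module generates inputs with the
    statistical structure each stage assumes, so the full pipeline runs and
    tests without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
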