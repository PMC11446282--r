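Package: helixscreen
Title: Interface-Confidence Screening and Register Annotation of
    Predicted Helix-Receptor Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for screening predicted protein complex models in which
    an alpha-helical binding element docks onto a receptor surface, modelled
    on the recognition of substrates by the PP2A-B55 phosphatase holoenzyme.
    Implements two-stage interface-residue detection restricted to a
    conserved binding site, confidence scoring from per-residue pLDDT and
    predicted aligned error (PAE) matrices with sentinel handling, helix
    register assignment against receptor surface patches, design-refolding
    quality control by rigid-body superposition, saturation binding-curve
    fitting, and seeded synthetic-fixture generators for all of the above.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    broom,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
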