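Package: crowdnn
Title: Nearest-Neighbor Thermodynamics of RNA Duplexes under Molecular
    Crowding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the hybridization thermodynamics (enthalpy, entropy,
    free energy at 37 degrees C, and melting temperature) of RNA duplexes
    with a nearest-neighbor model whose parameters were determined under
    cell-mimicking molecular crowding (40 wt% PEG200, 100 mM NaCl).  Each
    nearest-neighbor free energy is decomposed into bulk, cation,
    excluded-volume and water-activity contributions, so that parameter
    sets can be recomposed for arbitrary cosolutes, cosolute
    concentrations and cation conditions, including potassium and
    intracellular cation compositions.  Also provides the linear
    least-squares machinery used to derive nearest-neighbor parameters
    from per-duplex melting data, a van't Hoff analysis of melting
    temperature versus strand concentration, crowding-aware hairpin and
    loop rules, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
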