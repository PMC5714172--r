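Package: marinercleave
Title: Cleavage-Topology Models and Subunit-Mixing Simulations for
    mariner Transposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting how a mariner-family transposase cleaves
    the two DNA strands at its transposon ends. Implements exhaustive
    endpoint simulations of wild-type/catalytically-dead transposase mixing
    experiments under competing cleavage-topology models (single dimer
    versus dimer-of-dimers, with every assignment of the four strand nicks
    to active sites), binomial and kinetic subunit-exchange models for
    dimer redistribution, master-equation kinetics of ordered strand
    nicking with a leaky 5'-before-3' gate, least-squares discrimination
    of the models against gel-band quantifications, an idealized B-form
    DNA phosphate-trace builder for scissile-phosphate geometry, and
    seeded synthetic-data generators emulating densitometry measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    deSolve,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    Biostrings,
    withr
Config/testthat/edition: 3
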