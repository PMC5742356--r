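Package: scfvtools
Title: Annotation and Clone Tracking for Full-Length scFv Long-Read Amplicons
Version: 0.1.0
Authors@R:
    person("Repertoire", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of full-length single chain Fragment variable (scFv)
    amplicon reads produced by long-read circular-consensus sequencing of
    phage-display combinatorial libraries. Detects and annotates the two
    variable domains (VH and VL) of each read against a germline V/(D)/J
    reference, extracts CDR3 junctions, applies germline-identity and
    reading-frame filters, ranks VH-VL clonotype associations, and tracks a
    reference clone across PCR samples and sequencing cells with mutation
    description in IMGT-style nomenclature, mutation localization relative to
    the amplicon geometry, and replicate-based provenance classification.
    Includes a seeded synthetic scFv library and read simulator that emulates
    the amplicon geometry, clone-abundance enrichment, light-chain-biased
    library mutations, and a residual consensus error model with primer-end
    artifacts, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
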