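Package: cactkey
Title: Identification Toolkit for Cyst Nematodes of the Genus Cactodera
Version: 1.0.0
Authors@R:
    person("cactkey", "developers", email = "cactkey@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying cyst-forming nematodes of the genus
    Cactodera (Nematoda: Heteroderinae). Ships a versioned comparative
    character matrix for all seventeen species (cyst, second-stage
    juvenile and egg characters), an executable dichotomous key evaluated
    with three-valued (Kleene) logic so that interval data and missing
    characters propagate honestly, a multi-access (polyclave) identifier
    that ranks candidate species by interval-overlap similarity, de Man
    ratio and publication-style morphometric summary computation, pairwise
    divergence arithmetic for pre-aligned rDNA sequences, and seeded
    simulators that generate specimens and toy alignments with known
    ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
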