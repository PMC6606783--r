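Package: peptaibols
Title: Mass-Spectrometric Identification and Classification of Peptaibols
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for identifying and classifying 19- and 20-residue
    peptaibols from electrospray mass spectra. Implements the residue-mass
    calculus for non-proteinogenic units (Aib, isovaline, C-terminal amino
    alcohols) with the flooring conventions of published compound tables,
    de novo sequence reading from b- and y-ion ladders including the
    composite step across the fragmentation-stable Gln-Aib bond, comparison
    against a reference catalogue with substitution and gap reporting,
    group assignment and elution-order nomenclature, complete-linkage
    clustering of strain production profiles, and scoring of NRPS
    adenylation-domain predictions against detected residues. Includes a
    simulator for synthetic spectra and producer-profile matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
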