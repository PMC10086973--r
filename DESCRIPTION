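Package: pestid
Title: CRISPR-Cas12a Diagnostic Assay Design from Multiple Sequence Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designs CRISPR-Cas12a (LbCas12a) diagnostic assays for species
    identification from a multiple sequence alignment of marker sequences
    (for example mitochondrial genomes). Profiles per-column conservation,
    calls variable-region hotspots flanked by conserved blocks, enumerates
    TTTV-PAM guide RNA candidates on a linker-concatenated template, screens
    guides for cross-reactivity against every non-target species (PAM
    integrity, total and seed-region mismatches, indels), and designs
    universal (conserved-flank) and species-specific recombinase polymerase
    amplification (RPA) primer pairs. Includes a ground-truth synthetic panel
    simulator for end-to-end validation and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
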