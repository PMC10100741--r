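Package: tfcoevo
Title: Residue Coevolution and DNA-Binding Specificity in Transcription
    Factor Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links transcription-factor DNA-binding specificity to
    intra-domain residue coevolution. Clusters family members into
    subclasses from position-weight-matrix similarity, scores alignment
    columns for subclass specificity (relative entropy, physicochemical
    divergence and evolutionary-rate heterogeneity with a permutation
    test), computes four residue covariation statistics (MI, MIp, OMES,
    SCA) and combines them into coevolving residue pairs, analyses the
    resulting residue network, and maps pairs onto protein-DNA complex
    structures. Ships a synthetic-family generator with planted subclass
    sites and covarying column pairs so the whole chain is testable
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    igraph,
    jsonlite,
    limma,
    mclust,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
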