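Package: mirenrich
Title: Region-Wise Enrichment of Lysine Acetylation in Membrane-Binding Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps lysine-acetylation sites onto membrane-interaction regions
    (MIRs) and non-binding regions (NBRs) of peripheral membrane-binding
    domains (BAR, PX, C2, EHD) by template-based annotation transfer.
    Provides global pairwise sequence alignment with affine gaps, Kabsch
    C-alpha superposition, homology clustering and C2 subtype assignment,
    interval annotation transfer with boundary-perturbation controls,
    amphipathic-helix detection by hydrophobic moment, region-wise
    acetylation tallies and enrichment statistics, a permutation
    significance check, and a synthetic-family generator with planted
    region-biased acetylation rates for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    yaml,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
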