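Package: nudixevol
Title: Evolutionary Analysis of the Nudix Homology Clan
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the evolution of enzymatic function across
    very large, highly diverged protein superfamilies, developed around the
    Nudix homology clan. Implements a confidence-score model that maps
    heterogeneous experimental evidence (enzyme kinetics, substrate screens,
    genetic phenotypes) to per-annotation confidence scores; a
    patristic-distance tree partitioner for divide-and-conquer alignment of
    families with tens of thousands of members; scaffold-guided merging of
    subgroup alignments that share a common core alignment; Nudix-box motif
    scanning and X-loop window localisation; and function-on-phylogeny
    analysis (midpoint rooting, functionally coherent clade detection,
    polyphyly counting). Seeded synthetic-data generators with planted
    ground truth make every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
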