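Package: ringscape
Title: Ring-System Scaffold Analysis for Drug and Clinical-Trial Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decomposes small molecules into ring systems and
    Bemis-Murcko-style frameworks with exocyclic double bonds retained,
    records the growth vectors of every ring system, and builds on that
    decomposition a set of scaffold-space analyses: novelty classification
    of molecules against a reference drug ring set, ring-system catalogs
    with frequencies and growth-vector combinations, systematic one- and
    two-atom ring mutations with valence and stability filters, scaffold
    co-occurrence networks with Girvan-Newman clustering and centrality
    rankings, and ring-property distribution reports. Includes a synthetic
    library generator with full ground truth so every pipeline stage can be
    validated end to end without proprietary compound collections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    ChemmineR,
    ChemmineOB,
    graphics,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown,
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
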