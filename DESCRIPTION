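Package: trflpr
Title: Simulation and Analysis of Terminal Restriction Fragment Length
    Polymorphism Community Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for terminal restriction fragment length
    polymorphism (T-RFLP) fingerprinting of microbial communities: in-silico
    PCR and restriction digestion of 16S rRNA gene sequences, screening of
    restriction enzymes by their power to discriminate the taxa of a clone
    library, electropherogram peak filtering, replicate-consensus alignment
    and cross-sample binning, Dice (Sorensen) similarity with within- and
    between-group summaries, furthest-neighbour OTU clustering with analytic
    rarefaction, Jukes-Cantor neighbour-joining trees with bootstrap support,
    and correspondence-analysis ordination. A seeded synthetic-community
    generator emulating a host-plant by location sampling design with a
    ubiquitous core microbiota provides ground-truthed inputs for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
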