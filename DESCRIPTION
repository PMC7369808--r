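Package: repairguide
Title: Guide Design and Sanger Trace Modelling for Site-Directed A-to-I
    Editing of Premature Termination Codons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design and quality-control toolkit for site-directed A-to-I RNA
    editing of premature termination codons (PTCs) with dCas13b/ADAR2-DD
    (REPAIRv2) systems. Scans open reading frames for premature stop codons
    and identifies their editable adenosines, constructs antisense spacers
    with explicit length and C:A mismatch geometry, emits annealing-ready
    oligonucleotide pairs with directional-cloning overhangs, enumerates
    bystander adenosines within the guide window and their protein
    consequences, predicts the translated outcome of A-to-I(=G) edits, and
    simulates four-channel Sanger electropherogram peak heights to estimate
    edited fractions and characterise the minor-peak detection limit of
    standard sequencing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
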