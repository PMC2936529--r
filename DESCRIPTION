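Package: gcsel
Title: Testing Selection on Bacterial GC-Content from Synonymous Polymorphism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the direction of synonymous GC<->AT polymorphisms at
    degenerate third codon positions in bacterial multi-strain gene
    alignments, by the minor-allele-frequency method and by Fitch parsimony
    on clock-rooted neighbor-joining trees. Compares the observed excess of
    GC->AT SNPs (Z = U/(U+V)) against the prediction of a Wright stationary
    diffusion model with mutation bias, with or without selection on GC, and
    with a correction for violations of the infinite-sites assumption under
    constant or exponentially distributed per-site mutation rates. Includes
    four-gamete and maximum chi-squared (maxchi) screens for recombination
    and homologous horizontal transfer, cohort-level regression and sign
    tests, and seeded synthetic-data generators (stationary alignments,
    tree-structured alignments with known ancestral states, recombinant
    mosaics, and whole cohorts) so every stage can be validated against
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phytools,
    seqinr,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
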