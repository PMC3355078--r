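Package: karyostab
Title: Karyotype Dynamics and Chromosome Instability in Aneuploid Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying whole-chromosome copy-number dynamics in
    aneuploid budding yeast populations: integer karyotype calling from
    flow-cytometry apparent ploidy combined with qPCR chromosome
    stoichiometry, stochastic simulation of chromosome mis-segregation in
    growing cell populations and of random spore karyotypes from triploid
    meiosis, parsimony reconstruction of karyotype networks with
    classification of chromosome instability (stable, mildly unstable,
    highly unstable), and the enrichment and comparison statistics used in
    such studies. A synthetic-data generator produces every input the
    pipeline consumes with known ground truth, so all stages can be tested
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
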