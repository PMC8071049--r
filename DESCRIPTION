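Package: nifloss
Title: Operon Detection and Gene-Loss Inference for Nitrogen Fixation Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the evolutionary history of the cyanobacterial nitrogenase
    (nif) gene repertoire from genome annotations and protein sequences. Detects
    the four canonical nif operons (nifBSU, nifHDK, nifENXW, nifVZT) in ordered
    gene tables by intergenic gap rules, resolves within-operon paralogs by
    congruence with a species tree, assigns nif1/nif2 identities to dual operon
    sets, flags horizontally transferred homologs by branch-length outliers and
    placement incongruence, and reconstructs minimum-loss (Dollo) histories of
    the repertoire on a rooted species tree. Ships a fully seeded synthetic-data
    generator (species trees, protein evolution, operon-bearing gene orders,
    lineage losses, duplications, fusions, injected transfers) so every stage of
    the pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
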