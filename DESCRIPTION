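Package: cmpscore
Title: Community Metabolic Potential Scoring for Microbiome-Metabolome Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links microbial community taxonomic composition to metabolomic
    variation through a stoichiometric gene-to-metabolite impact model.
    Builds a signed, row-normalized metabolite-by-gene matrix from
    KEGG-dialect reaction files, infers community gene content from taxon
    abundances and genome annotations, computes community-based metabolite
    potential (CMP) scores, and compares CMP variation to measured
    metabolite variation with Mantel permutation tests and false discovery
    rate control to classify metabolites as well-predicted or
    anti-predicted. Includes perturbation-based identification of key
    species, gene, and reaction contributors, degree-preserving network
    randomization and metabolite-label permutation null models, and a
    synthetic community generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
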