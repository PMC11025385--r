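Package: gh99evo
Title: Motif Annotation, Ohnolog Classification and Prevalence Analysis of
    GH99 Glycoside Hydrolases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-anchored analysis of glycoside hydrolase family 99
    (GH99) proteins: extraction of the five diagnostic sequence motifs in
    human MANEA numbering, rule-based prediction of endomannosidase versus
    endomannanase activity and catalytic status, position-specific scoring
    profiles discriminating the vertebrate ohnologs MANEA, MANEAL and
    CMANEAL, greedy identity clustering with cd-hit semantics,
    neighbor-joining trees with taxonomic-incongruence decontamination, and
    per-clade prevalence and motif-composition reporting. Includes a
    synthetic-cohort generator with planted ground truth for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    phangorn,
    tibble,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
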