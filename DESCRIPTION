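Package: metadark
Title: Metagenome-Guided Discovery of Novel Bacterial Taxa
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for mining assembled metagenomes for genomic "dark
    matter" belonging to novel bacterial species and for guiding their
    cultivation and confirmation. Provides genus-level taxonomic binning of
    contigs by proteome best-hit voting, a multi-evidence novelty screen
    that separates contigs of known species and mobile elements from
    putative novel taxa, glycosyl-hydrolase (GH) glycobiome profiling with
    carbon-source recommendation for selective cultivation, fragment-based
    average nucleotide identity (ANI) with the 95 percent species boundary,
    ITS-based isolate triage, core-genome ortholog clustering with a
    bootstrapped neighbor-joining phylogeny, and a deterministic synthetic
    community simulator with truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    Biostrings,
    ape,
    data.table,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    phangorn,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
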