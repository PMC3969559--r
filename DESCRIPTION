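Package: lecatrace
Title: Tracing the Prokaryotic Origins of Ancestral Eukaryotic Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A phylogenomic pipeline for classifying the prokaryotic origins
    of genes present in the last eukaryotic common ancestor (LECA) from
    single-gene trees. Detects monophyletic eukaryotic (LECA) clades in
    unrooted gene-family trees, reduces them to representative sequences by
    least-squares rooting and iterative leaf pruning, assigns taxonomy-aware
    origin "configurations" (group-related, domain-related, three-domain,
    unclear, paraphyletic) under per-group species-representation thresholds,
    and quantifies the robustness of each call with two bootstrap statistics:
    the node bootstrap support (NBS) of the tripartition at the base of the
    eukaryotic stem and the sister-group stability (SGS) score, with an SGS
    threshold calibration utility. A gene-tree simulator with gene loss,
    horizontal and endosymbiotic transfer, and controllable bootstrap
    instability makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    phytools,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
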