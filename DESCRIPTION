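Package: mirmycn
Title: Integrative Discovery of MYCN-Targeting microRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and contextualizing microRNAs that target
    the MYCN 3'UTR. Converts dual-luciferase reporter-screen readings into
    robust-z interaction scores with median centering against analog screens,
    derives a ROC maximum-accuracy hit cutoff, scans a 3'UTR for 6/7/8-mer
    seed-match sites, integrates screen hits with tumor miRNA/mRNA expression
    (Spearman correlation pi-values, preranked gene-set enrichment analysis
    with permutation FDR), and quantifies murine progression dynamics from
    qPCR Cq tables (global-mean normalization, genotype-by-time regression
    with delta-slope pi-values, signature scoring, differential expression).
    A synthetic-data generator with known planted truths makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
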