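Package: regnetr
Title: Mining Context-Specific Transcription Networks from Fold-Change Compendia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Composite gene-set analysis for transcription-network mining.
    Intersects transcription-factor binding-site (TFBS) gene sets with
    functional (GO/KEGG) gene sets, tests each significant intersection for
    coordinated expression change in every condition of a log fold-change
    compendium, and reports (TF, function, condition) triples together with
    candidate target genes. Includes hypergeometric overlap testing with
    Benjamini-Hochberg FDR control, gene-randomization z-statistics,
    guilt-by-association annotation extension through protein-interaction
    neighborhoods, pooled gold-standard evaluation, and a synthetic-data
    generator with planted regulons for end-to-end calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
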