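Package: dailoc
Title: Somato-Dendritic mRNA Localization Analysis via the Dendritic Accumulation Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide analysis of somato-dendritic mRNA localization
    from layer-microdissected RNA-seq of hippocampal CA1 (stratum pyramidale vs.
    stratum radiatum). Computes FPKM and the dendritic accumulation index (DAI),
    classifies transcripts into dendritically (D) and somatically (S) enriched
    sets with a Welch test and Benjamini-Hochberg FDR control, quantifies the
    genome-wide collapse of localization asymmetry between genotypes with a
    variance-ratio F test and selectivity correlations, and tests GO term
    over-representation with a hypergeometric model. Includes a negative-binomial
    simulator of compartmentalized RNA-seq data with known ground truth for
    validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
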