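Package: camelliaoil
Title: Seed Oil Dynamics and Lipid-Pathway Expression Screening in Camellia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for seed-oil dynamics during Camellia seed
    desiccation. Converts GC-FID peak tables into fatty-acid contents via
    internal-standard (margaric acid) normalisation, derives mole-percent
    composition and the USFA/SFA, MUFA/PUFA and 18C/16C ratios, infers
    relative enzyme-activity proxies (KASII, FatB, SAD, FAD2, FAD3, FAE)
    from week-over-week changes of pathway product pools, builds Pearson
    correlation networks among total oil and individual fatty acids, and
    implements the cross-cultivar differential-expression screen:
    reciprocal best-hit homolog pairing, within-cultivar fold changes, the
    ratio-of-fold-changes cutoff, and five-group classification of
    lipid-pathway genes. A synthetic-data module generates all pipeline
    inputs with stored ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, igraph, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
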