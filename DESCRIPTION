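Package: crfdeconv
Title: Deconvolution of Induced Transcriptome Responses with a Carbon
    Response Factor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Dissects the transcriptome response to an induced rise in
    trehalose 6-phosphate (Tre6P) in Arabidopsis into direct Tre6P effects,
    indirect low-sugar effects, and sugar-insensitive effects.  Implements a
    weighted beta-binomial proportions test for differential expression on
    replicated RNA-seq counts, correction for ethanol/empty-vector (alcR)
    off-target effects by shared-DEG omission or linear-model
    residualization, construction of a per-gene carbon response factor (CRF)
    from a panel of reference sugar-manipulation contrasts, assignment of
    responsive genes to groups G1/G2/G0, PageMan-style filtered-average
    display over MapMan BINs, sign-concordance and regression comparison
    with external response signatures, and a synthetic-data generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
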