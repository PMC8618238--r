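Package: riisregulome
Title: Transcription-Factor Dependence of Gene Expression Under Reduced
    Insulin/IGF-1 Signaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative transcriptomic framework for determining which genes
    depend on the DAF-16, SKN-1 and HSF-1 transcription factors downstream of
    reduced insulin/IGF-1 signaling (rIIS) in C. elegans RNAi knockdown
    designs. Provides a negative-binomial count simulator with known
    regulatory ground truth for the seven-condition study design, RPKM/CPM
    quantification and QC, oriented two-group differential expression (NB-GLM
    fold change with library-size offsets and a weighted beta-binomial
    proportions test with moderated overdispersion), numerically stable
    log-space hypergeometric overlap statistics with representation factors,
    and the comparative classification layer: rIIS-dependence cross-tabulation,
    reversal-to-control analysis, quadrant sign-concordance classification and
    combinatorial transcription-factor dominance tabulation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    DESeq2,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
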