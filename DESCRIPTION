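Package: metacred
Title: Meta-Analysis and Cumulative-Evidence Grading for Genetic
    Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for field-synopsis meta-analysis of genetic
    variant-disease associations from case-control genotype counts:
    per-study odds ratios and Hardy-Weinberg tests, fixed-effect and
    DerSimonian-Laird random-effects pooling with Cochran's Q, I-squared
    and tau-squared, sensitivity and cumulative analyses, subgroup
    pooling, meta-regression, the Harbord small-study-effects test,
    false-positive report probability (FPRP), Venice-criteria credibility
    grading, genetic model-free inference on the mode of inheritance, and
    a calibrated synthetic-catalogue generator.  Ships an encoded
    catalogue of published summary results for variants in the
    chromosome 8q24 region across seven cancers.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
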