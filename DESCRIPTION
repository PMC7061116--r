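Package: bradyvar
Title: ACMG/AMP Variant Classification for Familial Bradycardia Gene Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested implementation of the ACMG/AMP five-tier sequence
    variant classification framework applied to the genetics of familial
    bradycardia (sick sinus syndrome, atrioventricular block, progressive
    cardiac conduction disease). Provides the 28-code evidence taxonomy and
    the combination rule engine with exhaustive enumeration support, an
    annotation-to-evidence-code assignment layer with allele-frequency
    thresholds, a curated literature-derived variant dataset with per-gene
    prioritization reproducing the 13 high-priority conduction-disease
    genes, a synthetic cohort generator with planted pathogenic genes for
    end-to-end validation, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    digest,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
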