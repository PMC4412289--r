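Package: stressdiv
Title: Cis- and Trans-Regulatory Divergence of the ER Stress Transcriptional Response
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting the genetic architecture of the tunicamycin-induced
    ER stress transcriptional response across inbred mouse strains and their F1
    hybrids. Calls stress-induced genes per strain from gene-level read counts (TMM
    normalization and a common-dispersion negative-binomial exact test), tests for
    strain effects on induction magnitude by one-way ANOVA on log2 fold changes,
    classifies cis- versus trans-regulatory divergence per gene from F1
    allele-specific read counts with a two-step hierarchical exact-test procedure,
    detects stress-induced changes in allele-specific expression, and quantifies
    regulatory differences shared across F1 crosses. Includes a synthetic-data
    generator with known regulatory architecture (induction, cis, trans, and
    stress-only effects) so every stage can be validated by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    edgeR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
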