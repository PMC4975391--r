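Package: secondhit
Title: Somatic Second-Hit Analysis of TSC1/TSC2-Driven Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of paired tumor/normal exome variant data for tumors
    driven by biallelic inactivation of the TSC1 or TSC2 tumor suppressors
    (renal angiomyolipoma and lymphangioleiomyomatosis). Maps copy-neutral
    loss of heterozygosity from SNP allele-fraction skew, classifies the
    per-sample two-hit inactivation mechanism (second point mutation,
    copy-neutral LOH, or homozygous deletion), summarises somatic mutation
    burden per megabase with an exact Fisher contingency test, reconstructs
    patient-level clonal phylogenies of multifocal tumors from shared
    somatic events, and estimates tumor purity from variant allele
    fractions under copy-neutral genotype models. Ships transcriptions of
    the published variant tables as fixtures and a synthetic tumor/normal
    data generator with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
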