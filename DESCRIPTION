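Package: personALL
Title: Personalized Genetic Risk Assessment for Pediatric B-Cell Precursor ALL
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Copy-number aberration calling from digitalMLPA-style probe read
    counts (two-step dosage-quotient normalization, purity-aware clonal,
    subclonal and biallelic classification, exon-resolution IKZF1 deletion
    patterns, digital karyotyping), assembly of per-patient genetic lesion
    profiles with composite genotypes (IKZF1plus, double trisomies,
    high-hyperdiploidy), derivation of signed integer aberration scores from
    univariate Cox proportional-hazards models with frequency and
    hazard-ratio selection filters, cumulative per-patient scoring with
    four-group risk classification, a cytogenetics-aware IKAROS three-group
    classifier, Kaplan-Meier / log-rank survival comparison, pairwise
    Fisher co-segregation testing, and a synthetic B-cell precursor acute
    lymphoblastic leukemia cohort simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    tools,
    jsonlite,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
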