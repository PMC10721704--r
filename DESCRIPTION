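Package: penescreen
Title: Screening for Modifiers of Incomplete Penetrance in Founder-Variant Carriers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for identifying phenotypic and genetic factors
    associated with the absence of cardiomyopathy symptoms in carriers of an
    incompletely penetrant founder variant (modelled on PLN:c.40_42delAGA).
    Provides four-group classification of carriers and non-carriers by symptom
    status, kinship-aware linear mixed-model trait screens with permutation-based
    empirical false-discovery control, directional confirmation across group
    contrasts, a founder-haplotype window-expansion algorithm on phased
    genotypes, a logistic genome-wide scan with a founder-linkage confound
    screen, rare-variant burden tests with permutation calibration for extreme
    case-control imbalance, and polygenic-score interaction analyses. A
    family-structured synthetic-cohort generator with known ground truth drives
    all stages, together with analytic power calculators for the carrier
    screen design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
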