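Package: phylometab
Title: Parsimony Phylometabolomics of Untargeted Serum LC-MS Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies patient cohorts from untargeted LC-MS serum
    metabolomics feature tables using binary-character maximum parsimony.
    Feature intensities are polarized against a healthy outgroup into
    ancestral (0) and derived (1) character states (distinguishing up,
    down, novel and vanished peaks), a most-parsimonious cladogram is
    inferred by Wagner/Fitch parsimony with randomized stepwise addition
    and branch swapping, clade-defining synapomorphies are extracted at
    each node, and clade membership and metabolite biosignatures are
    correlated with clinical covariates. Includes ppm-tolerance adduct
    matching against a local compound table and a synthetic-cohort
    generator with planted clade structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
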