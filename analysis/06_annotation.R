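#!/usr/bin/env Rscript
# Putative identification of the simulated features against the packaged
# example compound table, at 5 ppm with H / Na / K adducts. Synthetic m/z
# values rarely coincide with real metabolite masses, so this script also
# plants one feature at the protonated mass of D-tryptophan to show a hit.
#
# Output: results/annotation.csv

suppressMessages(library(phylometab))

ft <- read_feature_table("results/cohort/features.csv")
compounds <- read_compound_table(
  system.file("extdata", "compounds_example.csv", package = "phylometab")
)

# plant a feature at the [M+H]+ of D-tryptophan as a positive control
trp <- compounds$monoisotopic_mass[compounds$name == "D-tryptophan"]
ft$features$mz[1] <- adduct_mz(trp, "[M+H]+")

hits <- match_features(ft, compounds, tol_ppm = 5)
utils::write.csv(hits, "results/annotation.csv", row.names = FALSE)
cat("candidate identifications within 5 ppm:\n")
print(hits)
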