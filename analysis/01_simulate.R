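#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study dataset.
#
# The field GC-MS data are not publicly deposited, so the whole workflow
# runs on a synthetic stand-in emulating the sampling design: 227 samples
# in the 11 non-empty year x species x sex cells, 113 compounds, sparse
# compositional percent profiles, and planted species/sex/year effects on
# a small marker set (documented in vignettes/chemical-signatures.Rmd).

library(iguanachem)

seed <- 20120527 %% .Machine$integer.max
dir.create("results", showWarnings = FALSE)

spec <- default_study_spec(seed)
gen <- generate_profiles(spec)

write_compound_table(gen$table, "results/profiles.csv",
                     "results/annotations.csv")
write.csv(gen$metadata, "results/metadata.csv", row.names = FALSE)

cat("Simulated", nrow(gen$table$abundances), "samples x",
    ncol(gen$table$abundances), "compounds\n")
print(with(gen$metadata, table(year, species, sex)))
cat("Planted species markers:",
    paste(sprintf("c%03d", spec$species_markers), collapse = ", "), "\n")
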