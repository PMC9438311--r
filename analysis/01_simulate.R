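#!/usr/bin/env Rscript
# Build the synthetic study cohort: 12 species (2 outgroup, 5 background,
# 5 contracted), 200 single-copy families, ~1500 introns with known
# orthology, ancestral sizes, classes, planted conserved elements and a
# planted term association. Writes per-species FASTA+GFF3 and truth tables.

library(intronevo)
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = 1L)
cohort <- simulate_cohort(cfg, dir = "results/cohort")
saveRDS(cohort, "results/cohort.rds")

cat("species:", paste(cohort$species, collapse = " "), "\n")
cat("reference:", cohort$reference,
    "| contracted:", paste(cohort$contracted, collapse = " "), "\n")
cat("introns:", nrow(cohort$truth$class), "\n")
print(table(cohort$truth$class$class))
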