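#!/usr/bin/env Rscript
# Reference-anchored intron orthology by sticky Needleman-Wunsch alignment
# of spliced transcripts with intron meta-characters; scored against truth.

library(intronevo)
cohort <- readRDS("results/cohort.rds")
catalogue <- readRDS("results/catalogue.rds")
families <- read.delim(file.path(cohort$dir, "families.tsv"))

orth <- build_orthology(cohort$files, families, cohort$reference,
                        catalogue = catalogue)
saveRDS(orth, "results/orthology.rds")
write.table(data.frame(intron = rownames(orth$lengths), orth$lengths,
                       check.names = FALSE),
            "results/orthology.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

m <- orth$matches
n_true <- sum(cohort$truth$orthology$species != cohort$reference)
cat("reference introns:", nrow(orth$lengths), "\n")
cat("recovered:", round(100 * sum(m$rank_ref == m$rank_partner) / n_true, 2),
    "% | misassigned:",
    round(100 * sum(m$rank_ref != m$rank_partner) / n_true, 3), "%\n")
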