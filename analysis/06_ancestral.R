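#!/usr/bin/env Rscript
# Sankoff maximum-parsimony reconstruction of discretised (10*log2) intron
# sizes on the inferred tree: root-state recovery, cumulative branch
# changes, mode lines and minimised proportions.

library(intronevo)
cohort <- readRDS("results/cohort.rds")
orth <- readRDS("results/orthology.rds")
tree <- readRDS("results/tree.rds")$tree

states <- discretize_size(orth$lengths)
dim(states) <- dim(orth$lengths)
dimnames(states) <- dimnames(orth$lengths)
recon <- sankoff_reconstruct(tree, states)
saveRDS(recon, "results/ancestral.rds")

## root-state recovery against truth
anc <- cohort$truth$ancestral
tru <- anc[anc$node == cohort$tree$node.label[1], ]
tru_states <- setNames(10 * tru$log2_size, tru$intron_id)
inf <- recon$states[, tree$node.label[1]]
common <- intersect(names(tru_states), names(inf))
cat("root-state Spearman correlation:",
    round(cor(tru_states[common], inf[common], method = "spearman"), 3),
    "\n")

bc <- branch_changes(recon, tree)
write.table(bc, "results/branch_changes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
tips <- bc[bc$is_tip, ]
cat("mean cumulative state change, contracted leaves:",
    round(mean(tips$mean_change[tips$node %in% cohort$contracted]), 1),
    "| background leaves:",
    round(mean(tips$mean_change[!(tips$node %in% cohort$contracted)]), 1),
    "\n")

## mode lines and minimised proportions, ancestral node vs one contracted
## and one background species
root_states <- recon$states[, tree$node.label[1]]
for (sp in c(cohort$contracted[1],
             setdiff(cohort$species,
                     c(cohort$contracted, cohort$outgroup))[1])) {
  ext <- states[, sp]
  ml <- mode_lines(root_states, ext, extant_lengths = orth$lengths[, sp],
                   taxon = sp)
  lines_df <- do.call(rbind, lapply(seq_along(ml), function(i)
    cbind(taxon = sp, line = i, ml[[i]])))
  write.table(lines_df, sprintf("results/mode_lines_%s.tsv", sp),
              sep = "\t", quote = FALSE, row.names = FALSE)
  mp <- minimised_proportion(root_states, orth$lengths[, sp])
  write.table(mp, sprintf("results/minimised_%s.tsv", sp), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sp, ": ", length(ml), " mode line(s); minimised proportion in",
      " anciently-long bins: ",
      round(mean(mp$proportion[mp$bin_lo >= 110], na.rm = TRUE), 3),
      "\n", sep = "")
}
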